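# Greedy identity clustering with deterministic representative selection.

#' Greedy identity clustering
#'
#' Deterministic single-pass clustering at an identity threshold (default
#' 90 percent): sequences are visited in order of decreasing ungapped
#' length (ties broken by id); each sequence joins the first existing
#' cluster whose representative it matches at or above the threshold,
#' otherwise it founds a new cluster and becomes its representative. The
#' founding (longest-first) ordering makes the manual "longest termini
#' privileged" representative choice reproducible.
#'
#' @param aln an [aligned_sequences()].
#' @param idmat a [pairwise_identity()] matrix for `aln`; computed when
#'   `NULL`.
#' @param threshold identity threshold in (0, 1].
#' @return object of class `cluster_set`: list with `clusters` (list of
#'   member id vectors), `representatives` (character vector),
#'   `membership` (named vector id -> cluster index), `threshold`.
#' @export
greedy_cluster <- function(aln, idmat = NULL, threshold = 0.90) {
  stopifnot(inherits(aln, "aligned_sequences"))
  if (!(threshold > 0 && threshold <= 1))
    .stopf("threshold must lie in (0, 1]")
  if (is.null(idmat)) idmat <- pairwise_identity(aln)
  if (!all(aln$ids %in% rownames(idmat)))
    .stopf("identity matrix does not cover all sequences")
  ord <- order(-.ungapped_length(aln), aln$ids)
  reps <- character(0)
  members <- list()
  membership <- setNames(integer(length(aln$ids)), aln$ids)
  for (i in ord) {
    id <- aln$ids[i]
    placed <- FALSE
    for (k in seq_along(reps)) {
      idk <- idmat[id, reps[k]]
      if (!is.na(idk) && idk >= threshold) {
        members[[k]] <- c(members[[k]], id)
        membership[id] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
      membership[id] <- length(reps)
    }
  }
  structure(list(clusters = members, representatives = reps,
                 membership = membership, threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters at %.0f%% identity (%d sequences)\n",
              length(x$clusters), 100 * x$threshold,
              length(x$membership)))
  invisible(x)
}

#' Write cluster membership as TSV
#'
#' @param clusters a [greedy_cluster()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(
    id = names(clusters$membership),
    cluster = unname(clusters$membership),
    representative = clusters$representatives[clusters$membership])
  utils::write.table(df[order(df$cluster, df$id), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequence-funnel filter report
#'
#' Configurable stand-in for a database mining stage: filters a sequence
#' set by minimal ungapped length and id keywords and reports the funnel
#' counts (input, after filters, clusters after [greedy_cluster()]).
#'
#' @param aln an [aligned_sequences()].
#' @param min_length minimal ungapped length (residues).
#' @param keep_pattern optional regular expression ids must match.
#' @param threshold clustering identity threshold.
#' @return list with `counts` (named: input, filtered, clusters), the
#'   filtered `aln` and the `clusters`.
#' @export
filter_report <- function(aln, min_length = 260, keep_pattern = NULL,
                          threshold = 0.90) {
  keep <- .ungapped_length(aln) >= min_length
  if (!is.null(keep_pattern)) keep <- keep & grepl(keep_pattern, aln$ids)
  if (!any(keep)) .stopf("no sequences pass the filters")
  sub <- aligned_sequences(aln$ids[keep], aln$seqs[keep],
                           clade = if (is.null(aln$clade)) NULL else
                             aln$clade[keep])
  cl <- if (sum(keep) >= 2L) greedy_cluster(sub, threshold = threshold) else NULL
  list(counts = c(input = length(aln$ids), filtered = sum(keep),
                  clusters = if (is.null(cl)) sum(keep) else
                    length(cl$clusters)),
       alignment = sub, clusters = cl)
}
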