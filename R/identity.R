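# Pairwise sequence identity and its cumulative distribution.

#' Pairwise identity matrix of an alignment
#'
#' Identity of a pair is the fraction of matching residues over the columns
#' where neither sequence has a gap (gap-excluded denominator, the
#' NRDB/BLAST-style convention; recorded in the result's metadata because
#' conventions differ). A pair with no comparable columns gets `NA` and is
#' flagged.
#'
#' @param aln an [aligned_sequences()].
#' @return object of class `identity_matrix`: symmetric numeric matrix with
#'   unit diagonal; attributes `denominator` (`"gap_excluded"`) and
#'   `undefined_pairs` (two-column matrix of ids, possibly empty).
#' @export
pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "aligned_sequences"))
  n <- length(aln$ids)
  if (n < 2L) .stopf("need at least 2 sequences")
  m <- .seq_matrix(aln)
  gap <- m == "-"
  idm <- diag(1, n)
  rownames(idm) <- colnames(idm) <- aln$ids
  undef <- matrix(character(0), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp)) {
        idm[i, j] <- idm[j, i] <- NA_real_
        undef <- rbind(undef, c(aln$ids[i], aln$ids[j]))
      } else {
        idm[i, j] <- idm[j, i] <- sum(m[i, comp] == m[j, comp]) / sum(comp)
      }
    }
  }
  structure(idm, class = c("identity_matrix", "matrix"),
            denominator = "gap_excluded", undefined_pairs = undef)
}

#' Cumulative distribution of pairwise identities
#'
#' Empirical CDF over all unordered pairs of an identity matrix.
#'
#' @param idmat an [pairwise_identity()] result.
#' @return a function of class `ecdf` (monotone non-decreasing, ends at 1).
#' @export
identity_cdf <- function(idmat) {
  v <- idmat[upper.tri(idmat)]
  v <- v[!is.na(v)]
  if (!length(v)) .stopf("no defined pairwise identities")
  stats::ecdf(v)
}

#' Distances from identities
#'
#' `d = 1 - identity` by default; `"jc"` applies a Jukes-Cantor-style
#' correction for 20 states: `d = -(19/20) log(1 - (20/19)(1 - I))`.
#'
#' @param idmat an identity matrix.
#' @param correction `"none"` or `"jc"`.
#' @return distance matrix (zero diagonal, symmetric).
#' @export
dist_from_identity <- function(idmat, correction = c("none", "jc")) {
  correction <- match.arg(correction)
  p <- 1 - unclass(idmat)
  d <- switch(correction,
              none = p,
              jc = {
                arg <- 1 - (20 / 19) * p
                if (any(arg <= 0, na.rm = TRUE))
                  .stopf("divergence too large for the JC correction")
                -(19 / 20) * log(arg)
              })
  diag(d) <- 0
  d
}
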