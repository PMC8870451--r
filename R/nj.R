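# Neighbor-joining from scratch (Saitou-Nei), serialized through ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q_ij = (n - 2) d_ij - r_i - r_j` is joined (ties broken by the lowest
#' row-major index pair), with branch lengths
#' `b_i = d_ij / 2 + (r_i - r_j) / (2 (n - 2))`, `b_j = d_ij - b_i`, and
#' distances to the new node `d_uk = (d_ik + d_jk - d_ij) / 2`. The method
#' is exact on additive matrices: it returns the generating topology and
#' branch lengths to machine precision. The result is an unrooted `phylo`
#' object (trifurcating root). Two taxa yield a degenerate single-edge tree
#' with a warning, not an error.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   labeled rows.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    .stopf("distance matrix must be square and symmetric")
  if (any(d < 0)) .stopf("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) .stopf("distance matrix must have zero diagonal")
  labs <- rownames(d)
  n <- nrow(d)
  if (n < 2L) .stopf("need at least 2 taxa")
  if (n == 2L) {
    .warnf("only 2 taxa: returning a degenerate single-edge tree")
    nwk <- sprintf("(%s:%.10g,%s:%.10g);", labs[1], d[1, 2] / 2,
                   labs[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  frag <- labs
  D <- d
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest row-major index pair on ties
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and reports for every internal edge of the original tree
#' the percentage of replicates containing the same leaf bipartition (500
#' replicates by protocol). Replicate `r` consumes the `r`-th substream of
#' the seed, so results are reproducible and independent of taxon input
#' order.
#'
#' @param aln an [aligned_sequences()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param correction distance model passed to [dist_from_identity()].
#' @param seed integer seed (mandatory).
#' @return list with `tree` (the original NJ tree, node labels set to the
#'   supports), `support` (numeric per internal node, percent; `NA` for the
#'   root node of the unrooted representation), `n_reps`.
#' @export
bootstrap_support <- function(aln, n_reps = 500, correction = "none", seed) {
  stopifnot(inherits(aln, "aligned_sequences"))
  if (missing(seed)) .stopf("a seed is mandatory for bootstrap resampling")
  if (n_reps < 1) .stopf("n_reps must be >= 1")
  build <- function(a) nj_tree(dist_from_identity(pairwise_identity(a),
                                                  correction))
  tree <- build(aln)
  m <- .seq_matrix(aln)
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_reps))
  boots <- lapply(seq_len(n_reps), function(r) {
    cols <- with_seed(rep_seeds[r],
                      sample.int(ncol(m), ncol(m), replace = TRUE))
    sub <- aligned_sequences(aln$ids,
                             apply(m[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""))
    build(sub)
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  support <- 100 * counts / n_reps
  tree$node.label <- as.character(round(support, 1))
  list(tree = tree, support = support, n_reps = n_reps)
}
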