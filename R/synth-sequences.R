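# Sequence families evolved along a known tree (ground-truth phylogeny).

#' Specification of a synthetic sequence family
#'
#' A root sequence is evolved along a guide tree under a Jukes-Cantor-style
#' uniform 20-state replacement model: along a branch of length `b`
#' substitutions/site, each site keeps its residue with probability
#' `1/20 + (19/20) exp(-20 b / 19)` and otherwise takes one of the other 19
#' residues uniformly. No indels are introduced, so the leaves are aligned
#' by construction and the guide tree is the true tree.
#'
#' @param tree an `ape` `phylo` object or a Newick string, with
#'   non-negative branch lengths and >= 2 tips.
#' @param root_sequence residue string (20-letter alphabet).
#' @param marked_columns optional named integer vector: Ballesteros-style
#'   label -> column index (within sequence length).
#' @param clade_overrides optional list of `list(label=, taxa=, residue=)`
#'   entries forcing a residue at a marked column in a set of leaves
#'   (planted diagnostic splits).
#' @param clade optional named character vector: leaf id -> clade label.
#' @param seed integer seed (mandatory).
#' @return object of class `sequence_evolution_spec`.
#' @export
sequence_evolution_spec <- function(tree, root_sequence,
                                    marked_columns = NULL,
                                    clade_overrides = NULL,
                                    clade = NULL, seed) {
  if (missing(seed)) .stopf("a seed is mandatory for synthetic generators")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) .stopf("tree must be a phylo object or Newick string")
  if (is.null(tree$tip.label) || length(tree$tip.label) < 2L)
    .stopf("empty or degenerate tree: need >= 2 tips")
  if (is.null(tree$edge.length)) .stopf("tree must have branch lengths")
  if (any(tree$edge.length < 0)) .stopf("branch lengths must be >= 0")
  L <- nchar(root_sequence)
  if (L < 1L) .stopf("root sequence must be non-empty")
  bad <- setdiff(unique(strsplit(root_sequence, "")[[1]]),
                 setdiff(.aa_alphabet, c("-", "X")))
  if (length(bad))
    .stopf("root sequence has non-residue character(s): %s",
           paste(bad, collapse = ", "))
  if (!is.null(marked_columns) &&
      any(marked_columns < 1 | marked_columns > L))
    .stopf("marked columns must lie within the sequence length (%d)", L)
  structure(list(tree = tree, root_sequence = root_sequence,
                 marked_columns = marked_columns,
                 clade_overrides = clade_overrides, clade = clade,
                 seed = as.integer(seed)),
            class = "sequence_evolution_spec")
}

# JC-20 probability of keeping a residue over branch length b (subs/site)
.jc20_keep <- function(b) 1 / 20 + (19 / 20) * exp(-20 * b / 19)

#' Generate an aligned sequence family along a known tree
#'
#' @param spec a [sequence_evolution_spec()].
#' @return list with `alignment` (an [aligned_sequences()] of the leaves)
#'   and `tree` (the true guide tree).
#' @export
gen_sequence_family <- function(spec) {
  stopifnot(inherits(spec, "sequence_evolution_spec"))
  tree <- spec$tree
  residues <- setdiff(.aa_alphabet, c("-", "X"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[root]] <- strsplit(spec$root_sequence, "")[[1]]
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents are always assigned before children in a rooted phylo
  ord <- ape::reorder.phylo(tree, "cladewise")
  with_seed(spec$seed, {
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      b <- ord$edge.length[e]
      s <- seqs[[parent]]
      keep <- .jc20_keep(b)
      hit <- runif(length(s)) > keep
      if (any(hit)) {
        s[hit] <- vapply(s[hit], function(old)
          sample(setdiff(residues, old), 1L), "")
      }
      seqs[[child]] <- s
    }
  })
  leaf_seqs <- vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), "")
  names(leaf_seqs) <- tree$tip.label
  for (ov in spec$clade_overrides) {
    col <- if (!is.null(ov$label) && !is.null(spec$marked_columns))
      spec$marked_columns[[ov$label]] else ov$column
    if (is.null(col)) .stopf("clade override needs a marked label or a column")
    for (tx in ov$taxa) {
      if (!tx %in% names(leaf_seqs)) .stopf("override taxon '%s' not a leaf", tx)
      substr(leaf_seqs[tx], col, col) <- ov$residue
    }
  }
  clade <- if (is.null(spec$clade)) NULL else
    unname(spec$clade[tree$tip.label])
  list(alignment = aligned_sequences(tree$tip.label, unname(leaf_seqs),
                                     clade = clade),
       tree = tree)
}
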