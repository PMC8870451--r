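# Ballesteros-Weinstein position annotation on an alignment.

#' Map reference positions to alignment columns and tabulate patterns
#'
#' Ballesteros-Weinstein labels (e.g. `2.50`, `3.35`, `7.46`) anchored on a
#' reference sequence's ungapped residue indices are mapped through the
#' alignment; for each label the table reports the residue carried by every
#' sequence, per-clade consensus (most frequent residue), and the logo
#' frequency vector of the column.
#'
#' @param aln an [aligned_sequences()] (clade labels used when present).
#' @param reference_id id of the reference sequence.
#' @param anchors named integer vector: label -> ungapped residue index in
#'   the reference.
#' @param anchor_residues optional named character vector declaring the
#'   reference residue expected at each anchor; a mismatch is an error
#'   (catches mis-specified numbering).
#' @return object of class `position_pattern_table`: list with `table`
#'   (long data frame: label, column, id, clade, residue), `consensus`
#'   (data frame: label, clade, residue), `frequencies` (named list of
#'   per-column residue frequency vectors), `columns` (label -> column).
#' @export
position_patterns <- function(aln, reference_id, anchors,
                              anchor_residues = NULL) {
  stopifnot(inherits(aln, "aligned_sequences"))
  ri <- match(reference_id, aln$ids)
  if (is.na(ri)) .stopf("reference '%s' not in the alignment", reference_id)
  if (is.null(names(anchors)) || any(names(anchors) == ""))
    .stopf("anchors must be a named vector (label -> residue index)")
  refchars <- strsplit(aln$seqs[ri], "")[[1]]
  notgap <- refchars != "-"
  nres <- sum(notgap)
  if (any(anchors < 1 | anchors > nres))
    .stopf("anchor index outside the reference's %d residues", nres)
  col_of_res <- which(notgap)
  columns <- setNames(col_of_res[anchors], names(anchors))
  if (!is.null(anchor_residues)) {
    for (lab in names(anchor_residues)) {
      got <- refchars[columns[lab]]
      if (got != anchor_residues[[lab]])
        .stopf("anchor %s: reference has '%s' at residue %d, declared '%s'",
               lab, got, anchors[[lab]], anchor_residues[[lab]])
    }
  }
  m <- .seq_matrix(aln)
  clade <- if (is.null(aln$clade)) rep("all", length(aln$ids)) else aln$clade
  tab <- do.call(rbind, lapply(names(columns), function(lab)
    data.frame(label = lab, column = columns[[lab]], id = aln$ids,
               clade = clade, residue = m[, columns[[lab]]],
               row.names = NULL)))
  consensus <- do.call(rbind, lapply(split(tab, tab[c("label", "clade")]),
    function(g) {
      if (!nrow(g)) return(NULL)
      cnt <- sort(table(g$residue), decreasing = TRUE)
      data.frame(label = g$label[1], clade = g$clade[1],
                 residue = names(cnt)[1], row.names = NULL)
    }))
  rownames(consensus) <- NULL
  freqs <- lapply(names(columns), function(lab) {
    v <- m[, columns[[lab]]]
    tf <- table(v) / length(v)
    setNames(as.numeric(tf), names(tf))
  })
  names(freqs) <- names(columns)
  structure(list(table = tab, consensus = consensus, frequencies = freqs,
                 columns = columns),
            class = "position_pattern_table")
}
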