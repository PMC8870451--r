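# Aligned sequence sets: container and FASTA I/O.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X")

#' Aligned sequence set
#'
#' Equal-length aligned residue strings over the 20 amino acids plus the
#' gap character `-` and the unknown `X`.
#'
#' @param ids character vector of unique sequence ids.
#' @param seqs character vector of aligned sequences (same length each).
#' @param clade optional character vector of taxon/clade labels (e.g.
#'   phylum), same length as `ids`.
#' @return object of class `aligned_sequences`.
#' @export
aligned_sequences <- function(ids, seqs, clade = NULL) {
  if (length(ids) != length(seqs)) .stopf("ids and seqs differ in length")
  if (anyDuplicated(ids)) .stopf("sequence ids must be unique")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    .stopf("sequences are not aligned: lengths %s", paste(len, collapse = ", "))
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 .aa_alphabet)
  if (length(bad))
    .stopf("illegal residue character(s): %s", paste(bad, collapse = ", "))
  if (!is.null(clade) && length(clade) != length(ids))
    .stopf("clade labels must match ids in length")
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 clade = clade, width = len),
            class = "aligned_sequences")
}

#' @export
print.aligned_sequences <- function(x, ...) {
  cat(sprintf("<aligned_sequences> %d sequences x %d columns\n",
              length(x$ids), x$width))
  invisible(x)
}

# character matrix (sequences x columns)
.seq_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Read / write aligned FASTA
#'
#' @param path file path.
#' @param clade optional clade labels for [read_fasta_alignment()].
#' @return [read_fasta_alignment()]: an [aligned_sequences()];
#'   [write_fasta_alignment()]: invisibly, `path`.
#' @export
read_fasta_alignment <- function(path, clade = NULL) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) .stopf("no FASTA headers in '%s'", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  seqs <- vapply(seq_along(hdr), function(i)
    toupper(paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")), "")
  aligned_sequences(ids, seqs, clade = clade)
}

#' @rdname read_fasta_alignment
#' @param aln an [aligned_sequences()].
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_sequences"))
  out <- character(2L * length(aln$ids))
  out[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  out[c(FALSE, TRUE)] <- aln$seqs
  writeLines(out, path)
  invisible(path)
}

# ungapped length per sequence
.ungapped_length <- function(aln) {
  nchar(gsub("-", "", aln$seqs, fixed = TRUE))
}
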