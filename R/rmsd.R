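# Ion positional deviation after rigid-body superposition.

#' Per-frame ion deviation from a reference position
#'
#' Each frame is rigid-body superposed (Kabsch) onto the reference
#' coordinates using the alignment selection, then the displacement of the
#' ion from its reference position is recorded. The default reference is
#' frame 1 and the default alignment selection is the protein ligand atoms,
#' so the series measures how far the ion wanders from its initial position
#' within the (aligned) binding site.
#'
#' @param traj a [trajectory()].
#' @param reference `n_atoms x 3` coordinate matrix; default frame 1.
#' @param align_ids atom ids used for superposition (>= 3); default all
#'   atoms with role `"protein_ligand"`.
#' @return list with `deviation` (numeric per-frame series, Angstrom),
#'   `times`, `mean`, `sd`.
#' @export
ion_rmsd <- function(traj, reference = NULL, align_ids = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ion <- .ion_index(traj)
  if (is.null(reference)) reference <- traj$coords[, , 1]
  if (!is.matrix(reference) || nrow(reference) != nrow(traj$atoms))
    .stopf("reference must be an n_atoms x 3 coordinate matrix")
  if (is.null(align_ids))
    align_ids <- traj$atoms$id[traj$atoms$role == "protein_ligand"]
  sel <- .atom_index(traj, align_ids)
  if (length(sel) < 3L)
    .stopf("superposition underdetermined: need >= 3 alignment atoms, got %d",
           length(sel))
  ref_sel <- reference[sel, , drop = FALSE]
  ref_ion <- reference[ion, ]
  dev <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- traj$coords[, , f]
    k <- .kabsch(fr[sel, , drop = FALSE], ref_sel)
    ion_aligned <- drop(fr[ion, ] %*% k$R) + k$t
    sqrt(sum((ion_aligned - ref_ion)^2))
  }, 0)
  list(deviation = dev, times = traj$times,
       mean = mean(dev), sd = if (length(dev) > 1) stats::sd(dev) else NA_real_)
}
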