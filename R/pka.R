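# Single-site pKa shifts from continuum electrostatics.

#' Default model-compound pKa values
#'
#' Intrinsic pKa of isolated titratable side chains in water; the
#' single-site protocol shifts these by the electrostatic work difference
#' between the protein environment and the model compound.
#' @return named numeric vector.
#' @export
model_pka_table <- function() {
  c(ASP = 4.0, GLU = 4.4, HIS = 6.3, CYS = 8.3, TYR = 9.6, LYS = 10.4,
    ARG = 12.0, CTR = 3.2, NTR = 8.0)
}

#' pKa from per-frame electrostatic shifts
#'
#' `pKa = pKa_model + ddG / (2.303 kT)` for an acid, with `ddG` (in kT) the
#' change, relative to the model compound, of the electrostatic work of
#' charging the site: a positive `ddG` (charged form destabilized by the
#' environment) raises the pKa of an acid; stabilization of the charged
#' form lowers it. For a base the sign flips.
#'
#' @param shifts_kT per-frame `ddG` values, kT.
#' @param pka_model model-compound pKa.
#' @param acid `TRUE` for acids (charged form is deprotonated).
#' @param residue optional residue id recorded in the result.
#' @return object of class `pka_result`: list with `residue`, `pka_model`,
#'   `per_frame` (pKa per frame), `shift` (mean shift in pK units),
#'   `pka` (mean), `sd`.
#' @export
pka_from_shifts <- function(shifts_kT, pka_model, acid = TRUE,
                            residue = NA_character_) {
  sgn <- if (acid) 1 else -1
  per <- pka_model + sgn * shifts_kT / log(10)
  structure(list(residue = residue, pka_model = pka_model,
                 per_frame = per, shift = mean(per) - pka_model,
                 pka = mean(per),
                 sd = if (length(per) > 1) stats::sd(per) else 0),
            class = "pka_result")
}

# environment (solvation) energy of a state: grid energy in its dielectric
# environment minus grid energy of the same charges on the same grid in
# uniform solvent; the lattice self-energy cancels in the difference.
.state_energy <- function(system, params, geometry) {
  genv <- build_grids(system, params, geometry = geometry)
  Eenv <- grid_energy(solve_lpb(genv, params), genv)
  phom <- params
  phom$eps_in <- params$eps_out     # uniform solvent reference
  ghom <- build_grids(system, phom, geometry = geometry)
  Ehom <- grid_energy(solve_lpb(ghom, phom), ghom)
  Eenv - Ehom
}

#' Single-site pKa from protonation-state charge systems
#'
#' The default protocol evaluates seven equally spaced frames. For each
#' frame, four systems are required: the site in its protein environment in
#' the charged and neutral protonation states, and the isolated model
#' compound in both states. Each state's electrostatic work is its grid
#' energy minus the grid energy of the same charges in uniform solvent
#' (lattice self-energies cancel); the frame shift is
#' `ddG = (G_protein_charged - G_protein_neutral) -
#' (G_model_charged - G_model_neutral)` and
#' `pKa = pKa_model + ddG/(2.303 kT)` for an acid.
#'
#' @param frames a list of frames; each frame is a list with elements
#'   `protein_charged`, `protein_neutral`, `model_charged`,
#'   `model_neutral`, all [charge_system()] objects. Seven frames by
#'   protocol; any count >= 1 is accepted.
#' @param pka_model model-compound pKa (e.g. `model_pka_table()[["ASP"]]`).
#' @param params a [pb_params()].
#' @param acid `TRUE` for acids.
#' @param residue optional residue id.
#' @return a `pka_result` (see [pka_from_shifts()]).
#' @export
pka <- function(frames, pka_model, params = pb_params(), acid = TRUE,
                residue = NA_character_) {
  need <- c("protein_charged", "protein_neutral", "model_charged",
            "model_neutral")
  if (!length(frames)) .stopf("need at least one frame")
  shifts <- vapply(seq_along(frames), function(f) {
    fr <- frames[[f]]
    if (!all(need %in% names(fr)))
      .stopf("frame %d: missing state(s): %s", f,
             paste(setdiff(need, names(fr)), collapse = ", "))
    gp <- build_grids(fr$protein_charged, params)
    geom_p <- .grid_geometry(gp)
    gm <- build_grids(fr$model_charged, params)
    geom_m <- .grid_geometry(gm)
    dg_prot <- .state_energy(fr$protein_charged, params, geom_p) -
      .state_energy(fr$protein_neutral, params, geom_p)
    dg_model <- .state_energy(fr$model_charged, params, geom_m) -
      .state_energy(fr$model_neutral, params, geom_m)
    dg_prot - dg_model
  }, 0)
  pka_from_shifts(shifts, pka_model, acid = acid, residue = residue)
}
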