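# Dual-boost accelerated-MD parameterization and the boost potential.

#' Energy series container
#'
#' @param times times in ns, strictly increasing.
#' @param dihedral dihedral energy values, kcal/mol.
#' @param potential total potential energy values, kcal/mol.
#' @return object of class `energy_series` (a data frame).
#' @export
energy_series <- function(times, dihedral, potential) {
  if (length(times) != length(dihedral) || length(times) != length(potential))
    .stopf("times, dihedral and potential must have equal length")
  if (any(diff(times) <= 0)) .stopf("times must be strictly increasing")
  structure(data.frame(time = times, dihedral = dihedral,
                       potential = potential),
            class = c("energy_series", "data.frame"))
}

#' Generate a stationary synthetic energy series
#'
#' Gaussian white noise around a fixed mean, for the dihedral and total
#' potential columns. `mean` and `sd` may be scalars (shared) or length-2
#' vectors `(dihedral, potential)`.
#'
#' @param mean mean energy, kcal/mol.
#' @param sd standard deviation, kcal/mol (>= 0).
#' @param n number of samples (>= 1).
#' @param dt sampling interval, ns.
#' @param seed integer seed (mandatory).
#' @return an [energy_series()].
#' @export
gen_energy_series <- function(mean, sd, n, dt = 0.1, seed) {
  if (missing(seed)) .stopf("a seed is mandatory for synthetic generators")
  if (n < 1) .stopf("n must be >= 1")
  if (any(sd < 0)) .stopf("sd must be >= 0")
  mean <- rep_len(mean, 2L); sd <- rep_len(sd, 2L)
  with_seed(seed, {
    energy_series(times = seq_len(n) * dt,
                  dihedral = rnorm(n, mean[1], sd[1]),
                  potential = rnorm(n, mean[2], sd[2]))
  })
}

#' Dual-boost acceleration parameters from a classical-MD energy series
#'
#' Threshold energies are the arithmetic means of the dihedral and total
#' potential energies over the stated window of the classical run (the
#' "soft" protocol; default window 20-120 ns). The acceleration factors are
#' `alpha_dihed = lambda * E_dihed_avg / 5` and `alpha_pot = lambda * N`
#' with `N` the atom count and `lambda` the acceleration parameter
#' (default 0.3).
#'
#' @param series an [energy_series()].
#' @param window length-2 numeric, inclusive time window in ns.
#' @param lambda acceleration parameter in (0, 1].
#' @param n_atoms atom count of the simulated system (>= 1).
#' @return object of class `boost_params`: list with `E_dihed_avg`,
#'   `E_pot_avg`, `alpha_dihed`, `alpha_pot`, `lambda`, `n_atoms`, `window`.
#' @export
boost_params <- function(series, window = c(20, 120), lambda = 0.3, n_atoms) {
  stopifnot(inherits(series, "energy_series"))
  if (!(lambda > 0 && lambda <= 1)) .stopf("lambda must lie in (0, 1]")
  if (n_atoms < 1) .stopf("n_atoms must be >= 1")
  sel <- series$time >= window[1] & series$time <= window[2]
  if (!any(sel)) .stopf("window [%g, %g] ns contains no samples",
                        window[1], window[2])
  ed <- mean(series$dihedral[sel])
  ep <- mean(series$potential[sel])
  structure(list(E_dihed_avg = ed, E_pot_avg = ep,
                 alpha_dihed = lambda * ed / 5,
                 alpha_pot = lambda * n_atoms,
                 lambda = lambda, n_atoms = as.integer(n_atoms),
                 window = window),
            class = "boost_params")
}

#' @export
print.boost_params <- function(x, ...) {
  cat(sprintf(paste0("<boost_params> lambda=%g, N=%d, window %g-%g ns\n",
                     "  E_dihed_avg=%.3f  alpha_dihed=%.3f\n",
                     "  E_pot_avg=%.3f  alpha_pot=%.3f\n"),
              x$lambda, x$n_atoms, x$window[1], x$window[2],
              x$E_dihed_avg, x$alpha_dihed, x$E_pot_avg, x$alpha_pot))
  invisible(x)
}

#' Write boost parameters as JSON and a NAMD-style snippet
#'
#' @param bp a [boost_params()].
#' @param json_path,snippet_path output paths (`NULL` to skip one).
#' @return invisibly, a list of the written paths.
#' @export
write_boost_params <- function(bp, json_path = NULL, snippet_path = NULL) {
  stopifnot(inherits(bp, "boost_params"))
  if (!is.null(json_path))
    jsonlite::write_json(unclass(bp), json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(snippet_path))
    writeLines(c("accelMD            on",
                 "accelMDdual        on",
                 sprintf("accelMDE           %.6f", bp$E_dihed_avg),
                 sprintf("accelMDalpha       %.6f", bp$alpha_dihed),
                 sprintf("accelMDTE          %.6f", bp$E_pot_avg),
                 sprintf("accelMDTalpha      %.6f", bp$alpha_pot)),
               snippet_path)
  invisible(list(json = json_path, snippet = snippet_path))
}

#' Dual-boost bias potential
#'
#' The boost added to a scalar energy `V` below a threshold `E`:
#' `dV = (E - V)^2 / (alpha + E - V)` for `V < E`, else 0. The boosted
#' energy `V + dV` never exceeds `E`, and `dV` is continuous at `V = E`.
#'
#' @param V energy value(s), kcal/mol.
#' @param E_threshold boost threshold, kcal/mol.
#' @param alpha acceleration factor, kcal/mol (> 0).
#' @return the boost `dV` (same length as `V`).
#' @export
apply_boost <- function(V, E_threshold, alpha) {
  if (!(alpha > 0)) .stopf("alpha must be > 0")
  gap <- E_threshold - V
  ifelse(gap > 0, gap^2 / (alpha + gap), 0)
}
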