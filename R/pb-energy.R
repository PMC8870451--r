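# Grid-energy-difference binding free energy and snapshot aggregation.

#' Electrostatic binding free energy by the three-run grid-energy difference
#'
#' `dG_bind = E_grid(complex) - E_grid(receptor) - E_grid(ion)`, all three
#' solved on the identical grid (same origin, spacing, node count), which
#' the complex defines. Identical placement makes the lattice self-energies
#' cancel. The receptor and ion systems must partition the complex atom for
#' atom at identical coordinates; any mismatch is rejected.
#'
#' @param complex,receptor,ion [charge_system()] objects; `receptor` plus
#'   `ion` must equal `complex`.
#' @param params a [pb_params()].
#' @return list with `dG` (kT), `E_complex`, `E_receptor`, `E_ion`,
#'   `box_occupancy`.
#' @export
binding_energy <- function(complex, receptor, ion, params = pb_params()) {
  comp <- .coords_mat(complex)
  part <- rbind(.coords_mat(receptor), .coords_mat(ion))
  if (nrow(part) != nrow(comp))
    .stopf("receptor (+ ion) has %d atoms, complex has %d", nrow(part),
           nrow(comp))
  key <- function(m, q) paste(sprintf("%.6f", m[, 1]), sprintf("%.6f", m[, 2]),
                              sprintf("%.6f", m[, 3]), sprintf("%.6f", q))
  if (!setequal(key(comp, complex$atoms$q),
                key(part, c(receptor$atoms$q, ion$atoms$q))))
    .stopf("receptor + ion do not match the complex atom-for-atom at identical coordinates")

  gc_ <- build_grids(complex, params)
  geom <- .grid_geometry(gc_)
  gr <- build_grids(receptor, params, geometry = geom)
  gi <- build_grids(ion, params, geometry = geom)
  if (!.geometry_equal(geom, .grid_geometry(gr)) ||
      !.geometry_equal(geom, .grid_geometry(gi)))
    .stopf("grid geometry mismatch between the three runs")
  Ec <- grid_energy(solve_lpb(gc_, params), gc_)
  Er <- grid_energy(solve_lpb(gr, params), gr)
  Ei <- grid_energy(solve_lpb(gi, params), gi)
  list(dG = Ec - Er - Ei, E_complex = Ec, E_receptor = Er, E_ion = Ei,
       box_occupancy = gc_$box_occupancy)
}

#' Binding energy from already-computed grid energies
#'
#' Direct substitution into the grid-energy-difference formula.
#'
#' @param e_complex,e_receptor,e_ion grid energies, kT.
#' @return `e_complex - e_receptor - e_ion` (kT).
#' @export
binding_energy_from_grid <- function(e_complex, e_receptor, e_ion) {
  e_complex - e_receptor - e_ion
}

#' Select equidistant snapshot times from a trajectory
#'
#' The aggregation protocol extracts equidistant snapshots (by default 35
#' snapshots separated by 8 ns) from each trajectory.
#'
#' @param times frame times, ns.
#' @param step snapshot spacing, ns.
#' @param count number of snapshots.
#' @return integer indices into `times`.
#' @export
select_snapshots <- function(times, step = 8, count = 35) {
  targets <- times[1] + (seq_len(count) - 1L) * step
  if (max(targets) > max(times) + 1e-9)
    .stopf("trajectory too short: needs %.0f ns for %d snapshots every %g ns",
           max(targets) - times[1], count, step)
  vapply(targets, function(t) which.min(abs(times - t)), 0L)
}

#' Aggregate per-snapshot binding energies across trajectories
#'
#' Boxplot statistics (median, quartiles, extremes) over all snapshots,
#' per-trajectory means, and the least-squares coefficient of determination
#' between per-trajectory mean binding energy and mean first-shell protein
#' coordination. With fewer than two trajectories the correlation is
#' omitted (`NA`), never fabricated. Warns when a solute's box occupancy
#' reaches 70 percent (grid-size check of the snapshot protocol).
#'
#' @param snapshots data frame with columns `traj` (trajectory id), `dG`
#'   (kT); optionally `time`.
#' @param coordination data frame with columns `traj` and
#'   `mean_first_protein` (per-trajectory mean first-shell protein
#'   coordination), or `NULL`.
#' @param box_occupancy optional numeric vector of box occupancies to check
#'   against the 70 percent rule.
#' @return object of class `binding_energy_report`: list with `stats`
#'   (median, q1, q3, min, max, mean, n), `per_trajectory`, `r2`,
#'   `fit` (slope, intercept) when computed.
#' @export
aggregate_binding <- function(snapshots, coordination = NULL,
                              box_occupancy = NULL) {
  if (!all(c("traj", "dG") %in% names(snapshots)))
    .stopf("snapshots must have columns 'traj' and 'dG'")
  if (!nrow(snapshots)) .stopf("no snapshots supplied")
  if (!is.null(box_occupancy) && any(box_occupancy >= 0.7))
    .warnf("solute occupies >= 70%% of the box edge in %d snapshot(s); enlarge the grid",
           sum(box_occupancy >= 0.7))
  qs <- stats::quantile(snapshots$dG, c(0.25, 0.5, 0.75), names = FALSE)
  per <- aggregate(dG ~ traj, snapshots, mean)
  names(per)[2] <- "mean_dG"
  r2 <- NA_real_; fit <- NULL
  if (!is.null(coordination)) {
    if (!all(c("traj", "mean_first_protein") %in% names(coordination)))
      .stopf("coordination must have columns 'traj' and 'mean_first_protein'")
    per <- merge(per, coordination, by = "traj")
    if (nrow(per) >= 2L && stats::var(per$mean_first_protein) > 0) {
      x <- per$mean_first_protein; y <- per$mean_dG
      beta <- stats::cov(x, y) / stats::var(x)
      alpha <- mean(y) - beta * mean(x)
      ss_res <- sum((y - alpha - beta * x)^2)
      ss_tot <- sum((y - mean(y))^2)
      r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      fit <- c(slope = beta, intercept = alpha)
    }
  }
  structure(list(
    stats = list(median = qs[2], q1 = qs[1], q3 = qs[3],
                 min = min(snapshots$dG), max = max(snapshots$dG),
                 mean = mean(snapshots$dG), n = nrow(snapshots)),
    per_trajectory = per, r2 = r2, fit = fit),
    class = "binding_energy_report")
}

#' @export
print.binding_energy_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    "<binding_energy_report> n=%d  median %.2f kT (IQR %.2f..%.2f, range %.2f..%.2f)\n",
    s$n, s$median, s$q1, s$q3, s$min, s$max))
  if (!is.na(x$r2))
    cat(sprintf("  dG vs first-shell coordination: R^2 = %.3f\n", x$r2))
  invisible(x)
}
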