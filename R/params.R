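#' Trajectory analysis parameters
#'
#' Container for the geometric cutoffs used in the sodium-pocket trajectory
#' analyses. Defaults are the values used throughout this package's target
#' protocol: protein ligands enter the ion's first coordination shell below
#' 2.8 Angstrom and the second shell up to 6 Angstrom provided a first-shell
#' water bridges them to the ion (water within 3 Angstrom of the protein
#' atom); water first/second shells are 3 and 6 Angstrom; hydrogen bonds use
#' a 3.5 Angstrom donor-acceptor distance and a 30 degree deviation from
#' linearity; the rotamer replica filter looks at the first 50 ns.
#'
#' @param first_shell_protein first-shell cutoff for protein ligands (Angstrom).
#' @param first_shell_water first-shell cutoff for water oxygens (Angstrom).
#' @param second_shell outer cutoff of the second shell (Angstrom).
#' @param bridge_water maximal distance between a first-shell water and a
#'   second-shell protein atom for the water to count as bridging (Angstrom).
#' @param hbond_dist donor-acceptor distance cutoff (Angstrom).
#' @param hbond_angle_dev maximal deviation of the D-H...A angle from 180
#'   degrees (degrees).
#' @param rotamer_filter_window length of the initial window, in ns, within
#'   which an outward rotamerization disqualifies a replica.
#' @return an object of class `analysis_params`.
#' @export
analysis_params <- function(first_shell_protein = 2.8,
                            first_shell_water = 3.0,
                            second_shell = 6.0,
                            bridge_water = 3.0,
                            hbond_dist = 3.5,
                            hbond_angle_dev = 30,
                            rotamer_filter_window = 50) {
  p <- list(first_shell_protein = first_shell_protein,
            first_shell_water = first_shell_water,
            second_shell = second_shell,
            bridge_water = bridge_water,
            hbond_dist = hbond_dist,
            hbond_angle_dev = hbond_angle_dev,
            rotamer_filter_window = rotamer_filter_window)
  if (!(first_shell_protein > 0 && first_shell_protein < second_shell))
    .stopf("need 0 < first_shell_protein < second_shell")
  if (!(hbond_angle_dev > 0 && hbond_angle_dev < 90))
    .stopf("hbond_angle_dev must lie in (0, 90) degrees")
  structure(p, class = "analysis_params")
}

#' Poisson-Boltzmann parameters
#'
#' Parameters of the finite-difference linear Poisson-Boltzmann solver with
#' the smooth Gaussian dielectric. Defaults correspond to the surface-group
#' parameterization used for sodium-pocket energetics: protein permittivity
#' 8, solvent 80, Gaussian width 0.7, ionic strength 0.15 M, 1.8 grid points
#' per Angstrom and a solute filling 70 percent of the box edge.
#'
#' @param eps_in solute (protein) relative permittivity.
#' @param eps_out solvent relative permittivity.
#' @param sigma width of the atomic Gaussian density (dimensionless, scales
#'   the van der Waals radius).
#' @param ionic_strength 1:1 salt ionic strength, mol/L.
#' @param scale grid points per Angstrom.
#' @param fill_ratio ratio of the solute's maximal extent to the box edge.
#' @param grid_points per-axis node count; `NULL` derives it from
#'   `scale` and `fill_ratio`.
#' @param temperature Kelvin.
#' @param dielectric_model `"gaussian"` for the smooth Gaussian dielectric
#'   or `"sharp"` for a two-dielectric model (used by analytic oracles).
#' @param rho_cut solute-density threshold above which mobile ions are
#'   excluded (screening zeroed).
#' @param tol relative residual tolerance of the linear solver.
#' @param maxit maximal solver iterations.
#' @return an object of class `pb_params`.
#' @export
pb_params <- function(eps_in = 8, eps_out = 80, sigma = 0.7,
                      ionic_strength = 0.15, scale = 1.8,
                      fill_ratio = 0.7, grid_points = NULL,
                      temperature = 298.15,
                      dielectric_model = c("gaussian", "sharp"),
                      rho_cut = 0.1, tol = 1e-6, maxit = 3000L) {
  dielectric_model <- match.arg(dielectric_model)
  if (!(eps_in >= 1 && eps_in <= eps_out)) .stopf("need 1 <= eps_in <= eps_out")
  if (!(sigma > 0 && sigma <= 1)) .stopf("sigma must lie in (0, 1]")
  if (!(scale > 0)) .stopf("scale must be positive")
  if (!(fill_ratio > 0 && fill_ratio < 1)) .stopf("fill_ratio must lie in (0, 1)")
  if (!is.null(grid_points) && grid_points < 9) .stopf("grid_points must be >= 9")
  structure(list(eps_in = eps_in, eps_out = eps_out, sigma = sigma,
                 ionic_strength = ionic_strength, scale = scale,
                 fill_ratio = fill_ratio, grid_points = grid_points,
                 temperature = temperature,
                 dielectric_model = dielectric_model,
                 rho_cut = rho_cut, tol = tol, maxit = as.integer(maxit)),
            class = "pb_params")
}
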