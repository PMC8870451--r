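# Dielectric / charge grids for the finite-difference Poisson-Boltzmann
# solver, with the smooth Gaussian dielectric model.

# solute density rho = 1 - prod(1 - g_i) evaluated on the tensor grid
# ax1 x ax2 x ax3 (gaussian) or the sphere-union indicator (sharp).
.density_grid <- function(at, xyz, params, ax1, ax2, ax3) {
  one_minus <- array(1, c(length(ax1), length(ax2), length(ax3)))
  model <- params$dielectric_model
  for (i in seq_len(nrow(at))) {
    R <- at$radius[i]
    cut <- if (model == "gaussian") 5 * params$sigma * R else R
    r1 <- which(abs(ax1 - xyz[i, 1]) <= cut)
    r2 <- which(abs(ax2 - xyz[i, 2]) <= cut)
    r3 <- which(abs(ax3 - xyz[i, 3]) <= cut)
    if (!length(r1) || !length(r2) || !length(r3)) next
    d2 <- outer(outer((ax1[r1] - xyz[i, 1])^2,
                      (ax2[r2] - xyz[i, 2])^2, `+`),
                (ax3[r3] - xyz[i, 3])^2, `+`)
    g <- if (model == "gaussian")
      exp(-d2 / (params$sigma^2 * R^2)) else as.numeric(d2 <= R^2)
    one_minus[r1, r2, r3] <- one_minus[r1, r2, r3] * (1 - g)
  }
  1 - one_minus
}

#' Build dielectric, screening and charge grids for a charge system
#'
#' Lays a cubic node-centered grid over the solute and populates:
#' * the dielectric field. In the `"gaussian"` model each atom contributes
#'   a Gaussian density `g_i(r) = exp(-|r - r_i|^2 / (sigma^2 R_i^2))`; the
#'   solute density is `rho = 1 - prod(1 - g_i)` and
#'   `eps = rho * eps_in + (1 - rho) * eps_out`, a smooth interpolation
#'   with no sharp molecular surface. In the `"sharp"` model `rho` is the
#'   union of the atomic spheres. The face dielectrics entering the
#'   stencil are harmonic averages of `eps` sampled along each edge (the
#'   flux-continuity rule, exact for a one-dimensional interface); node
#'   values are kept for diagnostics.
#' * the ionic screening term `K = eps_out * kappa^2`, zeroed where the
#'   node solute density exceeds `rho_cut` (mobile-ion exclusion).
#' * the charge grid, by trilinear spreading of each atomic charge onto
#'   its 8 surrounding nodes (total charge conserved to machine precision).
#'
#' Box geometry: spacing `h = 1/scale`. If `params$grid_points` is set it
#' fixes the per-axis node count; otherwise the edge is the solute's
#' maximal extent (including radii) divided by `fill_ratio`. The box is
#' centered on the solute unless `center` is given. An explicit `edge`
#' overrides the fill-ratio rule. The box must contain every atom plus its
#' density margin (3 sigma R for the Gaussian model).
#'
#' @param system a [charge_system()].
#' @param params a [pb_params()].
#' @param center optional box center (3-vector, Angstrom).
#' @param edge optional box edge length (Angstrom).
#' @param geometry optional geometry of a previously built grid (list with
#'   `n`, `h`, `origin`), enforcing node-for-node congruence; used by the
#'   three-run binding-energy protocol.
#' @return object of class `dielectric_grid`: list with `n`, `h`, `origin`,
#'   `eps` (node values), `epsx`/`epsy`/`epsz` (face values), `kdiag`
#'   (`K h^2` per node), `qgrid`, `solute_extent`, `box_occupancy`,
#'   `total_charge`, `params`.
#' @export
build_grids <- function(system, params = pb_params(), center = NULL,
                        edge = NULL, geometry = NULL) {
  stopifnot(inherits(system, "charge_system"), inherits(params, "pb_params"))
  at <- system$atoms
  if (!nrow(at)) .stopf("empty charge system")
  xyz <- .coords_mat(system)
  margin <- if (params$dielectric_model == "gaussian")
    3 * params$sigma * at$radius else at$radius
  lo <- apply(xyz - margin, 2L, min)
  hi <- apply(xyz + margin, 2L, max)
  extent <- max(hi - lo)

  h <- 1 / params$scale
  if (!is.null(geometry)) {
    n <- geometry$n; h <- geometry$h; origin <- geometry$origin
    edge <- (n - 1) * h
  } else {
    if (!is.null(params$grid_points)) {
      n <- as.integer(params$grid_points)
      edge <- (n - 1) * h
    } else {
      if (is.null(edge)) edge <- extent / params$fill_ratio
      n <- as.integer(ceiling(edge / h)) + 1L
      edge <- (n - 1) * h
    }
    if (is.null(center)) center <- (lo + hi) / 2
    origin <- center - edge / 2
  }
  if (n < 9L) .stopf("grid has only %d nodes per axis; enlarge the box", n)

  box_lo <- origin; box_hi <- origin + edge
  bad <- which(apply(xyz - margin, 1L, function(v) any(v < box_lo)) |
                 apply(xyz + margin, 1L, function(v) any(v > box_hi)))
  if (length(bad))
    .stopf("box too small: atom %d plus its density margin extends outside the grid",
           bad[1])

  ax <- lapply(1:3, function(d) origin[d] + (0:(n - 1)) * h)

  mix <- function(rho) rho * params$eps_in + (1 - rho) * params$eps_out
  rho <- .density_grid(at, xyz, params, ax[[1]], ax[[2]], ax[[3]])
  eps <- mix(rho)
  # face dielectric = harmonic average of eps sampled along the edge
  # (flux continuity across the interface; exact for a 1-D interface)
  ns_edge <- 8L
  face_eps <- function(axis) {
    inv <- 0
    for (o in (seq_len(ns_edge) - 0.5) / ns_edge * h) {
      a <- ax
      a[[axis]] <- a[[axis]] + o
      inv <- inv + 1 / mix(.density_grid(at, xyz, params, a[[1]], a[[2]],
                                         a[[3]]))
    }
    ns_edge / inv
  }
  epsx <- face_eps(1L)
  epsy <- face_eps(2L)
  epsz <- face_eps(3L)

  K <- .screening_K(params$ionic_strength, params$temperature)
  kdiag <- array(0, c(n, n, n))
  if (K > 0) kdiag[rho <= params$rho_cut] <- K * h^2

  # trilinear charge spreading
  qgrid <- array(0, c(n, n, n))
  for (i in seq_len(nrow(at))) {
    fx <- (xyz[i, ] - origin) / h
    i0 <- floor(fx)
    if (any(i0 < 1) || any(i0 > n - 3))
      .stopf("atom %d too close to the box boundary for charge spreading", i)
    w <- fx - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      ii <- i0 + c(dx, dy, dz) + 1L  # to 1-based
      qgrid[ii[1], ii[2], ii[3]] <- qgrid[ii[1], ii[2], ii[3]] + at$q[i] * wt
    }
  }

  structure(list(n = n, h = h, origin = origin, eps = eps,
                 epsx = epsx, epsy = epsy, epsz = epsz, kdiag = kdiag,
                 qgrid = qgrid, solute_extent = extent,
                 box_occupancy = extent / edge,
                 total_charge = sum(at$q), params = params),
            class = "dielectric_grid")
}

#' @export
print.dielectric_grid <- function(x, ...) {
  cat(sprintf(
    "<dielectric_grid> %d^3 nodes, h=%.3f A, eps in [%.2f, %.2f], Q=%+.3f e, box occupancy %.0f%%\n",
    x$n, x$h, min(x$eps), max(x$eps), x$total_charge, 100 * x$box_occupancy))
  invisible(x)
}

.grid_geometry <- function(grid) list(n = grid$n, h = grid$h,
                                      origin = grid$origin)

.geometry_equal <- function(a, b) {
  isTRUE(all.equal(a$n, b$n)) && isTRUE(all.equal(a$h, b$h)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-10))
}
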