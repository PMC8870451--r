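# Linear PB solve, grid energies, trilinear interpolation, OpenDX export.

#' Solve the linear Poisson-Boltzmann equation on a built grid
#'
#' Discretizes `div(eps grad phi) - eps_out kappa^2 phi = -4 pi C rho` on
#' the 7-point stencil with face-midpoint dielectrics and solves it by
#' Jacobi-preconditioned conjugate gradient. Boundary values are the sum of
#' Debye-Hueckel-screened monopole potentials of all charges (Dirichlet).
#' Potentials are in kT/e.
#'
#' @param grid a [build_grids()] result.
#' @param params a [pb_params()]; defaults to the parameters the grid was
#'   built with.
#' @return object of class `potential_grid`: list with `phi`
#'   (`n x n x n` array, kT/e), `n`, `h`, `origin`, `iterations`, `relres`.
#' @export
solve_lpb <- function(grid, params = grid$params) {
  stopifnot(inherits(grid, "dielectric_grid"))
  if (!(params$tol > 0)) .stopf("solver tolerance must be > 0")
  n <- grid$n; h <- grid$h
  C <- coulomb_const(params$temperature)
  K <- .screening_K(params$ionic_strength, params$temperature)
  kappa <- sqrt(K / params$eps_out)

  phi0 <- array(0, c(n, n, n))
  qidx <- which(grid$qgrid != 0, arr.ind = TRUE)
  if (nrow(qidx)) {
    qpos <- sweep((qidx - 1) * h, 2L, grid$origin, `+`)
    qval <- grid$qgrid[qidx]
    bmask <- array(FALSE, c(n, n, n))
    bmask[c(1, n), , ] <- TRUE; bmask[, c(1, n), ] <- TRUE
    bmask[, , c(1, n)] <- TRUE
    bidx <- which(bmask, arr.ind = TRUE)
    bpos <- sweep((bidx - 1) * h, 2L, grid$origin, `+`)
    phi0[bidx] <- dh_boundary(bpos, qpos, qval, C, params$eps_out, kappa)
  }

  rhs <- 4 * pi * C * grid$qgrid / h
  sol <- pb_cg_solve(c(n, n, n), as.numeric(grid$epsx),
                     as.numeric(grid$epsy), as.numeric(grid$epsz),
                     as.numeric(grid$kdiag), as.numeric(rhs),
                     as.numeric(phi0), params$tol, params$maxit)
  if (!sol$converged)
    .stopf("PB solver did not converge in %d iterations (relative residual %.3g)",
           sol$iterations, sol$relres)
  structure(list(phi = array(sol$phi, c(n, n, n)), n = n, h = h,
                 origin = grid$origin, iterations = sol$iterations,
                 relres = sol$relres),
            class = "potential_grid")
}

#' Total grid energy
#'
#' One half the sum over nodes of the node charge times the node potential,
#' in kT. Differences of grid energies between runs on node-for-node
#' identical grids cancel the lattice self-energy.
#'
#' @param potential a [solve_lpb()] result.
#' @param grid the [build_grids()] result the potential was solved on.
#' @return energy in kT.
#' @export
grid_energy <- function(potential, grid) {
  stopifnot(inherits(potential, "potential_grid"),
            inherits(grid, "dielectric_grid"))
  if (!.geometry_equal(.grid_geometry(grid),
                       list(n = potential$n, h = potential$h,
                            origin = potential$origin)))
    .stopf("potential and charge grids have different geometry")
  0.5 * sum(grid$qgrid * potential$phi)
}

#' Trilinear interpolation of a potential grid
#'
#' @param potential a `potential_grid`.
#' @param points `m x 3` matrix of coordinates (Angstrom).
#' @return numeric vector of interpolated potentials (kT/e).
#' @export
grid_interpolate <- function(potential, points) {
  points <- rbind(points)
  n <- potential$n; h <- potential$h
  vapply(seq_len(nrow(points)), function(p) {
    fx <- (points[p, ] - potential$origin) / h
    i0 <- pmin(pmax(floor(fx), 0), n - 2)
    w <- fx - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      acc <- acc + wt * potential$phi[i0[1] + dx + 1, i0[2] + dy + 1,
                                      i0[3] + dz + 1]
    }
    acc
  }, 0)
}

#' Export a potential grid as an OpenDX scalar field
#'
#' @param potential a `potential_grid`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_dx <- function(potential, path) {
  n <- potential$n
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n, n, n),
    sprintf("origin %.6f %.6f %.6f", potential$origin[1],
            potential$origin[2], potential$origin[3]),
    sprintf("delta %.6f 0 0", potential$h),
    sprintf("delta 0 %.6f 0", potential$h),
    sprintf("delta 0 0 %.6f", potential$h),
    sprintf("object 2 class gridconnections counts %d %d %d", n, n, n),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n^3)), con)
  # DX order: z fastest
  vals <- aperm(potential$phi, c(3, 2, 1))
  v <- as.numeric(vals)
  pad <- (-length(v)) %% 3
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1L, function(r)
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
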