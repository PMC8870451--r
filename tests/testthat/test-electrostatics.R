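# PB grids, solver oracles (small grids; deeper refinement checks live in
# the acceptance suite), Eq-style binding energies, aggregation, pKa.

fast_par <- function(...) pb_params(scale = 1.2, grid_points = 33,
                                    ionic_strength = 0, ...)

test_that("Gaussian dielectric field matches pointwise evaluation", {
  sys <- charge_system(data.frame(x = c(0, 1.5), y = 0, z = 0, q = c(1, -1),
                                  radius = c(1.8, 1.6)))
  par <- fast_par()
  g <- build_grids(sys, par, center = c(0, 0, 0))  # puts a node on atom 1
  # eps bounded and approaching eps_out far away
  expect_true(all(g$eps >= par$eps_in - 1e-9 & g$eps <= par$eps_out + 1e-9))
  corner <- g$eps[1, 1, 1]
  expect_lt(abs(corner - par$eps_out), 1e-6)
  # node on an atom center: rho = 1 -> eps = eps_in
  idx <- round((c(0, 0, 0) - g$origin) / g$h) + 1
  expect_equal(g$eps[idx[1], idx[2], idx[3]], par$eps_in)
  # two overlapping atoms: rho = 1 - (1 - g1)(1 - g2) at a probe node
  probe_i <- idx + c(1L, 0L, 0L)
  p <- g$origin + (probe_i - 1) * g$h
  g1 <- exp(-sum((p - c(0, 0, 0))^2) / (par$sigma^2 * 1.8^2))
  g2 <- exp(-sum((p - c(1.5, 0, 0))^2) / (par$sigma^2 * 1.6^2))
  rho <- 1 - (1 - g1) * (1 - g2)
  expect_equal(g$eps[probe_i[1], probe_i[2], probe_i[3]],
               rho * par$eps_in + (1 - rho) * par$eps_out, tolerance = 1e-10)
})

test_that("charge spreading conserves total charge; box validation works", {
  sys <- charge_system(data.frame(x = c(0.3, -1.2), y = c(0.7, 0.2),
                                  z = c(-0.5, 1.1), q = c(0.62, -1.4),
                                  radius = 1.5))
  g <- build_grids(sys, fast_par())
  expect_lt(abs(sum(g$qgrid) - sum(sys$atoms$q)), 1e-10)
  par_small <- pb_params(scale = 1.2, grid_points = 9, ionic_strength = 0)
  expect_error(build_grids(sys, par_small), "box too small")
})

test_that("zero charges give an identically zero potential", {
  sys <- charge_system(data.frame(x = 0, y = 0, z = 0, q = 0, radius = 1.5))
  par <- fast_par()
  g <- build_grids(sys, par)
  pot <- solve_lpb(g, par)
  expect_equal(max(abs(pot$phi)), 0)
  expect_equal(grid_energy(pot, g), 0)
})

test_that("linear PB superposition holds to solver tolerance", {
  par <- pb_params(eps_in = 80, eps_out = 80, scale = 1.5, grid_points = 41,
                   ionic_strength = 0.15, tol = 1e-8)
  mk <- function(q1, q2) charge_system(data.frame(
    x = c(-2, 2), y = 0, z = 0, q = c(q1, q2), radius = 1.5))
  geom_src <- build_grids(mk(1, 1), par, center = c(0, 0, 0))
  geom <- ionpocket:::.grid_geometry(geom_src)
  solve_one <- function(q1, q2) {
    g <- build_grids(mk(q1, q2), par, geometry = geom)
    solve_lpb(g, par)$phi
  }
  both <- solve_one(1, -0.5)
  a <- solve_one(1, 0)
  b <- solve_one(0, -0.5)
  expect_lt(max(abs(both - (a + b))), 1e-4 * max(abs(both)))
  # scaling linearity
  twice <- solve_one(2, -1)
  expect_lt(max(abs(twice - 2 * both)), 1e-4 * max(abs(twice)))
})

test_that("identical runs give identical grid energies", {
  sys <- gen_charge_system("dipole", q = 0.8, sep = 2.4)
  par <- fast_par()
  g1 <- build_grids(sys, par); g2 <- build_grids(sys, par)
  expect_identical(grid_energy(solve_lpb(g1, par), g1),
                   grid_energy(solve_lpb(g2, par), g2))
})

test_that("grid-energy difference formula and its guards", {
  expect_equal(binding_energy_from_grid(10, 6, 1), 3)
  # mismatched partition is rejected
  rec <- charge_system(data.frame(x = 0, y = 0, z = 0, q = -1, radius = 1.7))
  ion <- charge_system(data.frame(x = 2.1, y = 0, z = 0, q = 1, radius = 1.2))
  ion_moved <- charge_system(data.frame(x = 2.2, y = 0, z = 0, q = 1,
                                        radius = 1.2))
  cplx <- charge_system(rbind(rec$atoms, ion$atoms))
  expect_error(binding_energy(cplx, rec, ion_moved, fast_par()),
               "atom-for-atom")
  # attractive ion adjacent to a -1e pocket: dG < 0
  be <- binding_energy(cplx, rec, ion, fast_par())
  expect_lt(be$dG, 0)
  # translation invariance when the grid translates with the complex
  shift <- c(4.1, -2.3, 1.7)
  shift_sys <- function(s) {
    a <- s$atoms; a$x <- a$x + shift[1]; a$y <- a$y + shift[2]
    a$z <- a$z + shift[3]; charge_system(a)
  }
  be2 <- binding_energy(shift_sys(cplx), shift_sys(rec), shift_sys(ion),
                        fast_par())
  expect_equal(be2$dG, be$dG, tolerance = 1e-6)
})

test_that("aggregate_binding: boxplot stats, R^2 oracle, occupancy warning", {
  snaps <- data.frame(traj = rep(1:3, each = 4), dG = rep(-3, 12))
  rep0 <- aggregate_binding(snaps)
  expect_equal(rep0$stats$median, -3)
  expect_equal(rep0$stats$q3 - rep0$stats$q1, 0)
  expect_true(is.na(rep0$r2))  # no coordination supplied

  # exact line -> R^2 = 1
  coord <- data.frame(traj = 1:3, mean_first_protein = c(1, 2, 3))
  snaps2 <- data.frame(traj = rep(1:3, each = 2),
                       dG = rep(c(-1, -2, -3), each = 2))
  expect_equal(aggregate_binding(snaps2, coord)$r2, 1)

  # planted pairs vs normal-equations oracle
  set.seed(5)
  x <- c(1.2, 1.9, 2.7, 3.1, 3.8)
  y <- -0.8 * x + rnorm(5, 0, 0.3)
  snaps3 <- data.frame(traj = 1:5, dG = y)
  coord3 <- data.frame(traj = 1:5, mean_first_protein = x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2_oracle <- 1 - sum(res^2) / sum((y - mean(y))^2)
  expect_equal(aggregate_binding(snaps3, coord3)$r2, r2_oracle,
               tolerance = 1e-12)

  expect_warning(aggregate_binding(snaps, box_occupancy = c(0.5, 0.75)),
                 "70%")
  # single trajectory: correlation omitted
  expect_true(is.na(aggregate_binding(
    data.frame(traj = 1, dG = -2),
    data.frame(traj = 1, mean_first_protein = 2))$r2))
})

test_that("snapshot selection follows the equidistant protocol", {
  times <- seq(0, 280, by = 0.5)
  idx <- select_snapshots(times, step = 8, count = 35)
  expect_length(idx, 35)
  expect_equal(times[idx], seq(0, by = 8, length.out = 35))
  expect_error(select_snapshots(seq(0, 100, 1), step = 8, count = 35),
               "too short")
})

test_that("pKa shift arithmetic and degenerate protocols", {
  # zero shift on all frames -> model pKa, sd 0
  pk <- pka_from_shifts(rep(0, 7), 4.0)
  expect_equal(pk$pka, 4.0); expect_equal(pk$sd, 0)
  # +2.303 kT destabilization of the anion -> +1 pK unit
  pk1 <- pka_from_shifts(rep(log(10), 7), 4.0)
  expect_equal(pk1$pka, 5.0, tolerance = 1e-6)
  # frames {0, +1, -1} pK units -> mean model, sd 1
  pk2 <- pka_from_shifts(c(0, log(10), -log(10)), 4.0)
  expect_equal(pk2$pka, 4.0)
  expect_equal(pk2$sd, 1)
  # base flips the sign
  pkb <- pka_from_shifts(rep(log(10), 3), 6.3, acid = FALSE)
  expect_equal(pkb$pka, 5.3, tolerance = 1e-6)
})

test_that("full pKa protocol: isolated model compound returns pKa_model", {
  par <- fast_par()
  mk_state <- function(q) charge_system(data.frame(
    x = c(0, 1.4), y = 0, z = 0, q = c(q, 0.1), radius = c(1.6, 1.4)))
  frame <- list(protein_charged = mk_state(-1),
                protein_neutral = mk_state(0),
                model_charged = mk_state(-1),
                model_neutral = mk_state(0))
  pk <- pka(list(frame, frame), pka_model = 4.0, params = par)
  expect_equal(pk$pka, 4.0)
  expect_equal(pk$sd, 0)
  expect_error(pka(list(frame[-1]), 4.0, par), "missing state")
})
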