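# Coordination shells: rule examples, oracle equivalence, summary tables.

make_manual_traj <- function(positions, roles,
                             names = paste0("A", seq_along(roles))) {
  atoms <- data.frame(id = seq_along(roles), name = names,
                      resname = "X", resid = seq_along(roles), role = roles)
  coords <- array(as.numeric(positions), c(length(roles), 3, 1))
  trajectory(atoms, coords, times = 1)
}

test_that("assign_shells implements the compound distance/bridge rules", {
  # ligand at 2.5 A -> first shell
  tr <- make_manual_traj(rbind(c(0, 0, 0), c(2.5, 0, 0)),
                         c("ion", "protein_ligand"))
  sa <- assign_shells(tr)
  expect_identical(sa$first_protein[[1]], 2L)
  expect_length(sa$second_protein[[1]], 0)

  # ligand at 4.0 A with a bridging water (2.8 from ion, ~2.9 from ligand)
  tr <- make_manual_traj(rbind(c(0, 0, 0), c(4, 0, 0), c(1.2, 0.9, 0)),
                         c("ion", "protein_ligand", "water_oxygen"))
  dw <- sqrt(sum(c(1.2, 0.9, 0)^2))
  dlig <- sqrt(sum((c(4, 0, 0) - c(1.2, 0.9, 0))^2))
  expect_lt(dw, 3); expect_lt(dlig, 3)
  sa <- assign_shells(tr)
  expect_identical(sa$second_protein[[1]], 2L)
  expect_identical(sa$first_water[[1]], 3L)

  # ligand at 4.0 A whose nearest first-shell water is > 3 A away from it
  tr <- make_manual_traj(rbind(c(0, 0, 0), c(4, 0, 0), c(-2.5, 0, 0)),
                         c("ion", "protein_ligand", "water_oxygen"))
  sa <- assign_shells(tr)
  expect_length(sa$first_protein[[1]], 0)
  expect_length(sa$second_protein[[1]], 0)

  # water between 3 and 6 A -> second shell water
  tr <- make_manual_traj(rbind(c(0, 0, 0), c(0, 4.5, 0)),
                         c("ion", "water_oxygen"))
  expect_identical(assign_shells(tr)$second_water[[1]], 2L)
})

test_that("missing ion or roles are rejected by name", {
  atoms <- data.frame(id = 1:2, name = c("a", "b"), resname = "X",
                      resid = 1:2, role = c("protein_ligand", "water_oxygen"))
  tr <- trajectory(atoms, array(0, c(2, 3, 1)), times = 1)
  expect_error(assign_shells(tr), "exactly one atom with role 'ion'")
  atoms2 <- data.frame(id = 1, name = "NA+", resname = "SOD", resid = 1,
                       role = "ion")
  tr2 <- trajectory(atoms2, array(0, c(1, 3, 1)), times = 1)
  expect_error(assign_shells(tr2), "protein_ligand")
})

test_that("assign_shells equals the brute-force oracle on random fixtures", {
  for (seed in c(11, 23, 57, 101)) {
    out <- gen_site_trajectory(random_site_spec(seed, n_frames = 30))
    sa <- assign_shells(out$trajectory)
    expect_shells_equal(sa, brute_force_shells(out$trajectory))
  }
})

test_that("first-shell membership implies total; occupancy totals dominate", {
  out <- gen_site_trajectory(random_site_spec(7, n_frames = 60))
  sa <- assign_shells(out$trajectory)
  for (f in seq_along(sa$first_protein))
    expect_length(intersect(sa$first_protein[[f]], sa$second_protein[[f]]), 0)
  occ <- occupancy_table(sa)
  wide <- merge(occ[occ$shell == "first", c("ligand", "occupancy")],
                occ[occ$shell == "total", c("ligand", "occupancy")],
                by = "ligand", suffixes = c("_first", "_total"))
  expect_true(all(wide$occupancy_total >= wide$occupancy_first))
})

test_that("occupancy and coordination are permutation-invariant in frame order", {
  out <- gen_site_trajectory(random_site_spec(13, n_frames = 40))
  tr <- out$trajectory
  perm <- rev(seq_len(length(tr$times)))
  tr2 <- trajectory(tr$atoms, tr$coords[, , perm, drop = FALSE],
                    times = sort(tr$times), replica = tr$replica)
  o1 <- occupancy_table(assign_shells(tr))
  o2 <- occupancy_table(assign_shells(tr2))
  expect_equal(o1, o2)
})

test_that("coordination_counts pools replicas with the SEM formula", {
  # three replicas with constant per-frame first-shell protein counts 2,3,4
  reps <- lapply(c(2, 3, 4), function(k) {
    labels <- paste0("L", 1:4)
    sched <- c(rep("first", k), rep("none", 4 - k))
    spec <- site_trajectory_spec(20, ligand_atoms = data.frame(
      label = labels, nominal = c(2.3, 2.4, 2.5, 2.6)),
      shell_schedule = setNames(lapply(sched, rep, 20), labels),
      noise_sd = 0, seed = k)
    assign_shells(gen_site_trajectory(spec)$trajectory)
  })
  cc <- coordination_counts(reps)
  pf <- cc[cc$species == "protein" & cc$shell == "first", ]
  expect_equal(pf$mean, 3)
  expect_equal(pf$sem, sd(c(2, 3, 4)) / sqrt(3))

  # constant 3 ligands in first shell -> SEM exactly 0
  reps3 <- lapply(1:3, function(s) {
    spec <- site_trajectory_spec(10, ligand_atoms = data.frame(
      label = paste0("L", 1:3), nominal = c(2.3, 2.4, 2.5)),
      noise_sd = 0, seed = s)
    assign_shells(gen_site_trajectory(spec)$trajectory)
  })
  cc3 <- coordination_counts(reps3)
  pf3 <- cc3[cc3$species == "protein" & cc3$shell == "first", ]
  expect_equal(pf3$mean, 3); expect_equal(pf3$sem, 0)

  # single replica: dispersion undefined, not zero
  expect_true(is.na(coordination_counts(reps[1])$sem[1]))
})

test_that("occupancy_table recovers planted 60/80 percent occupancy", {
  sched <- list(L1 = rep(c("first", "second", "none"), c(60, 20, 20)))
  spec <- site_trajectory_spec(100, ligand_atoms = data.frame(
    label = "L1", nominal = 2.5), shell_schedule = sched,
    noise_sd = 0, seed = 3)
  occ <- occupancy_table(assign_shells(gen_site_trajectory(spec)$trajectory))
  expect_equal(occ$occupancy[occ$shell == "first"], 60)
  expect_equal(occ$occupancy[occ$shell == "total"], 80)
})
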