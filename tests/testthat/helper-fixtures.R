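# Shared fixture builders and independent oracles.

# Exhaustive per-frame re-check of the shell rules, written as plain loops
# independent of assign_shells' vectorized path.
brute_force_shells <- function(traj, params = analysis_params()) {
  at <- traj$atoms
  ion <- which(at$role == "ion")
  nf <- length(traj$times)
  res <- list(first_protein = vector("list", nf),
              first_water = vector("list", nf),
              second_protein = vector("list", nf),
              second_water = vector("list", nf))
  for (f in seq_len(nf)) {
    fr <- traj$coords[, , f]
    dist <- function(i, j) sqrt(sum((fr[i, ] - fr[j, ])^2))
    fp <- integer(0); fw <- integer(0); sp <- integer(0); sw <- integer(0)
    for (i in seq_len(nrow(at))) {
      if (i == ion) next
      d <- dist(ion, i)
      if (at$role[i] == "protein_ligand") {
        if (d <= params$first_shell_protein) fp <- c(fp, i)
      } else if (at$role[i] == "water_oxygen") {
        if (d <= params$first_shell_water) fw <- c(fw, i)
        else if (d <= params$second_shell) sw <- c(sw, i)
      }
    }
    for (i in seq_len(nrow(at))) {
      if (at$role[i] != "protein_ligand") next
      d <- dist(ion, i)
      if (d > params$first_shell_protein && d <= params$second_shell) {
        bridged <- FALSE
        for (w in fw) if (dist(i, w) <= params$bridge_water) bridged <- TRUE
        if (bridged) sp <- c(sp, i)
      }
    }
    res$first_protein[[f]] <- sort(at$id[fp])
    res$first_water[[f]] <- sort(at$id[fw])
    res$second_protein[[f]] <- sort(at$id[sp])
    res$second_water[[f]] <- sort(at$id[sw])
  }
  res
}

expect_shells_equal <- function(sa, oracle) {
  for (field in c("first_protein", "first_water", "second_protein",
                  "second_water")) {
    got <- lapply(sa[[field]], sort)
    expect_identical(got, oracle[[field]], label = field)
  }
}

# random planted spec for property-style tests
random_site_spec <- function(seed, n_frames = 50, max_ligands = 6) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    nl <- sample(2:max_ligands, 1)
    labels <- paste0("L", seq_len(nl))
    sched <- lapply(seq_len(nl), function(i)
      sample(c("first", "second", "none"), n_frames, replace = TRUE,
             prob = c(0.4, 0.4, 0.2)))
    names(sched) <- labels
    site_trajectory_spec(
      n_frames = n_frames,
      ligand_atoms = data.frame(label = labels,
                                nominal = runif(nl, 2.2, 2.6)),
      shell_schedule = sched,
      water_count = sample(0:3, 1),
      noise_sd = sample(c(0, 0.03, 0.05), 1),
      seed = seed)
  })
}

# additive distance matrix from a tree, with tip order possibly shuffled
tree_distance <- function(newick) {
  tr <- ape::read.tree(text = newick)
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, D = D[tr$tip.label, tr$tip.label])
}
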