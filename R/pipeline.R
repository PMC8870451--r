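# End-to-end orchestration from a JSON config.

.default_config <- function() {
  list(
    outdir = "ionpocket_out",
    seed = 1L,
    stages = c("simulate", "shells", "rotamers", "hbonds", "amd",
               "pb_bind", "phylo"),
    analysis = list(),
    pb = list(grid_points = 33, scale = 1.2, ionic_strength = 0.15),
    trajectory = list(n_replicas = 3L, n_frames = 60L, frame_interval = 1,
                      noise_sd = 0.03),
    amd = list(mean = c(500, -50000), sd = c(10, 200), n = 1300L, dt = 0.1,
               window = c(20, 120), lambda = 0.3, n_atoms = 10000L),
    pb_bind = list(snapshots_per_traj = 3L),
    phylo = list(n_reps = 50L, threshold = 0.90))
}

#' Validate and normalize a pipeline configuration
#'
#' @param config a named list or a path to a JSON config file; omitted keys
#'   take the demo defaults. Unknown keys are rejected by name.
#' @return the merged config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  defaults <- .default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      sub_unknown <- setdiff(names(config[[nm]]),
                             c(names(defaults[[nm]]),
                               if (nm == "pb") names(pb_params()),
                               if (nm == "analysis") names(analysis_params())))
      if (length(sub_unknown))
        .stopf("unknown config key(s) in '%s': %s", nm,
               paste(sub_unknown, collapse = ", "))
      defaults[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]])
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  if (is.null(defaults$seed)) .stopf("config must give an explicit seed")
  defaults
}

# deterministic per-replica demo trajectory specs: coordination of the
# N7.46-like ligand decreases across replicas to drive the dG correlation
.demo_traj_spec <- function(cfg, replica, seed) {
  tc <- cfg$trajectory
  nf <- as.integer(tc$n_frames)
  frac746 <- c(0.9, 0.6, 0.3, 0.8, 0.5, 0.4)[1 + (replica - 1) %% 6]
  n1 <- round(frac746 * nf)
  sched_746 <- rep(c("first", "second"), c(n1, nf - n1))
  chi <- rep("trans", nf)
  chi[seq_len(nf) %% 7 == 0] <- "g+"
  hb <- list("D2.50-N3.35" = seq_len(nf) %% 5 != 0,
             "N7.46-N3.35" = seq_len(nf) %% 2 == 0)
  site_trajectory_spec(
    n_frames = nf, frame_interval = tc$frame_interval,
    ligand_atoms = data.frame(
      label = c("D2.50_OD1", "D2.50_OD2", "N7.46_OD1", "S3.39_OG",
                "N3.35_OD1"),
      nominal = c(2.3, 2.5, 2.5, 4.5, 7.5)),
    shell_schedule = list(
      "D2.50_OD1" = rep("first", nf),
      "D2.50_OD2" = rep("first", nf),
      "N7.46_OD1" = sched_746,
      "S3.39_OG" = rep("second", nf),
      "N3.35_OD1" = rep("none", nf)),
    chi_schedule = chi, hbond_schedule = hb,
    noise_sd = tc$noise_sd, seed = seed)
}

.demo_phylo_tree <-
  "(((fish1:0.05,fish2:0.05):0.15,(fish3:0.06,fish4:0.06):0.14):0.1,((amni1:0.05,amni2:0.05):0.15,(amni3:0.06,amni4:0.06):0.14):0.1);"

#' Run the full analysis pipeline from a config
#'
#' Executes the requested stages in dependency order (simulate ->
#' shells/rotamers/hbonds -> aMD parameters -> PB binding energies ->
#' aggregation -> phylogenetics), writing CSV/JSON reports plus a run log
#' with every parameter and seed into `config$outdir`. Reruns with the same
#' config and seed produce byte-identical numeric reports (the run log
#' carries the only timestamp). A stage failure aborts downstream stages.
#'
#' @param config a named list or JSON path (see [validate_config()]).
#' @return invisibly, a list with the in-memory stage results and the
#'   output directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outdir, "run_log.txt")
  cat(sprintf("ionpocket pipeline run\nstarted: %s\nseed: %d\n\nconfig:\n%s\n",
              format(Sys.time()), cfg$seed,
              jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE)),
      file = log)
  stage_seeds <- with_seed(cfg$seed,
                           setNames(sample.int(2^31 - 1, 8),
                                    c("simulate", "amd", "pb_bind", "phylo",
                                      "s5", "s6", "s7", "s8")))
  say <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                file = log, append = TRUE)
  res <- list(outdir = outdir)
  stages <- cfg$stages
  apar <- do.call(analysis_params, cfg$analysis)
  jsonout <- function(x, f) jsonlite::write_json(
    x, file.path(outdir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if ("simulate" %in% stages) {
    reps <- lapply(seq_len(cfg$trajectory$n_replicas), function(r) {
      spec <- .demo_traj_spec(cfg, r, seed = stage_seeds[["simulate"]] + r)
      out <- gen_site_trajectory(spec)
      out$trajectory$replica <- r
      out
    })
    res$trajectories <- lapply(reps, `[[`, "trajectory")
    res$truths <- lapply(reps, `[[`, "truth")
    write_trajectory_pdb(res$trajectories[[1]],
                         file.path(outdir, "replica1_topology.pdb"),
                         file.path(outdir, "replica1_frames.pdb"))
    say("simulate: %d replicas x %d frames", length(reps),
        n_frames(res$trajectories[[1]]))
  }

  if ("shells" %in% stages) {
    if (is.null(res$trajectories)) .stopf("stage 'shells' requires 'simulate'")
    res$assignments <- lapply(res$trajectories, assign_shells, params = apar)
    occ <- occupancy_table(res$assignments)
    cc <- coordination_counts(res$assignments)
    write.csv(occ, file.path(outdir, "occupancy.csv"), row.names = FALSE)
    write.csv(cc, file.path(outdir, "coordination.csv"), row.names = FALSE)
    res$occupancy <- occ; res$coordination <- cc
    say("shells: occupancy and coordination tables written")
  }

  if ("rotamers" %in% stages) {
    if (is.null(res$trajectories)) .stopf("stage 'rotamers' requires 'simulate'")
    res$chi <- lapply(seq_along(res$trajectories), function(r)
      classify_rotamer(res$trajectories[[r]], res$truths[[r]]$chi_atom_ids))
    fr <- do.call(rbind, lapply(seq_along(res$chi), function(r)
      data.frame(replica = r, state = names(rotamer_fractions(res$chi[[r]])),
                 fraction = as.numeric(rotamer_fractions(res$chi[[r]])))))
    write.csv(fr, file.path(outdir, "chi_fractions.csv"), row.names = FALSE)
    say("rotamers: chi1 fractions written")
  }

  if ("hbonds" %in% stages) {
    if (is.null(res$chi)) .stopf("stage 'hbonds' requires 'rotamers'")
    t1 <- res$truths[[1]]
    pairs <- data.frame(
      pair = names(t1$hbond_atom_ids),
      donor = vapply(t1$hbond_atom_ids, `[`, 0L, 1L),
      hydrogen = vapply(t1$hbond_atom_ids, `[`, 0L, 2L),
      acceptor = vapply(t1$hbond_atom_ids, `[`, 0L, 3L))
    hb <- hbond_occupancy(res$trajectories, pairs, params = apar,
                          filter_on = res$chi)
    write.csv(as.data.frame(hb), file.path(outdir, "hbond.csv"),
              row.names = FALSE)
    res$hbond <- hb
    say("hbonds: %d pair(s), %d replica(s) retained", nrow(hb),
        hb$n_replicas_used[1])
  }

  if ("amd" %in% stages) {
    ac <- cfg$amd
    es <- gen_energy_series(ac$mean, ac$sd, n = ac$n, dt = ac$dt,
                            seed = stage_seeds[["amd"]])
    write.csv(es, file.path(outdir, "energy_series.csv"), row.names = FALSE)
    bp <- boost_params(es, window = ac$window, lambda = ac$lambda,
                       n_atoms = ac$n_atoms)
    write_boost_params(bp, json_path = file.path(outdir, "boost_params.json"),
                       snippet_path = file.path(outdir, "boost_params.namd"))
    res$boost <- bp
    say("amd: alpha_dihed=%.4f alpha_pot=%.1f", bp$alpha_dihed, bp$alpha_pot)
  }

  if ("pb_bind" %in% stages) {
    if (is.null(res$assignments)) .stopf("stage 'pb_bind' requires 'shells'")
    ppar <- do.call(pb_params, cfg$pb)
    per_cc <- lapply(res$assignments, coordination_counts)
    coord <- data.frame(
      traj = seq_along(res$assignments),
      mean_first_protein = vapply(per_cc, function(x)
        x$mean[x$species == "protein" & x$shell == "first"], 0))
    snap_seeds <- with_seed(stage_seeds[["pb_bind"]],
                            sample.int(2^31 - 1, nrow(coord)))
    snaps <- do.call(rbind, lapply(seq_len(nrow(coord)), function(tr) {
      qrec <- -0.35 - 0.12 * coord$mean_first_protein[tr]
      jit <- with_seed(snap_seeds[tr],
                       matrix(runif(3 * cfg$pb_bind$snapshots_per_traj,
                                    -0.2, 0.2), ncol = 3))
      dg <- vapply(seq_len(cfg$pb_bind$snapshots_per_traj), function(s) {
        ionpos <- c(0, 0, 0) + jit[s, ]
        rec <- charge_system(data.frame(
          x = c(2.2, -2.2), y = c(0, 0), z = c(0, 0),
          q = c(qrec, qrec / 2), radius = 1.7))
        ion <- charge_system(data.frame(x = ionpos[1], y = ionpos[2],
                                        z = ionpos[3], q = 1, radius = 1.2))
        cplx <- charge_system(rbind(rec$atoms, ion$atoms))
        binding_energy(cplx, rec, ion, ppar)$dG
      }, 0)
      data.frame(traj = tr, snapshot = seq_along(dg), dG = dg)
    }))
    write.csv(snaps, file.path(outdir, "binding_snapshots.csv"),
              row.names = FALSE)
    rep_ <- aggregate_binding(snaps, coord)
    jsonout(list(stats = rep_$stats, r2 = rep_$r2,
                 per_trajectory = rep_$per_trajectory),
            "binding_report.json")
    res$binding <- rep_
    say("pb_bind: median dG %.3f kT, R^2 %.3f", rep_$stats$median, rep_$r2)
  }

  if ("phylo" %in% stages) {
    pc <- cfg$phylo
    clades <- setNames(rep(c("fish", "amniota"), each = 4),
                       c(paste0("fish", 1:4), paste0("amni", 1:4)))
    root <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 3), collapse = "")
    spec <- sequence_evolution_spec(
      .demo_phylo_tree, root_sequence = root,
      marked_columns = c("7.46" = 30L),
      clade_overrides = list(list(label = "7.46",
                                  taxa = paste0("amni", 1:4),
                                  residue = "N"),
                             list(label = "7.46",
                                  taxa = paste0("fish", 1:4),
                                  residue = "S")),
      clade = clades, seed = stage_seeds[["phylo"]])
    fam <- gen_sequence_family(spec)
    write_fasta_alignment(fam$alignment, file.path(outdir, "family.fasta"))
    idm <- pairwise_identity(fam$alignment)
    write.csv(round(unclass(idm), 6), file.path(outdir, "identity.csv"))
    cl <- greedy_cluster(fam$alignment, idm, threshold = pc$threshold)
    write_clusters_tsv(cl, file.path(outdir, "clusters.tsv"))
    bs <- bootstrap_support(fam$alignment, n_reps = pc$n_reps,
                            seed = stage_seeds[["phylo"]] + 1L)
    ape::write.tree(bs$tree, file.path(outdir, "tree.nwk"))
    pat <- position_patterns(fam$alignment, "fish1",
                             anchors = c("7.46" = 30L))
    write.csv(pat$table, file.path(outdir, "patterns.csv"),
              row.names = FALSE)
    res$phylo <- list(clusters = cl, bootstrap = bs, patterns = pat)
    say("phylo: %d clusters, tree with %d internal nodes",
        length(cl$clusters), bs$tree$Nnode)
  }

  say("done")
  invisible(res)
}
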