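# Synthetic ion-binding-site trajectories with exact, planted ground truth.

#' Specification of a synthetic ion-binding-site trajectory
#'
#' Describes a toy sodium pocket: one ion, a set of electronegative protein
#' ligand atoms whose coordination-shell membership is planted frame by
#' frame, bridging waters that realize second-shell membership, an optional
#' side chain with a planted chi1 rotamer schedule, and optional
#' donor-hydrogen-acceptor triples with planted H-bond event series.
#'
#' Planted geometry respects the analysis cutoffs with a safety margin of
#' `3 * noise_sd` (noise displacements are truncated at `1.5 * noise_sd`
#' per atom), so the analyses recover the schedules exactly.
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_interval time between frames, ns.
#' @param ion_start 3-vector, initial ion position (Angstrom).
#' @param ligand_atoms data frame with columns `label` and `nominal`
#'   (nominal distance to the ion, Angstrom).
#' @param shell_schedule named list (one entry per ligand label) of
#'   character vectors of length `n_frames` with values `"first"`,
#'   `"second"` or `"none"`; `NULL` plants a constant membership implied by
#'   each ligand's nominal distance.
#' @param water_count number of additional far (non-coordinating) waters.
#' @param chi_schedule character vector of length `n_frames` with values
#'   `"trans"`, `"g+"`, `"g-"`, or `NULL` for no rotamer group.
#' @param hbond_schedule named list of logical vectors of length
#'   `n_frames`, one per donor-acceptor pair, or `NULL`.
#' @param noise_sd isotropic Gaussian coordinate noise, Angstrom (<= 0.1).
#' @param seed integer seed (mandatory).
#' @return an object of class `site_trajectory_spec`.
#' @export
site_trajectory_spec <- function(n_frames, frame_interval = 1,
                                 ion_start = c(0, 0, 0),
                                 ligand_atoms = data.frame(
                                   label = "D2.50_OD1", nominal = 2.5),
                                 shell_schedule = NULL,
                                 water_count = 0L,
                                 chi_schedule = NULL,
                                 hbond_schedule = NULL,
                                 noise_sd = 0, seed) {
  if (missing(seed)) .stopf("a seed is mandatory for synthetic generators")
  if (n_frames < 1) .stopf("n_frames must be >= 1")
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (noise_sd > 0.1)
    .stopf("noise_sd > 0.1 Angstrom would not preserve planted rotamer/H-bond margins")
  if (!all(c("label", "nominal") %in% names(ligand_atoms)))
    .stopf("ligand_atoms needs columns 'label' and 'nominal'")
  if (nrow(ligand_atoms) > nrow(.direction_table))
    .stopf("at most %d ligand atoms supported", nrow(.direction_table))
  if (!is.null(chi_schedule)) {
    if (length(chi_schedule) != n_frames)
      .stopf("chi_schedule must have length n_frames")
    bad <- setdiff(unique(chi_schedule), c("trans", "g+", "g-"))
    if (length(bad)) .stopf("unknown chi state(s): %s", paste(bad, collapse = ", "))
  }
  if (!is.null(hbond_schedule)) {
    if (is.null(names(hbond_schedule)) || any(names(hbond_schedule) == ""))
      .stopf("hbond_schedule must be a named list")
    if (any(lengths(hbond_schedule) != n_frames))
      .stopf("every hbond_schedule series must have length n_frames")
  }
  m <- 3 * noise_sd + 0.01
  if (is.null(shell_schedule)) {
    shell_schedule <- lapply(seq_len(nrow(ligand_atoms)), function(i) {
      d <- ligand_atoms$nominal[i]
      state <- if (d <= 2.8 - m) "first" else if (d <= 6) "second" else "none"
      rep(state, n_frames)
    })
    names(shell_schedule) <- ligand_atoms$label
  }
  if (!setequal(names(shell_schedule), ligand_atoms$label))
    .stopf("shell_schedule names must match ligand labels")
  if (any(lengths(shell_schedule) != n_frames))
    .stopf("every shell_schedule series must have length n_frames")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 ion_start = as.numeric(ion_start),
                 ligand_atoms = ligand_atoms,
                 shell_schedule = shell_schedule,
                 water_count = as.integer(water_count),
                 chi_schedule = chi_schedule,
                 hbond_schedule = hbond_schedule,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "site_trajectory_spec")
}

# distance planted for a ligand with nominal distance d0 in a given state;
# errors on an inconsistent first-shell request.
.planted_distance <- function(state, d0, m, label, frame) {
  switch(state,
    first = {
      if (d0 > 2.8 - m)
        .stopf(paste0("ligand '%s', frame %d: nominal distance %.2f Angstrom is ",
                      "incompatible with planted first-shell membership ",
                      "(needs <= %.2f)"), label, frame, d0, 2.8 - m)
      d0
    },
    second = if (d0 > 2.8 + m && d0 <= 6 - 2 * m) d0 else 4.5,
    none = if (d0 > 6 + m) d0 else 7.5,
    .stopf("ligand '%s', frame %d: unknown shell state '%s'", label, frame, state))
}

#' Generate a synthetic ion-binding-site trajectory
#'
#' Builds a [trajectory()] realizing the planted schedules of a
#' [site_trajectory_spec()], together with the exact ground truth that the
#' coordination-shell, rotamer and H-bond analyses must recover. Bridging
#' waters for second-shell frames are placed on the ion-ligand axis at half
#' the ligand distance, which puts them inside the ion's first water shell
#' (<= 3 Angstrom) and within 3 Angstrom of the ligand by construction.
#' Deterministic given `spec$seed`; coordinates are rounded to the PDB's
#' 3-decimal precision so serialization round trips are lossless.
#'
#' @param spec a [site_trajectory_spec()].
#' @return list with elements `trajectory` (a [trajectory()]) and `truth`
#'   (list with `ligand_occupancy`, `coordination`, `chi_states`,
#'   `hbond_occupancy`).
#' @export
gen_site_trajectory <- function(spec) {
  stopifnot(inherits(spec, "site_trajectory_spec"))
  nf <- spec$n_frames
  nl <- nrow(spec$ligand_atoms)
  m <- 3 * spec$noise_sd + 0.01
  labels <- spec$ligand_atoms$label
  sched <- spec$shell_schedule[labels]

  # ---- atom table -----------------------------------------------------------
  atoms <- data.frame(id = 1L, name = "NA+", resname = "SOD", resid = 1L,
                      role = "ion", stringsAsFactors = FALSE)
  atoms <- rbind(atoms, data.frame(
    id = 1L + seq_len(nl), name = labels, resname = "LIG",
    resid = 1L + seq_len(nl), role = "protein_ligand"))
  next_id <- nl + 2L
  bridge_ids <- integer(0)
  bridged <- vapply(sched, function(s) any(s == "second"), TRUE)
  for (i in seq_len(nl)) {
    if (!bridged[i]) { bridge_ids[i] <- NA_integer_; next }
    atoms <- rbind(atoms, data.frame(
      id = next_id, name = "OH2", resname = "TIP3", resid = 100L + i,
      role = "water_oxygen"))
    bridge_ids[i] <- next_id; next_id <- next_id + 1L
  }
  far_water_ids <- integer(0)
  for (w in seq_len(spec$water_count)) {
    atoms <- rbind(atoms, data.frame(
      id = next_id, name = "OH2", resname = "TIP3", resid = 200L + w,
      role = "water_oxygen"))
    far_water_ids[w] <- next_id; next_id <- next_id + 1L
  }
  chi_ids <- NULL
  if (!is.null(spec$chi_schedule)) {
    chi_ids <- next_id + 0:3
    atoms <- rbind(atoms, data.frame(
      id = chi_ids, name = c("N", "CA", "CB", "CG"), resname = "ASN",
      resid = 90L, role = "other"))
    next_id <- next_id + 4L
  }
  hb_ids <- list()
  if (!is.null(spec$hbond_schedule)) {
    for (p in names(spec$hbond_schedule)) {
      ids <- next_id + 0:2
      atoms <- rbind(atoms, data.frame(
        id = ids, name = c("ND2", "HD21", "OD1"), resname = "HBP",
        resid = 300L + length(hb_ids), role = c("donor", "hydrogen", "acceptor")))
      hb_ids[[p]] <- ids; next_id <- next_id + 3L
    }
  }

  # ---- base coordinates per frame ------------------------------------------
  ion0 <- spec$ion_start
  ligdir <- .direction_table[seq_len(nl), , drop = FALSE]
  coords <- array(0, c(nrow(atoms), 3L, nf))
  idx <- function(id) match(id, atoms$id)
  chi_target <- c(trans = 180, `g+` = 60, `g-` = -60)
  for (f in seq_len(nf)) {
    fr <- matrix(0, nrow(atoms), 3L)
    fr[1L, ] <- ion0
    for (i in seq_len(nl)) {
      st <- sched[[i]][f]
      d <- .planted_distance(st, spec$ligand_atoms$nominal[i], m, labels[i], f)
      fr[idx(1L + i), ] <- ion0 + d * ligdir[i, ]
      if (!is.na(bridge_ids[i])) {
        wpos <- if (st == "second") ion0 + (d / 2) * ligdir[i, ]
                else ion0 + 9 * ligdir[i, ]   # parked outside both shells
        fr[idx(bridge_ids[i]), ] <- wpos
      }
    }
    for (w in seq_along(far_water_ids)) {
      dirw <- .direction_table[1L + (w - 1L) %% nrow(.direction_table), ]
      fr[idx(far_water_ids[w]), ] <- ion0 + (9 + 0.5 * w) * dirw
    }
    if (!is.null(chi_ids)) {
      base <- ion0 + c(15, 0, 0)
      A <- base
      B <- base + c(1.52, 0, 0)
      C <- B + 1.54 * c(cos(69 * pi / 180), sin(69 * pi / 180), 0)
      D <- .place_dihedral(A, B, C, 1.52, 113,
                           chi_target[[spec$chi_schedule[f]]])
      fr[idx(chi_ids), ] <- rbind(A, B, C, D)
    }
    for (p in names(hb_ids)) {
      k <- match(p, names(hb_ids))
      u <- .direction_table[1L + (k - 1L) %% nrow(.direction_table), ]
      base <- ion0 + 14 * u + c(0, 0, 10 * k)
      da <- if (spec$hbond_schedule[[p]][f]) 2.9 else 4.5
      fr[idx(hb_ids[[p]]), ] <- rbind(base, base + c(1, 0, 0),
                                      base + c(da, 0, 0))
    }
    coords[, , f] <- fr
  }

  # ---- truncated noise, deterministic under the seed ------------------------
  with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      eps <- array(rnorm(length(coords), 0, spec$noise_sd), dim(coords))
      nrm <- sqrt(eps[, 1, , drop = FALSE]^2 + eps[, 2, , drop = FALSE]^2 +
                    eps[, 3, , drop = FALSE]^2)
      cap <- 1.5 * spec$noise_sd
      scl <- ifelse(nrm > cap, cap / nrm, 1)
      for (k in 1:3) eps[, k, ] <- eps[, k, ] * scl[, 1, ]
      coords <- coords + eps
    }
  })
  coords <- round(coords, 3)

  traj <- trajectory(atoms, coords,
                     times = seq_len(nf) * spec$frame_interval)

  # ---- ground truth straight from the schedules -----------------------------
  first_mat <- vapply(sched, function(s) s == "first", logical(nf))
  second_mat <- vapply(sched, function(s) s == "second", logical(nf))
  if (nf == 1L) { first_mat <- rbind(first_mat); second_mat <- rbind(second_mat) }
  truth <- list(
    ligand_occupancy = data.frame(
      ligand = labels,
      first_frac = colMeans(first_mat),
      total_frac = colMeans(first_mat | second_mat),
      row.names = NULL),
    coordination = data.frame(
      frame = seq_len(nf),
      protein_first = rowSums(first_mat),
      protein_second = rowSums(second_mat),
      protein_total = rowSums(first_mat | second_mat),
      water_first = rowSums(second_mat),
      water_second = 0L),
    chi_states = spec$chi_schedule,
    hbond_occupancy = if (is.null(spec$hbond_schedule)) NULL else data.frame(
      pair = names(spec$hbond_schedule),
      occupancy_frac = vapply(spec$hbond_schedule, mean, 0),
      row.names = NULL),
    chi_atom_ids = chi_ids,
    hbond_atom_ids = hb_ids,
    ligand_ids = 1L + seq_len(nl))
  list(trajectory = traj, truth = truth)
}
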