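# Ion coordination shells: first/second shell assignment with the
# bridging-water rule for second-shell protein ligands.

#' Assign coordination-shell membership per frame
#'
#' For each frame, classifies protein ligand atoms and water oxygens with
#' respect to the ion:
#' * first-shell protein: distance to ion `<= first_shell_protein` (2.8 A);
#' * first-shell water: distance `<= first_shell_water` (3.0 A);
#' * second-shell water: distance in `(first_shell_water, second_shell]`;
#' * second-shell protein: distance in `(first_shell_protein, second_shell]`
#'   *and* at least one first-shell water within `bridge_water` (3.0 A) of
#'   the protein atom that frame.
#'
#' @param traj a [trajectory()] with one ion and annotated roles.
#' @param params an [analysis_params()].
#' @return object of class `shell_assignment`: a list with per-frame integer
#'   vectors of atom ids `first_protein`, `first_water`, `second_protein`,
#'   `second_water`, plus `times` and `replica`.
#' @export
assign_shells <- function(traj, params = analysis_params()) {
  stopifnot(inherits(traj, "trajectory"))
  ion <- .ion_index(traj)
  lig <- which(traj$atoms$role == "protein_ligand")
  wat <- which(traj$atoms$role == "water_oxygen")
  if (!length(lig) && !length(wat))
    .stopf("trajectory has no atoms with role 'protein_ligand' or 'water_oxygen'")
  nf <- n_frames(traj)
  out <- list(first_protein = vector("list", nf),
              first_water = vector("list", nf),
              second_protein = vector("list", nf),
              second_water = vector("list", nf))
  ids <- traj$atoms$id
  for (f in seq_len(nf)) {
    fr <- traj$coords[, , f, drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    ionp <- fr[ion, ]
    dl <- if (length(lig)) .dist_to(ionp, fr[lig, , drop = FALSE]) else numeric(0)
    dw <- if (length(wat)) .dist_to(ionp, fr[wat, , drop = FALSE]) else numeric(0)
    fw <- wat[dw <= params$first_shell_water]
    sw <- wat[dw > params$first_shell_water & dw <= params$second_shell]
    fp <- lig[dl <= params$first_shell_protein]
    cand <- lig[dl > params$first_shell_protein & dl <= params$second_shell]
    sp <- integer(0)
    if (length(cand) && length(fw)) {
      fwc <- fr[fw, , drop = FALSE]
      ok <- vapply(cand, function(a)
        any(.dist_to(fr[a, ], fwc) <= params$bridge_water), TRUE)
      sp <- cand[ok]
    }
    out$first_protein[[f]] <- ids[fp]
    out$first_water[[f]] <- ids[fw]
    out$second_protein[[f]] <- ids[sp]
    out$second_water[[f]] <- ids[sw]
  }
  structure(c(out, list(times = traj$times, replica = traj$replica,
                        ligand_ids = ids[lig], params = params)),
            class = "shell_assignment")
}

#' Coordination-count summary across replicas
#'
#' Per-frame counts of protein ligands and waters in the first, second and
#' total (first union second) shells are averaged within each replica; the
#' summary reports the mean and the standard error of the mean across
#' replicas (sample sd, n - 1; `NA` for a single replica).
#'
#' @param assignments a `shell_assignment` or a list of them (replicas).
#' @return data frame with columns `species` (protein/water), `shell`
#'   (first/second/total), `mean`, `sem`, `n_replicas`.
#' @export
coordination_counts <- function(assignments) {
  reps <- .as_replica_list(assignments)
  per <- lapply(reps, function(a) {
    nf <- length(a$first_protein)
    if (!nf) .stopf("empty shell assignment")
    c(protein.first = mean(lengths(a$first_protein)),
      protein.second = mean(lengths(a$second_protein)),
      protein.total = mean(lengths(a$first_protein) + lengths(a$second_protein)),
      water.first = mean(lengths(a$first_water)),
      water.second = mean(lengths(a$second_water)),
      water.total = mean(lengths(a$first_water) + lengths(a$second_water)))
  })
  mat <- do.call(rbind, per)
  keys <- strsplit(colnames(mat), ".", fixed = TRUE)
  data.frame(species = vapply(keys, `[`, "", 1L),
             shell = vapply(keys, `[`, "", 2L),
             mean = colMeans(mat),
             sem = apply(mat, 2L, sem),
             n_replicas = nrow(mat),
             row.names = NULL)
}

#' Per-ligand shell occupancy table
#'
#' Percent of frames each protein ligand spends in the first shell and in
#' the "total" (first or second) shell, per replica and pooled as a mean
#' with SEM across replicas.
#'
#' @param assignments a `shell_assignment` or list of them (replicas).
#' @return data frame with columns `ligand`, `shell` (`first`/`total`),
#'   `occupancy` (pooled mean, percent), `sem`, `n_replicas`.
#' @export
occupancy_table <- function(assignments) {
  reps <- .as_replica_list(assignments)
  ligs <- sort(unique(unlist(lapply(reps, `[[`, "ligand_ids"))))
  per <- lapply(reps, function(a) {
    nf <- length(a$first_protein)
    if (!nf) .stopf("occupancy undefined: zero retained frames")
    first <- vapply(ligs, function(id)
      100 * mean(vapply(a$first_protein, function(v) id %in% v, TRUE)), 0)
    total <- vapply(ligs, function(id)
      100 * mean(vapply(seq_len(nf), function(f)
        id %in% a$first_protein[[f]] || id %in% a$second_protein[[f]], TRUE)), 0)
    cbind(first = first, total = total)
  })
  firstm <- vapply(per, function(p) p[, "first"], numeric(length(ligs)))
  totalm <- vapply(per, function(p) p[, "total"], numeric(length(ligs)))
  if (length(ligs) == 1L) { firstm <- rbind(firstm); totalm <- rbind(totalm) }
  data.frame(
    ligand = rep(ligs, 2L),
    shell = rep(c("first", "total"), each = length(ligs)),
    occupancy = c(rowMeans(firstm), rowMeans(totalm)),
    sem = c(apply(firstm, 1L, sem), apply(totalm, 1L, sem)),
    n_replicas = length(reps),
    row.names = NULL)
}

.as_replica_list <- function(x) {
  if (inherits(x, "shell_assignment")) return(list(x))
  if (!length(x)) .stopf("need at least one replica")
  if (!all(vapply(x, inherits, TRUE, "shell_assignment")))
    .stopf("expected shell_assignment objects")
  x
}
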