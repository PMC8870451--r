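#' Molecular trajectory container
#'
#' A lightweight trajectory: per-atom metadata plus a 3-D coordinate array.
#' Atom roles drive the sodium-pocket analyses: exactly one atom must carry
#' the role `"ion"`; electronegative protein atoms that may coordinate the
#' ion are `"protein_ligand"`; water oxygens are `"water_oxygen"`; hydrogen
#' bond partners are `"donor"`, `"hydrogen"`, `"acceptor"`; everything else
#' `"other"`.
#'
#' @param atoms data frame with columns `id` (integer, unique), `name`,
#'   `resname`, `resid`, `role`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param replica replica identifier (integer or character).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times, replica = 1L) {
  need <- c("id", "name", "resname", "resid", "role")
  if (!all(need %in% names(atoms)))
    .stopf("atoms must have columns: %s", paste(need, collapse = ", "))
  roles <- c("ion", "protein_ligand", "water_oxygen", "donor", "hydrogen",
             "acceptor", "other")
  bad <- setdiff(unique(atoms$role), roles)
  if (length(bad)) .stopf("unknown atom role(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(atoms$id)) .stopf("atom ids must be unique")
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    .stopf("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(atoms))
    .stopf("coords first dimension (%d) != number of atoms (%d)",
           dim(coords)[1], nrow(atoms))
  if (dim(coords)[3] != length(times))
    .stopf("coords third dimension (%d) != number of times (%d)",
           dim(coords)[3], length(times))
  if (length(times) < 1L) .stopf("trajectory needs at least one frame")
  if (any(diff(times) <= 0)) .stopf("times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times),
                 replica = replica),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms, %d frames, %.3g-%.3g ns, replica %s\n",
              nrow(x$atoms), length(x$times), x$times[1],
              x$times[length(x$times)], as.character(x$replica)))
  print(table(x$atoms$role))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

# index of the unique ion atom; errors otherwise
.ion_index <- function(traj) {
  i <- which(traj$atoms$role == "ion")
  if (length(i) != 1L)
    .stopf("trajectory must contain exactly one atom with role 'ion' (found %d)",
           length(i))
  i
}

.atom_index <- function(traj, ids) {
  idx <- match(ids, traj$atoms$id)
  if (anyNA(idx))
    .stopf("unknown atom id(s): %s", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# ---- PDB serialization ------------------------------------------------------

.role_codes <- c(other = 0, ion = 1, protein_ligand = 2, water_oxygen = 3,
                 donor = 4, hydrogen = 5, acceptor = 6)

.pdb_atom_line <- function(id, name, resname, resid, xyz, occ, b = 0) {
  sprintf("ATOM  %5d %-4s%-4s%5d     %8.3f%8.3f%8.3f%6.2f%6.2f",
          id, substr(name, 1, 4), substr(resname, 1, 4), resid,
          xyz[1], xyz[2], xyz[3], occ, b)
}

#' Write a trajectory as PDB topology plus multi-model PDB frames
#'
#' The occupancy column of the topology is repurposed to carry an integer
#' role code; the mapping, frame times and replica id are documented in a
#' JSON sidecar next to the topology. Coordinates are written at the PDB's
#' fixed 3-decimal precision, so a round trip through
#' [read_trajectory_pdb()] is lossless for coordinates already on that grid
#' (the synthetic generators emit such coordinates).
#'
#' @param traj a [trajectory()].
#' @param topology path of the single-frame topology PDB.
#' @param frames path of the multi-model frame PDB.
#' @param sidecar path of the JSON sidecar; default `<topology>.json`.
#' @return invisibly, the sidecar path.
#' @export
write_trajectory_pdb <- function(traj, topology, frames,
                                 sidecar = paste0(topology, ".json")) {
  at <- traj$atoms
  occ <- .role_codes[at$role]
  top <- vapply(seq_len(nrow(at)), function(i)
    .pdb_atom_line(at$id[i], at$name[i], at$resname[i], at$resid[i],
                   traj$coords[i, , 1], occ[i]), "")
  writeLines(c(top, "END"), topology)
  con <- file(frames, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(vapply(seq_len(nrow(at)), function(i)
      .pdb_atom_line(at$id[i], at$name[i], at$resname[i], at$resid[i],
                     traj$coords[i, , f], occ[i]), ""), con)
    writeLines("ENDMDL", con)
  }
  meta <- list(role_codes = as.list(.role_codes), times = traj$times,
               replica = traj$replica)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

.parse_pdb_atoms <- function(lines) {
  lines <- lines[startsWith(lines, "ATOM")]
  data.frame(
    id = as.integer(substr(lines, 7, 11)),
    name = trimws(substr(lines, 13, 16)),
    resname = trimws(substr(lines, 17, 20)),
    resid = as.integer(substr(lines, 21, 25)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = as.numeric(substr(lines, 55, 60)),
    stringsAsFactors = FALSE)
}

#' Read a trajectory written by [write_trajectory_pdb()]
#'
#' @inheritParams write_trajectory_pdb
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(topology, frames,
                                sidecar = paste0(topology, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  top <- .parse_pdb_atoms(readLines(topology))
  code2role <- setNames(names(.role_codes), .role_codes)
  atoms <- data.frame(id = top$id, name = top$name, resname = top$resname,
                      resid = top$resid,
                      role = unname(code2role[as.character(round(top$occ))]),
                      stringsAsFactors = FALSE)
  lines <- readLines(frames)
  starts <- which(startsWith(lines, "MODEL"))
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(starts) != length(ends) || !length(starts))
    .stopf("malformed multi-model PDB: %d MODEL vs %d ENDMDL records",
           length(starts), length(ends))
  nf <- length(starts)
  coords <- array(NA_real_, c(nrow(atoms), 3, nf))
  for (f in seq_len(nf)) {
    fr <- .parse_pdb_atoms(lines[(starts[f] + 1L):(ends[f] - 1L)])
    if (nrow(fr) != nrow(atoms))
      .stopf("frame %d has %d atoms, topology has %d", f, nrow(fr), nrow(atoms))
    coords[, , f] <- as.matrix(fr[, c("x", "y", "z")])
  }
  trajectory(atoms, coords, times = as.numeric(meta$times),
             replica = meta$replica)
}

#' Write / read frames in a whitespace XYZ-per-frame dialect
#'
#' Each frame is `n_atoms`, a comment line `frame <i> time <t>`, then one
#' `name x y z` line per atom. Roles come from the accompanying topology
#' when reading, so the XYZ file alone is not a full trajectory.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(traj$atoms)
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(na),
                 sprintf("frame %d time %.6f", f, traj$times[f]),
                 sprintf("%-4s %12.6f %12.6f %12.6f", traj$atoms$name,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f])), con)
  }
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @param atoms atom metadata data frame (see [trajectory()]).
#' @param times frame times in ns; parsed from comment lines when `NULL`.
#' @param replica replica identifier.
#' @export
read_trajectory_xyz <- function(path, atoms, times = NULL, replica = 1L) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); tparsed <- numeric()
  while (i <= length(lines)) {
    na <- as.integer(lines[i])
    cm <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    tparsed <- c(tparsed, suppressWarnings(as.numeric(cm[length(cm)])))
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1L]] <-
      t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    i <- i + 2L + na
  }
  coords <- array(unlist(frames), c(nrow(atoms), 3, length(frames)))
  if (is.null(times)) times <- tparsed
  trajectory(atoms, coords, times, replica)
}
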