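# Charge systems: containers, PQR I/O, and analytic oracle systems for the
# Poisson-Boltzmann solver.

#' Charge system container
#'
#' A set of point charges with radii, the minimal input of the
#' Poisson-Boltzmann machinery.
#'
#' @param atoms data frame with columns `x`, `y`, `z` (Angstrom), `q`
#'   (elementary charges), `radius` (Angstrom, > 0); optional `name`,
#'   `resname`, `resid`, `titratable` (logical).
#' @param ion_id optional row index of a distinguished ion atom.
#' @param reference optional list of closed-form reference values attached
#'   by the generators.
#' @return object of class `charge_system`.
#' @export
charge_system <- function(atoms, ion_id = NULL, reference = NULL) {
  need <- c("x", "y", "z", "q", "radius")
  if (!all(need %in% names(atoms)))
    .stopf("atoms must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, need]))))
    .stopf("charge system contains non-finite values")
  if (any(atoms$radius <= 0)) .stopf("all radii must be > 0")
  if (is.null(atoms$titratable)) atoms$titratable <- FALSE
  structure(list(atoms = atoms, ion_id = ion_id, reference = reference),
            class = "charge_system")
}

#' @export
print.charge_system <- function(x, ...) {
  cat(sprintf("<charge_system> %d atoms, net charge %+.3f e\n",
              nrow(x$atoms), sum(x$atoms$q)))
  invisible(x)
}

.coords_mat <- function(system) as.matrix(system$atoms[, c("x", "y", "z")])

#' Generate analytic oracle charge systems
#'
#' Small systems whose electrostatics have closed forms, used to validate
#' the grid solver:
#' * `point`: a single charge; reference Coulomb potential
#'   `phi(r) = q C / (eps r)` in a homogeneous medium `eps`.
#' * `born`: a Born ion of radius `a`; reference solvation energy
#'   `-q^2 C / (2 a) (1/eps_in - 1/eps_out)` (kT).
#' * `dipole`: charges `+q`/`-q` separated by `sep` along z.
#' * `two_body`: charges `q1`, `q2` at separation `r`; reference
#'   interaction energy `q1 q2 C / (eps r)` (kT).
#'
#' `C = coulomb_const(temperature)`.
#'
#' @param kind one of `"point"`, `"born"`, `"dipole"`, `"two_body"`.
#' @param q,q1,q2 charges, e.
#' @param a,radius radii, Angstrom.
#' @param sep,r separations, Angstrom.
#' @param eps,eps_in,eps_out relative permittivities.
#' @param temperature Kelvin.
#' @return a [charge_system()] with a `reference` list attached.
#' @export
gen_charge_system <- function(kind, q = 1, a = 2, radius = 1.5, sep = 2,
                              r = 5, q1 = 1, q2 = -1, eps = 80,
                              eps_in = 2, eps_out = 80,
                              temperature = 298.15) {
  C <- coulomb_const(temperature)
  switch(kind,
    point = charge_system(
      data.frame(x = 0, y = 0, z = 0, q = q, radius = radius),
      reference = list(
        potential = function(rr) q * C / (eps * rr),
        eps = eps)),
    born = charge_system(
      data.frame(x = 0, y = 0, z = 0, q = q, radius = a),
      reference = list(
        solvation_kT = -q^2 * C / (2 * a) * (1 / eps_in - 1 / eps_out),
        eps_in = eps_in, eps_out = eps_out)),
    dipole = charge_system(
      data.frame(x = c(0, 0), y = c(0, 0), z = c(-sep / 2, sep / 2),
                 q = c(-q, q), radius = radius),
      reference = list(moment = q * sep)),
    two_body = charge_system(
      data.frame(x = c(0, r), y = c(0, 0), z = c(0, 0),
                 q = c(q1, q2), radius = radius),
      reference = list(
        interaction_kT = q1 * q2 * C / (eps * r), eps = eps)),
    .stopf("unknown charge system kind '%s'", kind))
}

#' Read / write PQR files
#'
#' Whitespace-delimited PQR (as produced by pdb2pqr): ATOM/HETATM records
#' with fields name, residue, residue number, x, y, z, charge, radius.
#'
#' @param path file path.
#' @return [read_pqr()]: a [charge_system()]; [write_pqr()]: invisibly,
#'   `path`.
#' @export
read_pqr <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(lines)) .stopf("no ATOM/HETATM records in '%s'", path)
  parts <- strsplit(trimws(lines), "\\s+")
  nfld <- lengths(parts)
  if (any(nfld < 10L)) .stopf("malformed PQR record (need >= 10 fields)")
  get <- function(i) vapply(parts, `[`, "", i)
  n <- length(parts)
  # last five numeric fields are x y z q r; field layout before them varies
  num <- t(vapply(parts, function(p) as.numeric(tail(p, 5L)), numeric(5)))
  charge_system(data.frame(
    name = get(3L), resname = get(4L),
    x = num[, 1], y = num[, 2], z = num[, 3],
    q = num[, 4], radius = num[, 5],
    stringsAsFactors = FALSE))
}

#' @rdname read_pqr
#' @param system a [charge_system()].
#' @export
write_pqr <- function(system, path) {
  at <- system$atoms
  name <- if (is.null(at$name)) sprintf("Q%d", seq_len(nrow(at))) else at$name
  resname <- if (is.null(at$resname)) "UNK" else at$resname
  resid <- if (is.null(at$resid)) seq_len(nrow(at)) else at$resid
  writeLines(sprintf(
    "ATOM  %5d %-4s %-4s %4d %11.4f %11.4f %11.4f %8.4f %7.4f",
    seq_len(nrow(at)), name, resname, resid,
    at$x, at$y, at$z, at$q, at$radius), path)
  invisible(path)
}
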