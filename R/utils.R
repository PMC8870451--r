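# Shared helpers: physical constants, seeded RNG, small statistics.

# CODATA-2018 constants
.const <- list(
  e      = 1.602176634e-19,   # C
  kB     = 1.380649e-23,      # J/K
  eps0_4pi = 1.112650056e-10, # C^2 J^-1 m^-1  (4*pi*eps0)
  NA_avo = 6.02214076e23      # mol^-1
)

#' Coulomb constant in kT Angstrom / e^2
#'
#' The prefactor \eqn{C = e^2 / (4\pi\epsilon_0 k_B T)} expressed in
#' kT.Angstrom per squared elementary charge, so that the potential of a
#' point charge q (in e) at distance r (in Angstrom) in a medium of relative
#' permittivity eps is `q * coulomb_const(T) / (eps * r)` in kT/e.
#' At 298.15 K the value is about 560.5.
#'
#' @param temperature temperature in Kelvin.
#' @return scalar, kT.Angstrom/e^2.
#' @export
coulomb_const <- function(temperature = 298.15) {
  with(.const, e^2 / (eps0_4pi * 1e-10 * kB * temperature))
}

# Debye screening prefactor K = eps_out * kappa^2 (Angstrom^-2) for a 1:1
# salt at ionic strength I mol/L: K = 4*pi*C*2*I_n with I_n in Angstrom^-3.
.screening_K <- function(ionic_strength, temperature = 298.15) {
  In <- ionic_strength * .const$NA_avo * 1e-27
  4 * pi * coulomb_const(temperature) * 2 * In
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by sqrt(n).
#' A single observation yields `NA` (dispersion undefined), not 0.
#'
#' @param x numeric vector.
#' @return scalar SEM, `NA_real_` if `length(x) < 2`.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Euclidean norm of rows of an n x 3 matrix
.row_norm <- function(m) sqrt(rowSums(m * m))

# distances from one point to rows of a matrix
.dist_to <- function(point, coords) {
  .row_norm(sweep(coords, 2L, point))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
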