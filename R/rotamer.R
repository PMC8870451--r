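# Side-chain chi dihedral series and rotamer classification.

#' Default chi1 rotamer bins
#'
#' Standard wells centered at 180 (trans), +60 (g+) and -60 (g-) degrees:
#' trans for |chi| > 120, g+ for chi in (0, 120], g- for chi in [-120, 0]
#' (the boundary at exactly -120 is assigned to g- so the bins partition
#' the circle).
#' @export
rotamer_bins <- function() {
  list(trans = function(x) abs(x) > 120,
       `g+` = function(x) x > 0 & x <= 120,
       `g-` = function(x) x >= -120 & x <= 0)
}

#' Chi dihedral series and rotamer labels
#'
#' Computes the chi dihedral defined by four atoms for every frame and
#' classifies it into rotamer states. Frames where the dihedral is
#' undefined (colinear atoms) are labelled `NA` and flagged, not dropped.
#'
#' @param traj a [trajectory()].
#' @param atom_ids integer vector of 4 atom ids (e.g. N, CA, CB, CG for
#'   chi1 of an Asn side chain).
#' @param bins named list of predicate functions over degrees; default
#'   [rotamer_bins()].
#' @return object of class `chi_series`: data frame with `frame`, `time`,
#'   `chi` (degrees in (-180, 180]), `state`; attribute `fractions` holds
#'   the histogram fractions over defined frames and attribute `undefined`
#'   the indices of flagged frames.
#' @export
classify_rotamer <- function(traj, atom_ids, bins = rotamer_bins()) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(atom_ids) != 4L) .stopf("need exactly 4 atom ids for a dihedral")
  idx <- .atom_index(traj, atom_ids)
  nf <- n_frames(traj)
  chi <- vapply(seq_len(nf), function(f) {
    fr <- traj$coords[, , f]
    dihedral_angle(fr[idx[1], ], fr[idx[2], ], fr[idx[3], ], fr[idx[4], ])
  }, 0)
  state <- rep(NA_character_, nf)
  for (nm in names(bins)) {
    hit <- !is.na(chi) & bins[[nm]](chi)
    if (any(hit & !is.na(state)))
      .stopf("rotamer bins overlap at chi = %.1f", chi[which(hit & !is.na(state))[1]])
    state[hit] <- nm
  }
  defined <- !is.na(chi)
  if (any(defined & is.na(state)))
    .stopf("rotamer bins do not cover chi = %.1f",
           chi[which(defined & is.na(state))[1]])
  fr <- table(factor(state[defined], levels = names(bins)))
  res <- data.frame(frame = seq_len(nf), time = traj$times, chi = chi,
                    state = state)
  structure(res, class = c("chi_series", "data.frame"),
            fractions = setNames(as.numeric(fr) / max(sum(fr), 1L),
                                 names(bins)),
            undefined = which(!defined))
}

#' Histogram fractions of a chi series
#' @param x a `chi_series`.
#' @return named numeric vector of state fractions (sums to 1 over defined
#'   frames).
#' @export
rotamer_fractions <- function(x) attr(x, "fractions")
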