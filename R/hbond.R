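# Hydrogen-bond occupancy with the early-outward-rotamer replica filter.

#' Hydrogen-bond occupancy over one or more replicas
#'
#' A frame counts as H-bonded for a donor-hydrogen-acceptor triple when the
#' donor-acceptor distance is `<= hbond_dist` (3.5 A) and the D-H...A angle
#' deviates from linearity by `<= hbond_angle_dev` (30 degrees).
#'
#' When chi series are supplied via `filter_on`, the replica filter of the
#' inward/outward rotamer protocol applies: a replica whose filtered side
#' chain reaches the outward state (label `outward_state`, default `"g-"`)
#' within the first `rotamer_filter_window` ns (50 ns) is excluded from the
#' analysis entirely; in the remaining replicas only frames with an inward
#' label are retained as the denominator.
#'
#' @param trajs a [trajectory()] or a list of them (replicas).
#' @param pairs data frame with columns `pair`, `donor`, `hydrogen`,
#'   `acceptor` (atom ids).
#' @param params an [analysis_params()].
#' @param filter_on `NULL`, or a list (one per replica) of `chi_series`
#'   objects from [classify_rotamer()].
#' @param outward_state rotamer label treated as outward.
#' @return object of class `hbond_table`: data frame with `pair`,
#'   `occupancy` (pooled percent over retained frames of retained
#'   replicas), `sem` (across retained replicas), `n_replicas_used`;
#'   attributes `removed_replicas` (replica ids excluded by the filter) and
#'   `retained_frames` (per replica logical masks).
#' @export
hbond_occupancy <- function(trajs, pairs, params = analysis_params(),
                            filter_on = NULL, outward_state = "g-") {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (!length(trajs)) .stopf("need at least one replica")
  need <- c("pair", "donor", "hydrogen", "acceptor")
  if (!all(need %in% names(pairs)))
    .stopf("pairs must have columns: %s", paste(need, collapse = ", "))
  if (!is.null(filter_on) && length(filter_on) != length(trajs))
    .stopf("filter_on must supply one chi series per replica")

  removed <- character(0)
  keep <- rep(TRUE, length(trajs))
  masks <- vector("list", length(trajs))
  for (r in seq_along(trajs)) {
    nf <- n_frames(trajs[[r]])
    if (is.null(filter_on)) { masks[[r]] <- rep(TRUE, nf); next }
    cs <- filter_on[[r]]
    if (nrow(cs) != nf)
      .stopf("replica %d: chi series has %d frames, trajectory %d",
             r, nrow(cs), nf)
    early <- cs$time <= params$rotamer_filter_window
    if (any(cs$state[early] == outward_state, na.rm = TRUE)) {
      keep[r] <- FALSE
      removed <- c(removed, as.character(trajs[[r]]$replica))
      masks[[r]] <- rep(FALSE, nf)
    } else {
      masks[[r]] <- !is.na(cs$state) & cs$state != outward_state
    }
  }
  if (!any(keep))
    .stopf("all replicas removed by the %g ns outward-rotamer filter",
           params$rotamer_filter_window)

  per <- lapply(which(keep), function(r) {
    traj <- trajs[[r]]
    mask <- masks[[r]]
    if (!any(mask)) .stopf("replica %d retains no frames", r)
    vapply(seq_len(nrow(pairs)), function(p) {
      di <- .atom_index(traj, pairs$donor[p])
      hi <- .atom_index(traj, pairs$hydrogen[p])
      ai <- .atom_index(traj, pairs$acceptor[p])
      if (traj$atoms$role[hi] != "hydrogen")
        .stopf("pair '%s': atom %d is not annotated as hydrogen",
               pairs$pair[p], pairs$hydrogen[p])
      hits <- vapply(which(mask), function(f) {
        fr <- traj$coords[, , f]
        d <- sqrt(sum((fr[di, ] - fr[ai, ])^2))
        if (d > params$hbond_dist) return(FALSE)
        v1 <- fr[di, ] - fr[hi, ]; v2 <- fr[ai, ] - fr[hi, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        (180 - ang) <= params$hbond_angle_dev
      }, TRUE)
      100 * mean(hits)
    }, 0)
  })
  mat <- do.call(rbind, per)
  res <- data.frame(pair = pairs$pair,
                    occupancy = colMeans(mat),
                    sem = apply(mat, 2L, sem),
                    n_replicas_used = sum(keep),
                    row.names = NULL)
  structure(res, class = c("hbond_table", "data.frame"),
            removed_replicas = removed, retained_frames = masks)
}
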