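# Independent oracles used across the suite. These re-derive expected
# results by a different route than the implementation (vectorized
# all-prefix scans, closed forms) so agreement is meaningful.

# Brute-force annotation oracle: compute the net displacement from t0 to
# EVERY frame of the evaluation grid in one vectorized sweep, then take
# the first strict threshold crossing and re-derive the quadrant label
# from scratch.
oracle_annotate <- function(traj, t0, diameter_um = 18, eval_interval_min = 15) {
  step <- as.integer(round(eval_interval_min / traj$frame_interval_min))
  i0 <- which(traj$frames == t0)
  cand <- t0 + step * seq_len(2 * length(traj$frames))
  idx <- match(cand, traj$frames)
  last_ok <- which(is.na(idx))[1]
  if (!is.na(last_ok)) idx <- idx[seq_len(last_ok - 1L)]
  if (length(idx) == 0L) return(NULL)
  dx <- traj$x_um[idx] - traj$x_um[i0]
  dy <- traj$y_um[idx] - traj$y_um[i0]
  net <- sqrt(dx^2 + dy^2)
  hit <- which(net > diameter_um)[1]
  if (is.na(hit)) return(NULL)
  lab <- if (dy[hit] <= 0) (if (dx[hit] >= 0) 0L else 1L) else
                           (if (dx[hit] < 0) 2L else 3L)
  list(label = lab, delta_t_min = hit * eval_interval_min,
       dx = dx[hit], dy = dy[hit], net = net[hit])
}

# Random trajectory with heterogeneous steps (not the package simulator):
# isotropic correlated-ish walk with occasional near-zero steps, so both
# crossing and exclusion cases occur.
random_track <- function(n_points = 20, frame_interval_min = 15,
                         step_scale = 8) {
  ang <- cumsum(runif(n_points - 1, -pi / 2, pi / 2))
  len <- abs(rnorm(n_points - 1, step_scale, step_scale))
  x <- cumsum(c(0, len * cos(ang)))
  y <- cumsum(c(0, len * sin(ang)))
  cell_track(1L, 0:(n_points - 1L), x, y,
             frame_interval_min = frame_interval_min)
}

# Apply a planar isometry to a trajectory (about the origin; annotation
# labels only depend on displacements, so the center does not matter).
transform_track <- function(traj, transform) {
  x <- traj$x_um; y <- traj$y_um
  new <- switch(transform,
    identity = list(x, y),
    hflip  = list(-x, y),
    vflip  = list(x, -y),
    rot90  = list(y, -x),   # (dx, dy) -> (dy, -dx), image-coordinate CCW
    rot180 = list(-x, -y),
    rot270 = list(-y, x),
    stop("unknown transform"))
  cell_track(traj$cell_id, traj$frames, new[[1]], new[[2]],
             frame_interval_min = traj$frame_interval_min)
}
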