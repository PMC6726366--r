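#' Construct a cell trajectory
#'
#' A trajectory is the time-ordered sequence of tracked positions of one
#' cell, in micrometers, in image coordinates (y grows downward). Frame
#' indices are 0-based and must be strictly increasing; the acquisition
#' time of point i is \code{frames[i] * frame_interval_min}.
#'
#' @param cell_id Identifier of the cell.
#' @param frames Integer frame indices, 0-based, strictly increasing.
#' @param x_um,y_um Positions in micrometers.
#' @param frame_interval_min Acquisition interval in minutes.
#' @param pixel_size_um Pixel size in micrometers (metadata; optional).
#' @param headings Optional per-point heading angles in radians (ground
#'   truth from the simulator; the direction of the subsequent
#'   displacement).
#' @return An object of class \code{cell_track}.
#' @examples
#' tr <- cell_track(1, 0:2, c(0, 10, 10), c(0, 0, 10), frame_interval_min = 15)
#' net_displacement(tr, 0, 2) # sqrt(200)
#' @export
cell_track <- function(cell_id, frames, x_um, y_um, frame_interval_min,
                       pixel_size_um = NULL, headings = NULL) {
  frames <- as.integer(frames)
  if (length(frames) < 1L) stop("a trajectory needs at least one point")
  if (length(x_um) != length(frames) || length(y_um) != length(frames))
    stop("frames, x_um and y_um must have equal length")
  if (any(diff(frames) <= 0L)) stop("frame indices must be strictly increasing")
  if (any(frames < 0L)) stop("frame indices must be non-negative")
  if (!is.numeric(frame_interval_min) || frame_interval_min <= 0)
    stop("frame_interval_min must be positive")
  structure(list(cell_id = cell_id, frames = frames,
                 x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                 frame_interval_min = frame_interval_min,
                 pixel_size_um = pixel_size_um,
                 headings = headings),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> cell %s: %d points, frames %d..%d, %g-min interval\n",
              format(x$cell_id), length(x$frames), min(x$frames), max(x$frames),
              x$frame_interval_min))
  invisible(x)
}

#' @export
length.cell_track <- function(x) length(x$frames)

track_point <- function(traj, frame) {
  i <- match(frame, traj$frames)
  if (is.na(i)) stop(sprintf("frame %d is not in the trajectory of cell %s",
                             frame, format(traj$cell_id)))
  c(x = traj$x_um[i], y = traj$y_um[i])
}

#' Net displacement between two frames
#'
#' Euclidean distance between the positions of the cell at frames
#' \code{t0} and \code{t}, in micrometers.
#'
#' @param traj A [cell_track()].
#' @param t0,t Frame indices present in the trajectory, \code{t0 <= t}.
#' @return Distance in micrometers.
#' @export
net_displacement <- function(traj, t0, t) {
  stopifnot(inherits(traj, "cell_track"), t0 <= t)
  p0 <- track_point(traj, t0)
  p1 <- track_point(traj, t)
  sqrt(sum((p1 - p0)^2))
}

#' Resample a trajectory onto a coarser evaluation grid
#'
#' Keeps every (eval/acquisition)-th point starting from the first, e.g.
#' every 3rd point of a 5-min track for a 15-min evaluation grid. Frame
#' indices are renumbered consecutively from 0 and the trajectory's
#' interval becomes \code{eval_interval_min}, so point times stay
#' consistent.
#'
#' @param traj A [cell_track()].
#' @param eval_interval_min Evaluation interval in minutes; must be an
#'   integer multiple of the trajectory's acquisition interval.
#' @return A [cell_track()] on the evaluation grid.
#' @export
resample_interval <- function(traj, eval_interval_min = 15) {
  stopifnot(inherits(traj, "cell_track"))
  step <- eval_interval_min / traj$frame_interval_min
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop("eval_interval_min must be a positive integer multiple of the acquisition interval")
  step <- as.integer(round(step))
  keep <- seq(1L, length(traj$frames), by = step)
  cell_track(traj$cell_id, seq_along(keep) - 1L,
             traj$x_um[keep], traj$y_um[keep],
             frame_interval_min = eval_interval_min,
             pixel_size_um = traj$pixel_size_um,
             headings = if (!is.null(traj$headings)) traj$headings[keep])
}

# Frames of the evaluation grid anchored at t0: t0, t0 + step, t0 + 2*step,
# ... for as long as they are present in the trajectory (a missing frame
# ends the scan, as for a lost cell).
eval_grid_frames <- function(traj, t0, eval_interval_min) {
  step <- eval_interval_min / traj$frame_interval_min
  if (abs(step - round(step)) > 1e-9 || step < 1)
    stop("eval_interval_min must be a positive integer multiple of the acquisition interval")
  step <- as.integer(round(step))
  out <- t0
  f <- t0 + step
  while (f %in% traj$frames) {
    out <- c(out, f)
    f <- f + step
  }
  out
}

#' Annotate the moving direction at an anchor frame
#'
#' Scans the evaluation grid forward from the anchor frame \code{t0} and
#' finds the first time the net displacement strictly exceeds one cell
#' diameter (default 18 um, the average diameter of NIH/3T3 fibroblasts).
#' The moving direction is the quadrant of the displacement \code{(dx,
#' dy)} at that crossing (see [quadrant_label()]); \code{delta_t_min} is
#' the elapsed time. Cells whose net migration never exceeds the diameter
#' before the track ends are excluded (\code{NULL} is returned).
#'
#' @param traj A [cell_track()].
#' @param t0 Anchor frame index (must be in the trajectory).
#' @param diameter_um Net-displacement threshold in micrometers.
#' @param eval_interval_min Evaluation grid spacing in minutes; the
#'   crossing is searched at this resolution regardless of the acquisition
#'   interval.
#' @return A list of class \code{direction_annotation} with elements
#'   \code{cell_id}, \code{frame}, \code{label}, \code{label_name},
#'   \code{delta_t_min}, \code{dx_um}, \code{dy_um} and \code{net_um}, or
#'   \code{NULL} when the cell is excluded.
#' @examples
#' # straight +x at 2 um per 15-min step: crossing at step 10, upper right
#' tr <- cell_track(1, 0:12, 2 * (0:12), rep(0, 13), frame_interval_min = 15)
#' annotate_direction(tr, 0)
#' @export
annotate_direction <- function(traj, t0, diameter_um = 18,
                               eval_interval_min = 15) {
  stopifnot(inherits(traj, "cell_track"))
  if (!t0 %in% traj$frames)
    stop(sprintf("anchor frame %d is not in the trajectory", t0))
  grid <- eval_grid_frames(traj, t0, eval_interval_min)
  if (length(grid) < 2L) return(NULL)
  p0 <- track_point(traj, t0)
  for (f in grid[-1L]) {
    p <- track_point(traj, f)
    d <- p - p0
    net <- sqrt(sum(d^2))
    if (net > diameter_um) {
      return(structure(list(
        cell_id = traj$cell_id, frame = t0,
        label = quadrant_label(d[["x"]], d[["y"]]),
        label_name = direction_name(quadrant_label(d[["x"]], d[["y"]])),
        delta_t_min = (f - t0) * traj$frame_interval_min,
        dx_um = unname(d[["x"]]), dy_um = unname(d[["y"]]),
        net_um = net), class = "direction_annotation"))
    }
  }
  NULL
}

#' Annotate every anchor frame of a trajectory
#'
#' Applies [annotate_direction()] with every track point as anchor and
#' collects the non-excluded results.
#'
#' @inheritParams annotate_direction
#' @return A data frame with one row per annotated anchor: \code{cell_id},
#'   \code{frame}, \code{label}, \code{delta_t_min}, \code{dx_um},
#'   \code{dy_um}. Zero rows when every anchor is excluded.
#' @export
annotate_all <- function(traj, diameter_um = 18, eval_interval_min = 15) {
  rows <- lapply(traj$frames, function(f) {
    a <- annotate_direction(traj, f, diameter_um, eval_interval_min)
    if (is.null(a)) return(NULL)
    data.frame(cell_id = a$cell_id, frame = a$frame, label = a$label,
               delta_t_min = a$delta_t_min, dx_um = a$dx_um, dy_um = a$dy_um)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(cell_id = character(0), frame = integer(0),
                      label = integer(0), delta_t_min = numeric(0),
                      dx_um = numeric(0), dy_um = numeric(0)))
  do.call(rbind, rows)
}

# Steps of the evaluation grid from t0 up to (and including) the crossing
# frame; internal helper shared by the motility statistics.
crossing_path <- function(traj, t0, diameter_um, eval_interval_min) {
  ann <- annotate_direction(traj, t0, diameter_um, eval_interval_min)
  if (is.null(ann))
    stop("motility statistics are undefined for excluded cells (no threshold crossing)")
  grid <- eval_grid_frames(traj, t0, eval_interval_min)
  tc <- t0 + ann$delta_t_min / traj$frame_interval_min
  grid <- grid[grid <= tc]
  xs <- traj$x_um[match(grid, traj$frames)]
  ys <- traj$y_um[match(grid, traj$frames)]
  list(ann = ann, step_lengths = sqrt(diff(xs)^2 + diff(ys)^2))
}

#' Average speed up to the annotation crossing
#'
#' The total distance travelled on the evaluation grid between the anchor
#' frame and the threshold crossing, divided by the elapsed time:
#' v = sum(step lengths) / delta_t.
#'
#' @inheritParams annotate_direction
#' @return Speed in micrometers per minute.
#' @export
average_speed <- function(traj, t0, diameter_um = 18, eval_interval_min = 15) {
  cp <- crossing_path(traj, t0, diameter_um, eval_interval_min)
  sum(cp$step_lengths) / cp$ann$delta_t_min
}

#' Directionality up to the annotation crossing
#'
#' The net displacement at the crossing divided by the total distance
#' travelled on the evaluation grid: k = dr / sum(dd). k equals 1 for a
#' perfectly straight path and approaches 0 for a cell that keeps turning.
#'
#' @inheritParams annotate_direction
#' @return Unitless value in (0, 1].
#' @export
directionality <- function(traj, t0, diameter_um = 18, eval_interval_min = 15) {
  cp <- crossing_path(traj, t0, diameter_um, eval_interval_min)
  total <- sum(cp$step_lengths)
  if (total <= 0) stop("directionality undefined: zero path length")
  cp$ann$net_um / total
}
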