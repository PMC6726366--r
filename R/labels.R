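#' Moving-direction labels
#'
#' The four moving directions are encoded as integers \code{0:3} in the
#' order upper right, upper left, lower left, lower right. Coordinates
#' follow the image convention: x grows to the right, y grows \emph{down},
#' so a negative \code{dy} means upward movement.
#'
#' @return A named integer vector mapping label names to codes.
#' @examples
#' direction_labels()
#' @export
direction_labels <- function() {
  c(upper_right = 0L, upper_left = 1L, lower_left = 2L, lower_right = 3L)
}

#' @rdname direction_labels
#' @param label Integer label codes in \code{0:3}.
#' @return For \code{direction_name}, the label names as characters.
#' @export
direction_name <- function(label) {
  stopifnot(all(label %in% 0:3))
  names(direction_labels())[label + 1L]
}

#' Quadrant rule for a displacement vector
#'
#' Maps a displacement \code{(dx, dy)} in image coordinates to one of the
#' four moving directions: \code{dx >= 0, dy <= 0} is upper right;
#' \code{dx < 0, dy <= 0} upper left; \code{dx < 0, dy > 0} lower left;
#' \code{dx >= 0, dy > 0} lower right. The four predicates partition every
#' nonzero displacement; the degenerate input \code{(0, 0)} falls into the
#' upper-right branch and never arises from a threshold crossing.
#'
#' @param dx,dy Displacement components (same units), vectorized.
#' @return Integer labels as in [direction_labels()].
#' @examples
#' quadrant_label(3, -4)   # upper_right
#' quadrant_label(-5, -20) # upper_left
#' @export
quadrant_label <- function(dx, dy) {
  stopifnot(length(dx) == length(dy), all(is.finite(dx)), all(is.finite(dy)))
  ifelse(dy <= 0,
         ifelse(dx >= 0, 0L, 1L),
         ifelse(dx < 0, 2L, 3L))
}

#' Transform a direction label under a planar isometry
#'
#' When an image patch is flipped or rotated, a cell that was moving to the
#' upper right appears to move in a different quadrant; the label must be
#' transformed with the patch. Rotations are counterclockwise in the
#' displayed image (y down), under which the quadrant cycle
#' upper_right -> upper_left -> lower_left -> lower_right advances by one.
#'
#' @param label Integer labels in \code{0:3}.
#' @param transform One of \code{"identity"}, \code{"hflip"} (mirror x),
#'   \code{"vflip"} (mirror y), \code{"rot90"}, \code{"rot180"},
#'   \code{"rot270"}.
#' @return Transformed integer labels.
#' @examples
#' transform_label(0L, "rot180") # upper_right -> lower_left
#' transform_label(0L, "hflip")  # upper_right -> upper_left
#' @export
transform_label <- function(label, transform = c("identity", "hflip", "vflip",
                                                 "rot90", "rot180", "rot270")) {
  transform <- match.arg(transform)
  stopifnot(all(label %in% 0:3))
  label <- as.integer(label)
  switch(transform,
    identity = label,
    hflip  = c(1L, 0L, 3L, 2L)[label + 1L],
    vflip  = c(3L, 2L, 1L, 0L)[label + 1L],
    rot90  = (label + 1L) %% 4L,
    rot180 = (label + 2L) %% 4L,
    rot270 = (label + 3L) %% 4L)
}

#' Overlay colors for predicted directions
#'
#' Standard color convention for drawing direction boxes on movies:
#' red for upper right, blue for upper left, green for lower left and
#' yellow for lower right.
#'
#' @param label Integer labels in \code{0:3}.
#' @return Color names.
#' @export
direction_color <- function(label) {
  stopifnot(all(label %in% 0:3))
  c("red", "blue", "green", "yellow")[as.integer(label) + 1L]
}
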