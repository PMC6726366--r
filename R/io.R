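#' Write a movie as a multi-page 32-bit float TIFF
#'
#' @param movie H x W x T array (or a matrix for a single frame) with
#'   values in \[0, 1\].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  if (is.matrix(movie)) movie <- array(movie, dim = c(dim(movie), 1L))
  frames <- lapply(seq_len(dim(movie)[3]), function(t) movie[, , t])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' @param path TIFF file.
#' @return H x W x T array.
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]  # collapse any extra channels
    arr[, , t] <- f
  }
  arr
}

#' Write tracks CSV and its metadata sidecar
#'
#' Tracks are stored in the dialect the annotation tools read: a CSV with
#' header \code{cell_id,frame,x_px,y_px} (0-based frames, pixel
#' coordinates) and a JSON sidecar holding \code{pixel_size_um} and
#' \code{frame_interval_min}.
#'
#' @param tracks Data frame with columns \code{cell_id}, \code{frame},
#'   \code{x_px}, \code{y_px}.
#' @param path CSV output file.
#' @param pixel_size_um,frame_interval_min Acquisition metadata.
#' @param meta_path Sidecar path; defaults to \code{path} with a
#'   \code{.json} extension appended.
#' @return The CSV path, invisibly.
#' @export
write_tracks <- function(tracks, path, pixel_size_um, frame_interval_min,
                         meta_path = paste0(path, ".json")) {
  stopifnot(all(c("cell_id", "frame", "x_px", "y_px") %in% names(tracks)))
  write.csv(tracks[, c("cell_id", "frame", "x_px", "y_px")], path,
            row.names = FALSE)
  jsonlite::write_json(list(pixel_size_um = pixel_size_um,
                            frame_interval_min = frame_interval_min),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tracks CSV plus metadata sidecar
#'
#' @param path CSV file written by [write_tracks()] (or manual tracking
#'   exports using the same header).
#' @param meta_path JSON sidecar.
#' @return A list with \code{tracks} (data frame), \code{pixel_size_um}
#'   and \code{frame_interval_min}.
#' @export
read_tracks <- function(path, meta_path = paste0(path, ".json")) {
  tracks <- read.csv(path)
  stopifnot(all(c("cell_id", "frame", "x_px", "y_px") %in% names(tracks)))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  list(tracks = tracks, pixel_size_um = meta$pixel_size_um,
       frame_interval_min = meta$frame_interval_min)
}

#' Convert a tracks table to trajectory objects
#'
#' @param tracks Data frame \code{cell_id, frame, x_px, y_px}.
#' @param pixel_size_um Pixel size used to convert to micrometers.
#' @param frame_interval_min Acquisition interval.
#' @return A list of [cell_track()] objects, one per cell.
#' @export
tracks_to_trajectories <- function(tracks, pixel_size_um, frame_interval_min) {
  lapply(split(tracks, tracks$cell_id), function(d) {
    d <- d[order(d$frame), ]
    cell_track(d$cell_id[1], d$frame, d$x_px * pixel_size_um,
               d$y_px * pixel_size_um, frame_interval_min = frame_interval_min,
               pixel_size_um = pixel_size_um)
  })
}

#' Write an annotations table
#'
#' @param annotations Data frame as returned by [annotate_all()].
#' @param path CSV output file.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(annotations[, c("cell_id", "frame", "label", "delta_t_min",
                            "dx_um", "dy_um")], path, row.names = FALSE)
  invisible(path)
}
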