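#' Write a list of frames as a multi-page TIFF stack
#'
#' Intensities are scaled by `max_value` (default the full range of the
#' optics bit depth) into [0, 1] as required by the TIFF writer.
#'
#' @param frames List of numeric matrices (or a single matrix).
#' @param path Output file.
#' @param bit_depth Bits per sample (8 or 16).
#' @param max_value Intensity mapped to full scale; default `2^bit_depth - 1`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, bit_depth = 16,
                              max_value = 2^bit_depth - 1) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(f) {
    m <- pmin(pmax(f / max_value, 0), 1)
    matrix(as.numeric(m), nrow(f), ncol(f))
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @param max_value Scale applied to restore intensity units (inverse of
#'   [write_image_stack()]).
#' @return List of numeric matrices.
#' @export
read_image_stack <- function(path, max_value = 2^16 - 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * max_value
  })
}

#' Write detections (or trajectories) to CSV
#'
#' Adds a radius-in-micrometres column from the pixel size.
#'
#' @param detections data.frame with at least `x`, `y`, `r`.
#' @param path Output CSV.
#' @param pixel_size um/px used for the `r_um` column.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path, pixel_size = 0.1) {
  out <- detections
  out$r_um <- out$r * pixel_size
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Detect droplets across a movie
#'
#' Runs [detect_droplets()] on every frame and row-binds the results with a
#' 0-based `frame` column, ready for [link_trajectories()].
#'
#' @param frames List of matrices.
#' @param ... Passed to [detect_droplets()].
#' @return data.frame of detections with a `frame` column.
#' @export
detect_movie <- function(frames, ...) {
  out <- lapply(seq_along(frames), function(i) {
    d <- detect_droplets(frames[[i]], ...)
    if (nrow(d) > 0) cbind(frame = i - 1L, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      r = numeric(), score = numeric(), integrated = numeric(),
                      mean_interior = numeric(), pixel_count = integer())
  out
}
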