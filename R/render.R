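# Synthetic video rendering: cells as Gaussian spots on a uniform static
# background with additive Gaussian read noise, quantized to 8 bits. A
# rendered stack plus its ground-truth track table is the fixture every
# tracker test runs against.

#' Render per-frame cell positions as an 8-bit image stack
#'
#' Each frame is `background_level + sum of Gaussian spots + noise`, rounded
#' and clipped to 0..255. Spots have amplitude `cell_amplitude` and width
#' `psf_sigma` (px). The same inputs and seed give a bit-identical stack.
#'
#' @param track_tbl Per-frame positions, e.g. from [fov_track_table()]:
#'   columns `cell_id`, `frame` (0-based), `x_um`, `y_um` in FOV coordinates.
#' @param cfg A [render_config()].
#' @param n_frames Number of frames; default `max(frame) + 1`.
#' @return An object of class `image_stack`: a list of integer matrices
#'   (rows = y, columns = x) with attributes `frame_rate` and `pixel_size`.
#' @export
render_video <- function(track_tbl, cfg, n_frames = NULL) {
  stopifnot(inherits(cfg, "render_config"))
  if (cfg$pixel_size <= 0) stopf("pixel_size must be > 0")
  if (is.null(n_frames)) {
    n_frames <- if (nrow(track_tbl)) max(track_tbl$frame) + 1L else 1L
  }
  h <- cfg$image_height
  w <- cfg$image_width
  half <- ceiling(4 * cfg$psf_sigma)
  krange <- -half:half
  by_frame <- split(track_tbl, track_tbl$frame)

  with_seed(cfg$seed, {
    stack <- vector("list", n_frames)
    for (f in seq_len(n_frames) - 1L) {
      img <- matrix(cfg$background_level, nrow = h, ncol = w)
      dets <- by_frame[[as.character(f)]]
      if (!is.null(dets)) {
        for (j in seq_len(nrow(dets))) {
          x0 <- dets$x_um[j] / cfg$pixel_size
          y0 <- dets$y_um[j] / cfg$pixel_size
          cx <- round(x0)
          cy <- round(y0)
          xs <- cx + krange
          ys <- cy + krange
          okx <- xs >= 0 & xs < w
          oky <- ys >= 0 & ys < h
          if (!any(okx) || !any(oky)) next
          gx <- exp(-(xs[okx] - x0)^2 / (2 * cfg$psf_sigma^2))
          gy <- exp(-(ys[oky] - y0)^2 / (2 * cfg$psf_sigma^2))
          spot <- cfg$cell_amplitude * outer(gy, gx)
          ri <- ys[oky] + 1L
          ci <- xs[okx] + 1L
          img[ri, ci] <- img[ri, ci] + spot
        }
      }
      if (cfg$noise_sigma > 0)
        img <- img + matrix(rnorm(h * w, 0, cfg$noise_sigma), h, w)
      stack[[f + 1L]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
    }
    structure(stack, class = "image_stack",
              frame_rate = cfg$frame_rate, pixel_size = cfg$pixel_size)
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px @ %g fps, %g um/px\n",
              length(x), d[2], d[1], attr(x, "frame_rate"),
              attr(x, "pixel_size")))
  invisible(x)
}

#' Write an image stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack An `image_stack` (list of integer matrices, 0..255).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack, function(m) m / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param frame_rate,pixel_size Acquisition metadata to attach (TIFF files do
#'   not carry them).
#' @return An `image_stack`.
#' @export
read_stack <- function(path, frame_rate = 25, pixel_size = 1.3) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- lapply(pages, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]  # tolerate grey written as RGB
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  structure(stack, class = "image_stack",
            frame_rate = frame_rate, pixel_size = pixel_size)
}
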