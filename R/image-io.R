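# TIFF z-stack I/O.  Volumes are stored one z-slice per TIFF directory as
# 16-bit grayscale; intensities are scaled into [0, 1] by `scale` on write
# and multiplied back on read, so quantification (which is invariant to
# global intensity scaling) is unaffected.

#' Write a 3D volume as a multi-page TIFF
#'
#' @param vol 3D numeric array (x, y, z), non-negative.
#' @param path Output path.
#' @param scale Value mapped to full scale; defaults to `max(vol)`.
#' @return Invisibly, `path`.
#' @export
write_volume_tiff <- function(vol, path, scale = NULL) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L, all(vol >= 0))
  scale <- scale %||% max(vol, 1e-12)
  slices <- lapply(seq_len(dim(vol)[3L]), function(z) {
    pmin(vol[, , z] / scale, 1)
  })
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a 3D volume
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param scale Value to multiply the `[0, 1]` sample range back to
#'   (default 1).
#' @return 3D numeric array (x, y, z).
#' @export
read_volume_tiff <- function(path, scale = 1) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) {
    slices <- list(slices)
  }
  slices <- lapply(slices, function(s) {
    if (length(dim(s)) == 3L) s[, , 1L] else s
  })
  d <- dim(slices[[1L]])
  vol <- array(0, dim = c(d[1L], d[2L], length(slices)))
  for (z in seq_along(slices)) {
    vol[, , z] <- slices[[z]]
  }
  vol * scale
}
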