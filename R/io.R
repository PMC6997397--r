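#' Read / write clonogenic record CSVs
#'
#' The clonogenic dialect has header columns \code{cell_line, dose_gy, cem43,
#' n_plated, n_colonies, plating_efficiency} (UTF-8, '.' decimal separator).
#'
#' @param path file path.
#' @return \code{readClonogenicCSV}: validated data.frame.
#' @export
readClonogenicCSV <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  validateClonogenicRecords(rec)
  rec
}

#' @rdname readClonogenicCSV
#' @param records clonogenic data.frame to write.
#' @export
writeClonogenicCSV <- function(records, path) {
  validateClonogenicRecords(records)
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame metrics to CSV
#'
#' Columns: \code{frame_id, time_h, centroid_row, centroid_col,
#' mean_diameter_um, area_um2, mean_pi, d000 ... d175, fragmented}.
#'
#' @param metrics data.frame of rows from [quantifyFrame()].
#' @param path file path.
#' @export
writeMetricsCSV <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMetricsCSV
#' @export
readMetricsCSV <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write a growth curve to CSV (day, mean, sem, n)
#'
#' @param curve a [GrowthCurve-class].
#' @param path file path.
#' @export
writeGrowthCurveCSV <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Write a two-channel time-lapse as a multi-page TIFF
#'
#' Pages alternate phase, PI per frame (channel order phase first).
#' Intensities are stored as 32-bit floats divided by \code{intensityScale},
#' because TIFF float storage is only defined on [0, 1]; the companion reader
#' multiplies the same scale back. The default headroom scale of 4 is exact
#' in binary floating point, so the round trip is lossless up to float-32
#' quantization.
#'
#' @param frames list of [SpheroidFrame-class].
#' @param path output .tif path.
#' @param intensityScale headroom divisor applied on write and re-applied on
#'   read (default 4; use the same value in both directions).
#' @export
writeTimeLapseTIFF <- function(frames, path, intensityScale = 4) {
  pages <- unlist(lapply(frames, function(f)
    list(f@phase / intensityScale, f@pi / intensityScale)),
    recursive = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname writeTimeLapseTIFF
#' @param pixelSize microns per pixel of the stored frames.
#' @param timesHours acquisition times (hours) for the frames, recycled.
#' @return \code{readTimeLapseTIFF}: list of [SpheroidFrame-class].
#' @export
readTimeLapseTIFF <- function(path, pixelSize = 1, timesHours = NULL,
                              intensityScale = 4) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  pages <- lapply(pages, function(p) p * intensityScale)
  if (length(pages) %% 2 != 0)
    stop("expected an even number of TIFF pages (phase, PI per frame)")
  nf <- length(pages) / 2
  if (is.null(timesHours)) timesHours <- rep(0, nf)
  timesHours <- rep_len(timesHours, nf)
  lapply(seq_len(nf), function(i) {
    spheroidFrame(phase = pages[[2 * i - 1]], pi = pages[[2 * i]],
                  pixelSize = pixelSize, timeHours = timesHours[i])
  })
}

#' Read a two-channel frame from PNG files
#'
#' @param phasePath,piPath PNG paths for the two channels.
#' @param pixelSize microns per pixel.
#' @param timeHours acquisition time.
#' @return A [SpheroidFrame-class].
#' @export
readFramePNG <- function(phasePath, piPath, pixelSize = 1, timeHours = 0) {
  ph <- png::readPNG(phasePath)
  pic <- png::readPNG(piPath)
  if (length(dim(ph)) == 3) ph <- ph[, , 1]
  if (length(dim(pic)) == 3) pic <- pic[, , 1]
  spheroidFrame(ph, pic, pixelSize = pixelSize, timeHours = timeHours)
}
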