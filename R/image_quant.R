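#' Segment the spheroid body in a frame
#'
#' Classical segmentation of the structural (phase) channel: Gaussian
#' smoothing, Otsu thresholding, morphological closing, hole filling, and
#' retention of the largest connected component. Shed-cell debris (the corona)
#' is excluded by the largest-component rule; set \code{mergeCorona = TRUE} to
#' dilate and merge nearby components instead, e.g. to study the corona's
#' contribution to apparent size.
#'
#' The procedure is fully deterministic.
#'
#' @param frame a [SpheroidFrame-class].
#' @param sigma Gaussian smoothing sigma in pixels (default 2).
#' @param brushSize diameter (pixels, odd) of the disc brush used for
#'   morphological closing (default 5).
#' @param foreground \code{"bright"} (default) when the spheroid is brighter
#'   than the background, \code{"dark"} otherwise.
#' @param mergeCorona logical; merge nearby components via dilation before
#'   picking the largest component (default FALSE).
#' @return Logical matrix of the mask, with attributes \code{nComponents}
#'   (number of candidate components before the largest-component rule) and
#'   \code{fragmented} (TRUE when more than one component was present).
#' @examples
#' ph <- matrix(0.1, 64, 64)
#' rr <- row(ph) - 32; cc <- col(ph) - 32
#' ph[rr^2 + cc^2 <= 20^2] <- 1
#' fr <- spheroidFrame(ph, matrix(0, 64, 64))
#' mask <- segmentSpheroid(fr)
#' sum(mask) / (pi * 20^2)   # close to 1
#' @export
segmentSpheroid <- function(frame, sigma = 2, brushSize = 5,
                            foreground = c("bright", "dark"),
                            mergeCorona = FALSE) {
  stopifnot(is(frame, "SpheroidFrame"))
  foreground <- match.arg(foreground)
  img <- frame@phase
  if (sigma > 0) img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  rng <- range(img)
  if (rng[2] - rng[1] <= .Machine$double.eps)
    stop("no spheroid detected: the phase channel is constant")
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  if (foreground == "dark") norm <- 1 - norm
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr
  if (!any(bw)) stop("no spheroid detected: empty foreground after thresholding")

  kern <- EBImage::makeBrush(if (brushSize %% 2 == 1) brushSize else brushSize + 1,
                             shape = "disc")
  bwi <- EBImage::Image(bw * 1)
  bwi <- EBImage::closing(bwi, kern)
  if (mergeCorona) bwi <- EBImage::dilate(bwi, kern)
  bwi <- EBImage::fillHull(bwi)
  lab <- EBImage::bwlabel(bwi)
  labm <- as.matrix(lab)
  ncomp <- max(labm)
  if (ncomp == 0) stop("no spheroid detected: no connected component found")
  sizes <- tabulate(labm[labm > 0], nbins = ncomp)
  keep <- which.max(sizes)
  mask <- labm == keep
  if (mergeCorona) {
    # undo the merge dilation so the mask tracks the true contour
    er <- EBImage::erode(EBImage::Image(mask * 1), kern)
    mask <- as.matrix(er) > 0.5
    if (!any(mask)) mask <- labm == keep
  }
  attr(mask, "nComponents") <- ncomp
  attr(mask, "fragmented") <- ncomp > 1L
  mask
}

#' Measure 36 diameters through the centre of mass
#'
#' The spheroid diameter is the average of 36 diameters measured through the
#' centre of mass of the segmented area, one every five degrees over 180
#' degrees. Each diameter is the distance between the outermost mask crossings
#' along the line, which makes the measure robust to interior holes.
#'
#' Angles are counter-clockwise from the +column axis; coordinates are
#' (row, col) with origin at the top-left pixel.
#'
#' @param mask logical matrix (from [segmentSpheroid()] or ground truth).
#' @param pixelSize microns per pixel (default 1).
#' @param nAngles number of diameters (default 36, every 5 degrees over 180).
#' @param step ray-sampling step in pixels (default 0.25).
#' @return list with elements \code{centroid} (row, col in pixels),
#'   \code{diameters} (um, one per angle, named by angle in degrees),
#'   \code{meanDiameter} (um), \code{areaUm2} (um^2) and \code{fragmented}
#'   (carried over from the mask attribute, FALSE if absent).
#' @export
measureDiameters <- function(mask, pixelSize = 1, nAngles = 36, step = 0.25) {
  if (!is.logical(mask)) mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)            # (row, col)
  nr <- nrow(mask); nc <- ncol(mask)

  cr <- round(centroid[1]); cc <- round(centroid[2])
  if (cr < 1 || cr > nr || cc < 1 || cc > nc || !mask[cr, cc])
    warning("centre of mass lies outside the mask; diameters still measured")

  angles <- (seq_len(nAngles) - 1) * (180 / nAngles)
  th <- angles * pi / 180
  # direction in (row, col): CCW from +col axis with rows increasing downward
  dirs <- cbind(-sin(th), cos(th))

  outermost <- function(drow, dcol) {
    # distance to image border along the ray
    tmax <- Inf
    if (drow > 1e-12) tmax <- min(tmax, (nr - centroid[1]) / drow)
    if (drow < -1e-12) tmax <- min(tmax, (1 - centroid[1]) / drow)
    if (dcol > 1e-12) tmax <- min(tmax, (nc - centroid[2]) / dcol)
    if (dcol < -1e-12) tmax <- min(tmax, (1 - centroid[2]) / dcol)
    if (!is.finite(tmax) || tmax < 0) return(0)
    s <- seq(0, tmax, by = step)
    rr <- pmin(pmax(round(centroid[1] + s * drow), 1L), nr)
    ccol <- pmin(pmax(round(centroid[2] + s * dcol), 1L), nc)
    hit <- mask[cbind(rr, ccol)]
    if (!any(hit)) return(0)
    # distance to the centre of the outermost foreground pixel crossed,
    # projected onto the ray (avoids the half-pixel snap of raw sampling)
    i <- max(which(hit))
    (rr[i] - centroid[1]) * drow + (ccol[i] - centroid[2]) * dcol
  }

  diameters <- vapply(seq_len(nAngles), function(k) {
    (outermost(dirs[k, 1], dirs[k, 2]) +
       outermost(-dirs[k, 1], -dirs[k, 2])) * pixelSize
  }, numeric(1))
  names(diameters) <- sprintf("d%03d", round(angles))

  list(centroid = unname(centroid),
       diameters = diameters,
       meanDiameter = mean(diameters),
       areaUm2 = sum(mask) * pixelSize^2,
       fragmented = isTRUE(attr(mask, "fragmented")))
}

#' Mean fluorescence intensity
#'
#' Arithmetic mean of the PI channel, by default over the whole image (the
#' acquisition-faithful convention: overall mean intensity within each image).
#' A mask-restricted mode is provided because whole-image values depend on the
#' field of view; like the whole-image values, mask-restricted means should
#' only be compared between treatments imaged under identical settings.
#'
#' @param frame a [SpheroidFrame-class].
#' @param region \code{"image"} (default) or a logical matrix restricting the
#'   mean to a region.
#' @return Mean PI intensity (scalar).
#' @export
meanFluorescence <- function(frame, region = "image") {
  stopifnot(is(frame, "SpheroidFrame"))
  if (identical(region, "image")) return(mean(frame@pi))
  if (!is.logical(region)) region <- region > 0.5
  if (!identical(dim(region), dim(frame@pi)))
    stop("region mask shape does not match the frame")
  if (!any(region)) stop("empty region")
  mean(frame@pi[region])
}

# bilinear interpolation of matrix m at fractional (row, col) positions
.bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Radial PI line-profile average
#'
#' Line profiles are taken every 5 degrees (72 angles over 360 degrees by
#' default) through the given centre of mass of the Gaussian-filtered PI
#' channel, sampled at unit-pixel steps with bilinear interpolation from the
#' centre to the image edge. Profiles are aligned at radius 0 (the centre) and
#' averaged pointwise up to the shortest profile length.
#'
#' @param frame a [SpheroidFrame-class].
#' @param centroid centre of mass, (row, col) in pixels.
#' @param sigma Gaussian filter sigma in pixels (default 2; 0 disables
#'   filtering).
#' @param nAngles number of line profiles (default 72, every 5 degrees).
#' @return data.frame with columns \code{radius} (pixels, 0, 1, 2, ...) and
#'   \code{intensity} (mean PI across angles at that radius).
#' @export
radialProfile <- function(frame, centroid, sigma = 2, nAngles = 72) {
  stopifnot(is(frame, "SpheroidFrame"))
  nr <- nrow(frame@pi); nc <- ncol(frame@pi)
  if (length(centroid) != 2L || centroid[1] < 1 || centroid[1] > nr ||
      centroid[2] < 1 || centroid[2] > nc)
    stop("centroid must lie inside the image")
  img <- frame@pi
  if (sigma > 0) img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))

  th <- (seq_len(nAngles) - 1) * (2 * pi / nAngles)
  dirs <- cbind(-sin(th), cos(th))
  # shortest distance to border over all angles -> common profile length
  lens <- vapply(seq_len(nAngles), function(k) {
    drow <- dirs[k, 1]; dcol <- dirs[k, 2]
    tmax <- Inf
    if (drow > 1e-12) tmax <- min(tmax, (nr - centroid[1]) / drow)
    if (drow < -1e-12) tmax <- min(tmax, (1 - centroid[1]) / drow)
    if (dcol > 1e-12) tmax <- min(tmax, (nc - centroid[2]) / dcol)
    if (dcol < -1e-12) tmax <- min(tmax, (1 - centroid[2]) / dcol)
    tmax
  }, numeric(1))
  L <- floor(min(lens))
  radius <- 0:L
  prof <- matrix(0, nrow = length(radius), ncol = nAngles)
  for (k in seq_len(nAngles)) {
    rr <- centroid[1] + radius * dirs[k, 1]
    cc <- centroid[2] + radius * dirs[k, 2]
    prof[, k] <- .bilinear(img, rr, cc)
  }
  data.frame(radius = radius, intensity = rowMeans(prof))
}

#' Quantify a frame end to end
#'
#' Convenience wrapper: segment, measure diameters, and compute the mean PI
#' intensity, returning one metrics row in the package's CSV dialect.
#'
#' @param frame a [SpheroidFrame-class].
#' @param frameId identifier written into the row.
#' @param piRegion \code{"image"} (default) or \code{"mask"} for the PI mean.
#' @param ... passed to [segmentSpheroid()].
#' @return One-row data.frame with columns \code{frame_id, time_h,
#'   centroid_row, centroid_col, mean_diameter_um, area_um2, mean_pi,
#'   d000 ... d175, fragmented}.
#' @export
quantifyFrame <- function(frame, frameId = "frame", piRegion = "image", ...) {
  mask <- segmentSpheroid(frame, ...)
  m <- measureDiameters(mask, pixelSize = frame@pixelSize)
  mp <- if (identical(piRegion, "mask")) meanFluorescence(frame, mask)
        else meanFluorescence(frame)
  row <- data.frame(frame_id = frameId, time_h = frame@timeHours,
                    centroid_row = m$centroid[1], centroid_col = m$centroid[2],
                    mean_diameter_um = m$meanDiameter, area_um2 = m$areaUm2,
                    mean_pi = mp)
  dm <- as.data.frame(as.list(m$diameters))
  names(dm) <- names(m$diameters)
  cbind(row, dm, data.frame(fragmented = m$fragmented))
}
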