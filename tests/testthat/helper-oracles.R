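# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# rasterized disc mask: pixels whose centre lies within radius r of (cr, cc)
discMask <- function(n, r, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  (row(matrix(0, n, n)) - cr)^2 + (col(matrix(0, n, n)) - cc)^2 <= r^2
}

# axis-aligned ellipse mask with semi-axes (aRow, aCol)
ellipseMask <- function(n, aRow, aCol, cr = (n + 1) / 2, cc = (n + 1) / 2) {
  ((row(matrix(0, n, n)) - cr) / aRow)^2 +
    ((col(matrix(0, n, n)) - cc) / aCol)^2 <= 1
}

# brute-force diameter oracle: project every foreground pixel onto the line
# through the centroid at angle `deg` (CCW from +col axis) and take the span
# of projections among the pixels the line actually crosses (a unit square
# centred at perpendicular offset p is crossed iff |p| <= (|v_r| + |v_c|)/2)
rayMarchDiameterOracle <- function(mask, deg) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  th <- deg * pi / 180
  u <- c(-sin(th), cos(th))            # along-line direction (row, col)
  v <- c(cos(th), sin(th))             # perpendicular
  dr <- idx[, 1] - ctr[1]
  dc <- idx[, 2] - ctr[2]
  proj <- dr * u[1] + dc * u[2]
  perp <- dr * v[1] + dc * v[2]
  near <- abs(perp) <= (abs(v[1]) + abs(v[2])) / 2
  if (!any(near)) return(0)
  max(proj[near]) - min(proj[near])
}

# pixel-binned radial average: mean intensity by integer-rounded radius
annulusBinOracle <- function(img, ctr, maxR) {
  rad <- sqrt((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2)
  bins <- round(rad)
  keep <- bins <= maxR
  means <- tapply(img[keep], bins[keep], mean)
  data.frame(radius = as.integer(names(means)), intensity = as.numeric(means))
}

# independently coded Welch t-test (statistic, df and p from the t CDF)
welchOracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# closed-form normal equations for simple OLS
olsOracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, rSquared = r2)
}

# exhaustive bisection root-finder for monotone f on [lo, hi]
bisectionOracle <- function(f, lo, hi, iters = 200) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# noisy two-channel frame with a bright disc, for segmentation tests
noisyDiscFrame <- function(n = 256, r = 100, bg = 0.1, fg = 1.0,
                           noise = 0.02, seed = 1) {
  set.seed(seed)
  ph <- matrix(bg, n, n)
  m <- discMask(n, r)
  ph[m] <- fg
  ph <- pmax(ph + matrix(rnorm(n * n, 0, noise), n, n), 0)
  spheroidFrame(ph, matrix(0, n, n))
}

# run the render -> segment -> measure pipeline over a time-lapse and return
# measured vs ground-truth diameters per scan day
measureTimeLapse <- function(config, treatment, rcfg, scanDays, seed) {
  rows <- list()
  generateTimeLapse(config, treatment, rcfg, scanDays = scanDays, seed = seed,
                    frameCallback = function(frame, truthRow) {
                      mask <- segmentSpheroid(frame)
                      m <- measureDiameters(mask, pixelSize = frame@pixelSize)
                      rows[[length(rows) + 1L]] <<- data.frame(
                        day = truthRow$day, measured = m$meanDiameter,
                        truth = truthRow$diameter_um, meanPI = mean(frame@pi))
                    })
  do.call(rbind, rows)
}
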