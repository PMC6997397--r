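#' Assemble a daily-grid growth curve from repeat experiments
#'
#' Each repeat experiment contributes irregular scan times (days post
#' treatment) with the per-scan mean across its spheroids. Every repeat is
#' linearly interpolated onto the fixed daily grid 0..21; no extrapolation is
#' performed beyond a repeat's first or last scan (those grid days are marked
#' missing for that repeat). The grid-wise mean and standard error of the mean
#' are then taken over the repeats with data on each day.
#'
#' @param series list of repeats, each a data.frame with columns \code{day}
#'   (strictly increasing scan times in [0, 21]) and \code{value}.
#' @param units unit label stored in the curve (default "um").
#' @return A [GrowthCurve-class]. The publication-grade flag is TRUE when
#'   every grid day with data has at least three contributing repeats.
#' @examples
#' rep1 <- data.frame(day = c(0, 5, 12, 21), value = 300 + 20 * c(0, 5, 12, 21))
#' assembleGrowthCurve(list(rep1, rep1, rep1))
#' @export
assembleGrowthCurve <- function(series, units = "um") {
  if (!length(series)) stop("at least one repeat series is required")
  days <- 0:21
  vals <- vapply(seq_along(series), function(i) {
    s <- series[[i]]
    if (!all(c("day", "value") %in% names(s)))
      stop("repeat ", i, " must have columns 'day' and 'value'")
    if (nrow(s) < 2L)
      stop("repeat ", i, " has a single scan time; at least two are required ",
           "for interpolation")
    if (any(diff(s$day) <= 0))
      stop("repeat ", i, ": scan times must be strictly increasing")
    if (any(s$day < 0 | s$day > 21))
      stop("repeat ", i, ": scan times must lie within [0, 21] days")
    approx(s$day, s$value, xout = days, rule = 1)$y   # rule 1: NA outside
  }, numeric(length(days)))
  vals <- matrix(vals, nrow = length(days))
  n <- as.integer(rowSums(!is.na(vals)))
  mu <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  sdv <- apply(vals, 1, function(r) if (sum(!is.na(r)) >= 2) sd(r, na.rm = TRUE) else NA_real_)
  sem <- ifelse(n >= 2, sdv / sqrt(n), NA_real_)
  new("GrowthCurve", day = days, mean = as.numeric(mu), sem = as.numeric(sem),
      nRepeats = n, units = units,
      publicationGrade = all(n[n > 0] >= 3L) && any(n > 0))
}

#' Peak mean PI intensity within a window
#'
#' Maximum of the mean PI curve within the given post-treatment window and the
#' day at which it occurs; ties are broken towards the earliest day. The
#' default window is the first week post treatment (days 0-7).
#'
#' @param curve a [GrowthCurve-class] of PI intensities.
#' @param window two-day window \code{c(from, to)} within [0, 21], default
#'   \code{c(0, 7)}.
#' @return list with \code{peak} (intensity) and \code{day}.
#' @export
peakPI <- function(curve, window = c(0, 7)) {
  stopifnot(is(curve, "GrowthCurve"))
  if (length(window) != 2L || window[1] < 0 || window[2] > 21 ||
      window[1] > window[2])
    stop("window must be c(from, to) within [0, 21]")
  sel <- curve@day >= window[1] & curve@day <= window[2] & !is.na(curve@mean)
  if (!any(sel)) stop("no defined PI values within the window")
  v <- curve@mean[sel]; d <- curve@day[sel]
  i <- which.max(v)                    # which.max returns the first maximum
  list(peak = v[i], day = d[i])
}

#' Regress peak response on biological effect
#'
#' Ordinary least squares of a response (e.g. peak PI intensity) on the
#' biological effect E = -ln(S) of the corresponding treatments, summarising
#' how strongly early cell-death readout tracks clonogenic effect.
#' R-squared is 1 - SS_res / SS_tot, with the convention R-squared = 0 for a
#' constant response.
#'
#' @param peaks numeric response values (>= 3).
#' @param effects biological effects from [biologicalEffect()], same length.
#' @return list with \code{slope}, \code{intercept}, \code{rSquared}.
#' @export
regressEffect <- function(peaks, effects) {
  if (length(peaks) != length(effects)) stop("peaks and effects differ in length")
  if (length(peaks) < 3L) stop("at least 3 points are required")
  if (var(effects) == 0) stop("zero variance in effects")
  if (var(peaks) == 0) {
    return(list(slope = 0, intercept = mean(peaks), rSquared = 0))
  }
  fit <- lm(peaks ~ effects)
  res <- sum(fit$residuals^2)
  tot <- sum((peaks - mean(peaks))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       rSquared = 1 - res / tot)
}

# first (interpolated) day at which a curve reaches a threshold; Inf if never
.crossingDay <- function(curve, threshold) {
  v <- curve@mean; d <- curve@day
  ok <- !is.na(v)
  v <- v[ok]; d <- d[ok]
  if (!length(v)) return(Inf)
  if (v[1] >= threshold) return(d[1])
  hit <- which(v >= threshold)
  if (!length(hit)) return(Inf)
  i <- hit[1]
  # linear interpolation between grid days i-1 and i
  d[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) * (d[i] - d[i - 1])
}

#' Growth delay relative to a control curve
#'
#' Time difference (days) between a treated and a control growth curve first
#' reaching a threshold diameter, with linear interpolation between grid days.
#' A treated curve that never reaches the threshold within the observation
#' window corresponds to growth control and returns \code{Inf}.
#'
#' @param curve treated [GrowthCurve-class].
#' @param control control [GrowthCurve-class]; must reach the threshold.
#' @param thresholdUm threshold diameter (um).
#' @return Delay in days (possibly \code{Inf} = not reached).
#' @export
growthDelay <- function(curve, control, thresholdUm) {
  tc <- .crossingDay(control, thresholdUm)
  if (!is.finite(tc))
    stop("control curve never reaches the threshold within 21 days")
  tt <- .crossingDay(curve, thresholdUm)
  tt - tc
}

#' Classify the post-treatment growth regime
#'
#' Assigns one of five qualitative regimes to a diameter growth curve:
#' \itemize{
#'   \item \code{control-like growth}: (near-)monotone increase;
#'   \item \code{transient-swelling-then-shrinkage}: a local maximum above the
#'     day-0 diameter followed by a drop of at least \code{swellDrop} of the
#'     maximum - the hyperthermia signature of structural loosening followed
#'     by shedding/disintegration (regrowth, when present, is reported in the
#'     \code{regrowth} attribute);
#'   \item \code{shrinkage-then-regrowth}: a minimum below the day-0 diameter
#'     followed by a sustained rise over at least \code{riseDays} consecutive
#'     days;
#'   \item \code{monotone-shrinkage}: non-increasing decline;
#'   \item \code{growth-control}: final diameter at or below day 0 with no
#'     regrowth.
#' }
#' A relative tolerance absorbs measurement noise in the comparisons.
#'
#' @param curve diameter [GrowthCurve-class] on the full grid.
#' @param piCurve optional PI [GrowthCurve-class]; when given, the peak-PI day
#'   (window days 0-7) is attached as attribute \code{peakPIDay}.
#' @param swellDrop fractional drop from the swelling maximum that qualifies
#'   as shrinkage (default 0.15).
#' @param riseDays consecutive rising days that qualify as regrowth (default 3).
#' @param relTol relative noise tolerance on diameter comparisons (default
#'   0.03 of the day-0 value).
#' @return Character regime label with attributes \code{regrowth} (logical)
#'   and, when \code{piCurve} is given, \code{peakPIDay}.
#' @export
classifyRegime <- function(curve, piCurve = NULL, swellDrop = 0.15,
                           riseDays = 3, relTol = 0.03) {
  stopifnot(is(curve, "GrowthCurve"))
  v <- curve@mean
  if (any(is.na(v))) stop("regime classification requires a fully defined curve")
  d0 <- v[1]
  tol <- relTol * d0
  tolDay <- tol / riseDays

  # regrowth: >= riseDays consecutive rising days after the global minimum,
  # with a cumulative rise exceeding the noise tolerance
  m <- which.min(v)
  regrew <- FALSE
  if (m < length(v) - riseDays + 1) {
    inc <- diff(v)[m:(length(v) - 1)]
    run <- 0
    for (j in seq_along(inc)) {
      run <- if (inc[j] > tolDay) run + 1 else 0
      if (run >= riseDays) { regrew <- TRUE; break }
    }
  }

  # swelling: a value above day-0 followed by a >= swellDrop fractional drop
  swell <- FALSE
  if (length(v) > 2) {
    for (i in 2:(length(v) - 1)) {
      if (v[i] > d0 + tol && min(v[(i + 1):length(v)]) <= v[i] * (1 - swellDrop)) {
        swell <- TRUE; break
      }
    }
  }

  label <-
    if (swell) "transient-swelling-then-shrinkage"
    else if (min(v) < d0 - tol && regrew) "shrinkage-then-regrowth"
    else if (all(diff(v) <= tolDay) && v[length(v)] < d0 - tol) "monotone-shrinkage"
    else if (v[length(v)] <= d0 + tol && !regrew) "growth-control"
    else "control-like growth"

  attr(label, "regrowth") <- regrew
  if (!is.null(piCurve)) {
    pk <- tryCatch(peakPI(piCurve), error = function(e) NULL)
    if (!is.null(pk)) attr(label, "peakPIDay") <- pk$day
  }
  label
}

#' Compare two treatment groups at a fixed day
#'
#' Two-sided unpaired Welch t-test on per-repeat values (e.g. day-21
#' diameters) of two treatment groups.
#'
#' @param a,b numeric vectors of per-repeat values, each of length >= 2.
#' @param labels optional character(2) group labels.
#' @return list with \code{labels}, \code{t}, \code{df} and \code{p}.
#' @export
compareGroups <- function(a, b, labels = c("A", "B")) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 repeats")
  tt <- t.test(a, b, var.equal = FALSE)
  list(labels = labels, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
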