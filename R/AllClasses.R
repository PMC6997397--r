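#' @import methods
#' @importFrom stats approx lm coef vcov rnorm rpois runif sd setNames t.test uniroot var pt
#' @importFrom utils read.csv write.csv
NULL

#' Thermal exposure as an ordered list of temperature plateaus
#'
#' Represents a heating protocol as consecutive constant-temperature segments.
#' The thermal-dose concept used downstream is validated for temperatures up to
#' 50 degrees C, so segment temperatures are restricted to [20, 50] degrees C.
#'
#' @slot segments data.frame with columns \code{temp_c} (degrees Celsius) and
#'   \code{minutes} (segment duration, > 0), in exposure order.
#'
#' @seealso [computeCEM43()]
#' @export
setClass("ThermalExposure", representation(segments = "data.frame"))

setValidity("ThermalExposure", function(object) {
  s <- object@segments
  if (!all(c("temp_c", "minutes") %in% names(s)))
    return("segments must have columns 'temp_c' and 'minutes'")
  if (nrow(s) == 0L) return("exposure must contain at least one segment")
  if (!all(is.finite(s$minutes)) || any(s$minutes <= 0))
    return("every segment duration must be a finite value > 0 minutes")
  if (!all(is.finite(s$temp_c)) || any(s$temp_c < 20 | s$temp_c > 50))
    return("segment temperatures must lie in [20, 50] degrees C (validity range of the thermal-dose concept)")
  TRUE
})

#' Construct a ThermalExposure
#'
#' @param temp_c numeric vector of segment temperatures (degrees C, in [20, 50]).
#' @param minutes numeric vector of segment durations (minutes, > 0), recycled
#'   against \code{temp_c}.
#' @return A [ThermalExposure-class] object.
#' @examples
#' thermalExposure(47, 15)                      # single plateau
#' thermalExposure(c(45, 41), c(10, 16))        # ramped protocol
#' @export
thermalExposure <- function(temp_c, minutes) {
  new("ThermalExposure",
      segments = data.frame(temp_c = as.numeric(temp_c),
                            minutes = as.numeric(minutes)))
}

#' Treatment specification: radiation dose plus thermal dose
#'
#' The independent variable of every analysis in the package: a single-fraction
#' radiation dose in Gy combined with a thermal dose in CEM43 (cumulative
#' equivalent minutes at 43 degrees C). Sequencing information (e.g. the gap
#' between irradiation and heating) is carried as free-form metadata only and
#' is not modelled.
#'
#' @slot radiationGy non-negative radiation dose (Gy).
#' @slot cem43 non-negative thermal dose (CEM43).
#' @slot metadata list of informational fields (label, sequence, gap, ...).
#' @export
setClass("TreatmentSpec",
         representation(radiationGy = "numeric", cem43 = "numeric",
                        metadata = "list"),
         prototype(radiationGy = 0, cem43 = 0, metadata = list()))

setValidity("TreatmentSpec", function(object) {
  if (length(object@radiationGy) != 1L || !is.finite(object@radiationGy) ||
      object@radiationGy < 0)
    return("radiationGy must be a single finite value >= 0")
  if (length(object@cem43) != 1L || !is.finite(object@cem43) ||
      object@cem43 < 0)
    return("cem43 must be a single finite value >= 0")
  TRUE
})

#' Construct a TreatmentSpec
#'
#' @param radiationGy radiation dose in Gy (>= 0).
#' @param cem43 thermal dose in CEM43 (>= 0); alternatively pass a
#'   [ThermalExposure-class] via \code{exposure} to have it converted.
#' @param exposure optional ThermalExposure converted with [computeCEM43()]
#'   (ignored when \code{cem43} is given directly).
#' @param label optional character label stored in metadata.
#' @param ... further metadata fields.
#' @return A [TreatmentSpec-class].
#' @examples
#' treatmentSpec(10)                      # 10 Gy RT alone
#' treatmentSpec(2, cem43 = 120)          # combined RTHT
#' treatmentSpec(0, exposure = thermalExposure(47, 15))
#' @export
treatmentSpec <- function(radiationGy = 0, cem43 = NULL, exposure = NULL,
                          label = NULL, ...) {
  if (is.null(cem43)) {
    cem43 <- if (is.null(exposure)) 0 else computeCEM43(exposure)
  }
  md <- list(...)
  if (!is.null(label)) md$label <- label
  new("TreatmentSpec", radiationGy = as.numeric(radiationGy),
      cem43 = as.numeric(cem43), metadata = md)
}

#' @describeIn TreatmentSpec-class radiation dose accessor (Gy).
#' @param object a TreatmentSpec.
#' @export
setGeneric("radiationGy", function(object) standardGeneric("radiationGy"))

#' @export
setMethod("radiationGy", "TreatmentSpec", function(object) object@radiationGy)

#' @describeIn TreatmentSpec-class thermal dose accessor (CEM43).
#' @export
setGeneric("thermalDose", function(object) standardGeneric("thermalDose"))

#' @export
setMethod("thermalDose", "TreatmentSpec", function(object) object@cem43)

setMethod("show", "TreatmentSpec", function(object) {
  lab <- object@metadata$label
  cat("TreatmentSpec:", if (!is.null(lab)) paste0("[", lab, "]") else "",
      object@radiationGy, "Gy +", object@cem43, "CEM43\n")
})

#' Parameters of the combined radiation + heat clonogenic-survival model
#'
#' Parametric family for the clonogenic surviving fraction after a combined
#' treatment of D Gy radiation and H CEM43 thermal dose:
#' \deqn{S(D, H) = \exp[-(a H + b H^2) - \alpha_0 (1 + c H) D - \beta D^2]}
#' i.e. a linear-quadratic radiation term, a linear-quadratic thermal-effect
#' term, and a linear heat sensitization of the radiation alpha. This is the
#' package's declared stand-in for cell-line-specific combined-survival models;
#' it is the minimal family capturing thermal-only kill, LQ radiation kill and
#' heat-induced radiosensitization while remaining fittable and invertible.
#'
#' @slot alpha0 radiation sensitivity alpha at zero thermal dose (1/Gy).
#' @slot beta quadratic radiation sensitivity (1/Gy^2).
#' @slot aThermal linear thermal kill coefficient (1/CEM43).
#' @slot bThermal quadratic thermal kill coefficient (1/CEM43^2).
#' @slot cSens fractional increase of alpha per unit thermal dose (1/CEM43).
#' @slot cellLine character label.
#' @seealso [survivalFraction()], [fitSurvivalParams()], [beqd()]
#' @export
setClass("SurvivalParams",
         representation(alpha0 = "numeric", beta = "numeric",
                        aThermal = "numeric", bThermal = "numeric",
                        cSens = "numeric", cellLine = "character"),
         prototype(alpha0 = 0, beta = 0, aThermal = 0, bThermal = 0,
                   cSens = 0, cellLine = "unspecified"))

setValidity("SurvivalParams", function(object) {
  v <- c(alpha0 = object@alpha0, beta = object@beta,
         aThermal = object@aThermal, bThermal = object@bThermal,
         cSens = object@cSens)
  if (any(lengths(list(object@alpha0, object@beta, object@aThermal,
                       object@bThermal, object@cSens)) != 1L))
    return("all parameters must be single values")
  if (any(!is.finite(v))) return("all parameters must be finite")
  if (any(v < 0))
    return(paste("negative parameter(s):",
                 paste(names(v)[v < 0], collapse = ", ")))
  TRUE
})

#' Construct SurvivalParams
#'
#' Defaults emulate an HCT116-like cell line: a 10 Gy dose or a ~240 CEM43
#' thermal dose each reduce clonogenic survival to roughly 1e-4, matching the
#' isoeffect level used for combined-treatment comparisons.
#'
#' @param alpha0,beta,aThermal,bThermal,cSens model coefficients (all >= 0),
#'   see [SurvivalParams-class].
#' @param cellLine label.
#' @return A [SurvivalParams-class].
#' @examples
#' sp <- survivalParams(alpha0 = 0.3, beta = 0.03)
#' survivalFraction(treatmentSpec(10), sp)   # exp(-6)
#' @export
survivalParams <- function(alpha0 = 0.5, beta = 0.042, aThermal = 0.02,
                           bThermal = 7.7e-5, cSens = 0.01,
                           cellLine = "HCT116-like") {
  new("SurvivalParams", alpha0 = alpha0, beta = beta, aThermal = aThermal,
      bThermal = bThermal, cSens = cSens, cellLine = cellLine)
}

setMethod("show", "SurvivalParams", function(object) {
  cat("SurvivalParams [", object@cellLine, "]\n", sep = "")
  cat(sprintf("  alpha0 = %.4g /Gy, beta = %.4g /Gy^2\n",
              object@alpha0, object@beta))
  cat(sprintf("  aThermal = %.4g /CEM43, bThermal = %.4g /CEM43^2, cSens = %.4g /CEM43\n",
              object@aThermal, object@bThermal, object@cSens))
})

#' Two-channel spheroid frame
#'
#' A single time-lapse frame: a phase-contrast-like structural channel and a
#' propidium-iodide (PI) fluorescence channel of the same shape, with pixel
#' size and the post-treatment acquisition time.
#'
#' @slot phase numeric matrix, non-negative intensities.
#' @slot pi numeric matrix, same shape as \code{phase}.
#' @slot pixelSize microns per pixel (> 0); the reference acquisition setting
#'   is 1 um/pixel.
#' @slot timeHours hours post treatment.
#' @export
setClass("SpheroidFrame",
         representation(phase = "matrix", pi = "matrix",
                        pixelSize = "numeric", timeHours = "numeric"),
         prototype(pixelSize = 1, timeHours = 0))

setValidity("SpheroidFrame", function(object) {
  if (!is.numeric(object@phase) || !is.numeric(object@pi))
    return("channels must be numeric matrices")
  if (!identical(dim(object@phase), dim(object@pi)))
    return("phase and pi channels must have the same shape")
  if (any(object@phase < 0) || any(object@pi < 0))
    return("channel intensities must be non-negative")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("pixelSize must be a single value > 0")
  TRUE
})

#' Construct a SpheroidFrame
#'
#' @param phase,pi numeric intensity matrices of identical shape.
#' @param pixelSize microns per pixel.
#' @param timeHours acquisition time, hours post treatment.
#' @return A [SpheroidFrame-class].
#' @export
spheroidFrame <- function(phase, pi, pixelSize = 1, timeHours = 0) {
  new("SpheroidFrame", phase = phase, pi = pi,
      pixelSize = as.numeric(pixelSize), timeHours = as.numeric(timeHours))
}

setMethod("show", "SpheroidFrame", function(object) {
  cat(sprintf("SpheroidFrame %dx%d px @ %g um/px, t = %g h post treatment\n",
              nrow(object@phase), ncol(object@phase), object@pixelSize,
              object@timeHours))
})

#' Daily-grid growth curve pooled over repeat experiments
#'
#' Mean value (spheroid diameter in um, or mean PI intensity) with standard
#' error of the mean on a fixed daily grid 0..21 days post treatment, pooled
#' across independent repeat experiments. SEM is only defined on days with at
#' least two contributing repeats; at least three repeats on every defined day
#' are required for the publication-grade flag.
#'
#' @slot day integer grid, 0..21.
#' @slot mean per-day mean (NA where no repeat has data).
#' @slot sem per-day standard error of the mean (NA where fewer than 2 repeats).
#' @slot nRepeats number of repeats contributing per day.
#' @slot units character, e.g. "um" or "PI intensity".
#' @slot publicationGrade logical, TRUE when every day with data has >= 3 repeats.
#' @export
setClass("GrowthCurve",
         representation(day = "integer", mean = "numeric", sem = "numeric",
                        nRepeats = "integer", units = "character",
                        publicationGrade = "logical"))

setValidity("GrowthCurve", function(object) {
  if (!identical(object@day, 0:21))
    return("day grid must be the integers 0..21")
  n <- length(object@day)
  if (length(object@mean) != n || length(object@sem) != n ||
      length(object@nRepeats) != n)
    return("mean, sem and nRepeats must have one entry per grid day")
  if (any(!is.na(object@sem) & object@nRepeats < 2L))
    return("sem must be NA on days with fewer than 2 repeats")
  TRUE
})

#' @describeIn GrowthCurve-class coerce to data.frame (day, mean, sem, n).
#' @param x a GrowthCurve.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "GrowthCurve", function(x, ...) {
  data.frame(day = x@day, mean = x@mean, sem = x@sem, n = x@nRepeats)
})

#' @describeIn GrowthCurve-class per-day mean values.
#' @param object a GrowthCurve.
#' @export
setGeneric("curveMean", function(object) standardGeneric("curveMean"))

#' @export
setMethod("curveMean", "GrowthCurve", function(object) object@mean)

#' @describeIn GrowthCurve-class per-day SEM values.
#' @export
setGeneric("curveSEM", function(object) standardGeneric("curveSEM"))

#' @export
setMethod("curveSEM", "GrowthCurve", function(object) object@sem)

setMethod("show", "GrowthCurve", function(object) {
  ok <- !is.na(object@mean)
  cat(sprintf("GrowthCurve (%s), %d/%d grid days defined, n = %s repeats%s\n",
              object@units, sum(ok), length(ok),
              paste(range(object@nRepeats[ok]), collapse = "-"),
              if (object@publicationGrade) ", publication grade" else ""))
})

#' Simulated spheroid population trajectory
#'
#' Deterministic compartmental trajectory of a treated spheroid at 4-hour
#' resolution over 21 days: proliferating (P), quiescent (Q), necrotic-core
#' (C) cells, radiation-doomed but still metabolically active cells (Dm),
#' dead-but-attached pools by death origin (Aht, Art), cumulative shed cells,
#' packing density and the resulting radius/diameter.
#'
#' @slot series data.frame, one row per time step (see [simulateSpheroid()]).
#' @slot config the SimConfig list used.
#' @slot treatment the [TreatmentSpec-class] applied at t = 0.
#' @export
setClass("SpheroidSim",
         representation(series = "data.frame", config = "list",
                        treatment = "TreatmentSpec"))

#' @describeIn SpheroidSim-class coerce to the underlying time-series data.frame.
#' @param x a SpheroidSim.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "SpheroidSim", function(x, ...) x@series)

setMethod("show", "SpheroidSim", function(object) {
  s <- object@series
  cat(sprintf("SpheroidSim: %d steps over %g days, diameter %g -> %g um\n",
              nrow(s), max(s$t_hours) / 24,
              round(s$diameter_um[1], 1), round(s$diameter_um[nrow(s)], 1)))
  show(object@treatment)
})
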