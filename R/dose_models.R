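#' Cumulative equivalent minutes at 43 degrees C (CEM43)
#'
#' Converts an arbitrary time-temperature exposure into the equivalent heating
#' time at the reference temperature of 43 degrees C, using the standard
#' per-degree compounding rule
#' \deqn{CEM_{43} = \sum_i t_i \, R^{(43 - T_i)}}
#' with a breakpoint at 43 degrees C: \code{rAbove} applies to segments above
#' 43 degrees C and \code{rBelow} at or below it. The classic convention is
#' R = 0.5 above and R = 0.25 below the breakpoint; both factors are exposed
#' so cell-line-specific variants can be used.
#'
#' The measure is additive over segment concatenation.
#'
#' @param exposure a [ThermalExposure-class].
#' @param rAbove per-degree factor for T > 43 C, in (0, 1]; default 0.5.
#' @param rBelow per-degree factor for T <= 43 C, in (0, 1]; default 0.25.
#' @return Thermal dose in CEM43 (non-negative scalar).
#' @examples
#' computeCEM43(thermalExposure(43, 30))   # 30: 43 C is the reference
#' computeCEM43(thermalExposure(47, 15))   # 15 * 0.5^-4 = 240
#' @export
computeCEM43 <- function(exposure, rAbove = 0.5, rBelow = 0.25) {
  stopifnot(is(exposure, "ThermalExposure"))
  validObject(exposure)
  if (length(rAbove) != 1L || rAbove <= 0 || rAbove > 1)
    stop("rAbove must be a single value in (0, 1]")
  if (length(rBelow) != 1L || rBelow <= 0 || rBelow > 1)
    stop("rBelow must be a single value in (0, 1]")
  s <- exposure@segments
  r <- ifelse(s$temp_c > 43, rAbove, rBelow)
  sum(s$minutes * r^(43 - s$temp_c))
}

#' Clonogenic surviving fraction of a combined treatment
#'
#' Evaluates the combined radiation + heat survival model (see
#' [SurvivalParams-class]):
#' \deqn{S(D, H) = \exp[-(a H + b H^2) - \alpha_0 (1 + c H) D - \beta D^2]}
#' S(0, 0) = 1 and S is non-increasing in both the radiation dose D and the
#' thermal dose H.
#'
#' @param treatment a [TreatmentSpec-class].
#' @param params a [SurvivalParams-class].
#' @return Surviving fraction in (0, 1].
#' @export
survivalFraction <- function(treatment, params) {
  stopifnot(is(treatment, "TreatmentSpec"), is(params, "SurvivalParams"))
  validObject(treatment); validObject(params)
  D <- treatment@radiationGy
  H <- treatment@cem43
  exp(-(params@aThermal * H + params@bThermal * H^2) -
        (params@alpha0 * (1 + params@cSens * H) * D + params@beta * D^2))
}

#' Biological effect of a surviving fraction
#'
#' The biological effect is the negative logarithm of clonogenic survival,
#' E = -ln(S): the additive scale on which isoeffective treatments are matched.
#'
#' @param s surviving fraction(s) in (0, 1].
#' @return E = -log(s), >= 0.
#' @examples
#' biologicalEffect(1e-4)   # 4 log10 units: 9.2103...
#' @export
biologicalEffect <- function(s) {
  if (any(!is.finite(s) | s <= 0 | s > 1))
    stop("surviving fractions must lie in (0, 1]")
  -log(s)
}

# biological effect of a treatment computed directly on the log scale
# (avoids survival underflow at extreme doses)
.treatmentEffect <- function(D, H, params) {
  (params@aThermal * H + params@bThermal * H^2) +
    params@alpha0 * (1 + params@cSens * H) * D + params@beta * D^2
}

#' Validate a table of clonogenic records
#'
#' Checks the clonogenic CSV dialect: columns \code{cell_line, dose_gy, cem43,
#' n_plated, n_colonies, plating_efficiency}, with counts consistent and
#' plating efficiency in (0, 1].
#'
#' @param records data.frame of clonogenic records.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validateClonogenicRecords <- function(records) {
  need <- c("cell_line", "dose_gy", "cem43", "n_plated", "n_colonies",
            "plating_efficiency")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("clonogenic records are missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("clonogenic record table is empty")
  with(records, {
    if (any(dose_gy < 0) || any(cem43 < 0))
      stop("doses must be non-negative")
    if (any(n_plated <= 0) || any(n_colonies < 0))
      stop("counts must be positive (plated) / non-negative (colonies)")
    if (any(n_colonies > n_plated))
      stop("n_colonies cannot exceed n_plated")
    if (any(plating_efficiency <= 0 | plating_efficiency > 1))
      stop("plating_efficiency must lie in (0, 1]")
  })
  invisible(records)
}

#' Fit the combined survival model to clonogenic records
#'
#' Fits the [SurvivalParams-class] family by weighted least squares on the
#' biological-effect scale. Writing g = alpha0 * cSens, the model effect
#' -ln S = a H + b H^2 + alpha0 D + g H D + beta D^2 is linear in
#' (a, b, alpha0, g, beta), so the fit is an exact weighted linear regression;
#' cSens is recovered as g / alpha0 with a delta-method standard error.
#'
#' Weights are the colony counts, i.e. the inverse of the Poisson variance of
#' ln S (Var[ln N] ~ 1/N). Zero-colony records receive a +0.5 continuity
#' correction before the log transform.
#'
#' @param records clonogenic records data.frame (see
#'   [validateClonogenicRecords()]).
#' @param fixed named list fixing a subset of \code{alpha0, beta, aThermal,
#'   bThermal, cSens} at given values; fixed parameters are removed from the
#'   design and their contribution subtracted from the response.
#' @param cellLine label stored in the returned parameters (default: taken
#'   from the records when unique).
#' @return list with elements \code{params} (a [SurvivalParams-class], point
#'   estimates clamped at 0 to respect parameter-range invariants),
#'   \code{estimates} (raw unclamped named vector), \code{se} (standard
#'   errors), \code{rss} (weighted residual sum of squares), \code{df}
#'   (residual degrees of freedom) and \code{converged} (always TRUE for the
#'   closed-form fit; FALSE only if the design was rank-deficient, which
#'   raises an error instead).
#' @examples
#' sp <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0, bThermal = 0,
#'                      cSens = 0)
#' tr <- lapply(c(0, 2, 5, 10), treatmentSpec)
#' rec <- generateClonogenicDataset(sp, tr, nPlated = 1e5, nReps = 1,
#'                                  seed = 1, noiseless = TRUE)
#' fitSurvivalParams(rec, fixed = list(aThermal = 0, bThermal = 0, cSens = 0))
#' @export
fitSurvivalParams <- function(records, fixed = list(), cellLine = NULL) {
  validateClonogenicRecords(records)
  bad <- setdiff(names(fixed),
                 c("alpha0", "beta", "aThermal", "bThermal", "cSens"))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))

  D <- records$dose_gy
  H <- records$cem43
  ncol_adj <- ifelse(records$n_colonies == 0, 0.5, records$n_colonies)
  S <- pmin(ncol_adj / (records$n_plated * records$plating_efficiency), 1)
  E <- -log(S)                       # observed biological effect
  w <- ncol_adj                      # inverse variance of ln S (Poisson)

  fx <- function(p) if (p %in% names(fixed)) fixed[[p]] else NULL
  cols <- list()
  offset <- rep(0, length(E))

  addTerm <- function(name, column, value) {
    if (is.null(value)) cols[[name]] <<- column
    else offset <<- offset + value * column
  }
  addTerm("aThermal", H, fx("aThermal"))
  addTerm("bThermal", H^2, fx("bThermal"))

  a0fix <- fx("alpha0"); cfix <- fx("cSens")
  if (is.null(a0fix) && is.null(cfix)) {
    cols$alpha0 <- D
    cols$gSens <- H * D
  } else if (!is.null(a0fix) && is.null(cfix)) {
    offset <- offset + a0fix * D
    if (a0fix == 0) {
      if (any(H * D != 0))
        warning("alpha0 fixed at 0: cSens is inestimable and set to 0")
      fixed$cSens <- 0; cfix <- 0
    } else cols$cSens <- a0fix * H * D
  } else if (is.null(a0fix) && !is.null(cfix)) {
    cols$alpha0 <- D * (1 + cfix * H)
  } else {
    offset <- offset + a0fix * (1 + cfix * H) * D
  }
  addTerm("beta", D^2, fx("beta"))

  if (length(cols) == 0L) stop("no free parameters to fit")
  X <- do.call(cbind, cols)

  # informative-design checks
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X))
    stop("degenerate design: the dose points do not identify the free ",
         "parameters (", paste(names(cols), collapse = ", "), ")")
  if (length(unique(paste(D, H))) < ncol(X))
    stop("fewer informative dose points than free parameters")

  y <- E - offset
  fit <- lm(y ~ 0 + X, weights = w)
  est <- coef(fit)
  names(est) <- colnames(X)
  # vcov warns on zero-residual (noiseless) fits where SEs are moot
  V <- suppressWarnings(vcov(fit))
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))

  getp <- function(p, default = 0) {
    if (p %in% names(fixed)) fixed[[p]]
    else if (p %in% names(est)) unname(est[p])
    else default
  }
  alpha0 <- getp("alpha0")
  out_est <- c(alpha0 = alpha0, beta = getp("beta"),
               aThermal = getp("aThermal"), bThermal = getp("bThermal"))
  out_se <- c(alpha0 = if ("alpha0" %in% names(se)) se[["alpha0"]] else 0,
              beta = if ("beta" %in% names(se)) se[["beta"]] else 0,
              aThermal = if ("aThermal" %in% names(se)) se[["aThermal"]] else 0,
              bThermal = if ("bThermal" %in% names(se)) se[["bThermal"]] else 0)

  if ("gSens" %in% names(est)) {
    g <- unname(est["gSens"])
    if (alpha0 <= 0) {
      warning("fitted alpha0 <= 0: cSens undetermined, reported as 0")
      cS <- 0; cS_se <- NA_real_
    } else {
      cS <- g / alpha0
      # delta method on c = g/alpha0
      grad <- c(-g / alpha0^2, 1 / alpha0)
      Vsub <- V[c("alpha0", "gSens"), c("alpha0", "gSens")]
      cS_se <- sqrt(drop(t(grad) %*% Vsub %*% grad))
    }
    out_est <- c(out_est, cSens = cS)
    out_se <- c(out_se, cSens = cS_se)
  } else {
    out_est <- c(out_est, cSens = getp("cSens"))
    out_se <- c(out_se,
                cSens = if ("cSens" %in% names(se)) se[["cSens"]] else 0)
  }

  if (is.null(cellLine)) {
    cl <- unique(as.character(records$cell_line))
    cellLine <- if (length(cl) == 1L) cl else "mixed"
  }
  params <- new("SurvivalParams",
                alpha0 = max(0, out_est[["alpha0"]]),
                beta = max(0, out_est[["beta"]]),
                aThermal = max(0, out_est[["aThermal"]]),
                bThermal = max(0, out_est[["bThermal"]]),
                cSens = max(0, out_est[["cSens"]]),
                cellLine = cellLine)
  list(params = params, estimates = out_est, se = out_se,
       rss = sum(w * fit$residuals^2), df = fit$df.residual,
       converged = TRUE)
}

#' Biologically equivalent dose (BEQD)
#'
#' The radiation-only dose x producing the same biological effect E as a given
#' (possibly combined) treatment, i.e. the solution of
#' alpha0 * x + beta * x^2 = E. For beta > 0 the physical (positive) quadratic
#' root is used; for beta = 0 the linear inversion E / alpha0.
#'
#' By construction, the BEQD of a pure radiation treatment is its own dose.
#'
#' @param treatment a [TreatmentSpec-class].
#' @param params a [SurvivalParams-class] with alpha0 > 0 or beta > 0.
#' @return Equivalent radiation dose in Gy (>= 0).
#' @examples
#' sp <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0.025,
#'                      bThermal = 0, cSens = 0)
#' beqd(treatmentSpec(0, cem43 = 240), sp)   # thermal-only, E = 6 -> 10 Gy
#' @export
beqd <- function(treatment, params) {
  stopifnot(is(params, "SurvivalParams"))
  if (params@alpha0 == 0 && params@beta == 0)
    stop("no radiation response defined: alpha0 and beta are both 0")
  validObject(treatment); validObject(params)
  E <- .treatmentEffect(treatment@radiationGy, treatment@cem43, params)
  if (E == 0) return(0)
  if (params@beta > 0) {
    (-params@alpha0 + sqrt(params@alpha0^2 + 4 * params@beta * E)) /
      (2 * params@beta)
  } else {
    E / params@alpha0
  }
}

#' Isoeffective (radiation, thermal) dose combinations
#'
#' For every radiation dose D on a grid whose radiation-only effect does not
#' already exceed the target, finds the unique thermal dose H >= 0 such that
#' the combined treatment (D, H) reproduces the target biological effect
#' exactly: -ln S(D, H) = targetEffect. Monotonicity of the survival model in
#' H guarantees a unique root, located by 1-D root finding on [0, hMax] and
#' refined by bisection to the stated effect tolerance.
#'
#' Grid doses whose radiation-only effect exceeds the target (or for which the
#' target is unreachable within \code{hMax}) are omitted with a notice.
#'
#' @param targetEffect target biological effect E > 0 (e.g. 9.21 for a
#'   survival level of 1e-4).
#' @param params a [SurvivalParams-class].
#' @param radiationGrid radiation doses (Gy) to pair with thermal doses.
#' @param hMax upper bracket for the thermal dose (CEM43), default 1e5 - far
#'   beyond the experimentally relevant range (up to 780 CEM43).
#' @param tol tolerance on the achieved effect, default 1e-9.
#' @return data.frame with columns \code{dose_gy, cem43, effect, survival};
#'   every row satisfies |effect - targetEffect| <= tol.
#' @export
isoeffectCombinations <- function(targetEffect, params, radiationGrid,
                                  hMax = 1e5, tol = 1e-9) {
  stopifnot(is(params, "SurvivalParams"))
  if (!is.finite(targetEffect) || targetEffect <= 0)
    stop("targetEffect must be > 0")
  validObject(params)
  effectAt <- function(D, H) .treatmentEffect(D, H, params)
  rows <- lapply(radiationGrid, function(D) {
    f <- function(H) effectAt(D, H) - targetEffect
    e0 <- f(0)
    if (e0 > tol) {
      message(sprintf(
        "omitting D = %g Gy: radiation-only effect %.4g already exceeds target %.4g",
        D, e0 + targetEffect, targetEffect))
      return(NULL)
    }
    if (abs(e0) <= tol) {
      H <- 0
    } else {
      if (f(hMax) < 0) {
        message(sprintf(
          "omitting D = %g Gy: target effect unreachable within %g CEM43",
          D, hMax))
        return(NULL)
      }
      H <- uniroot(f, c(0, hMax), tol = 1e-12)$root
      lo <- max(0, H - 1e-6); hi <- min(hMax, H + 1e-6)
      if (f(lo) > 0) lo <- 0
      if (f(hi) < 0) hi <- hMax
      for (i in seq_len(200)) {
        if (abs(f(H)) <= tol * 0.5) break
        if (f(H) > 0) hi <- H else lo <- H
        H <- (lo + hi) / 2
      }
    }
    data.frame(dose_gy = D, cem43 = H, effect = effectAt(D, H),
               survival = exp(-effectAt(D, H)))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(dose_gy = numeric(0), cem43 = numeric(0),
                      effect = numeric(0), survival = numeric(0))
  out
}
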