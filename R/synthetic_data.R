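#' Simulation configuration for the compartmental spheroid model
#'
#' Returns a validated configuration list for [simulateSpheroid()]. The model
#' is a deliberately minimal compartment model of a treated spheroid: an outer
#' proliferating rim (P), a quiescent interior (Q), a necrotic core (C) once
#' the spheroid is large enough, radiation-doomed but still metabolically
#' active cells (Dm), dead-but-attached pools by death origin (Aht, Art) and a
#' cumulative shed-cell (corona) pool. Compartment boundaries are geometric
#' depths from the surface rather than computed oxygen fields.
#'
#' Defaults emulate the reference study conditions: ~300 um initial diameter
#' (about 4800 cells, no necrosis at treatment), 21-day observation at 4-hour
#' steps, heat killing all compartments uniformly with transient structural
#' loosening and fast shedding within days, radiation killing proliferating
#' cells after a mitosis-linked lag with slow surface shedding, and a growth
#' boost when the necrotic core is smaller than in a size-matched untreated
#' spheroid (reoxygenation).
#'
#' @param initialDiameterUm initial spheroid diameter (um); ~300 for small and
#'   ~550 for large spheroids.
#' @param lambda proliferation rate of rim cells (per day).
#' @param rimDepthUm proliferating rim thickness (um).
#' @param coreOnsetDepthUm depth from the surface beyond which quiescent cells
#'   become necrotic (um); 275 um means a 550 um spheroid has no core yet.
#' @param shedRateHT,shedRateRT shedding rate of dead-attached cells per day,
#'   by death origin.
#' @param shedDelayHT,shedDelayRT onset delay (days) before shedding starts.
#' @param looseningFactor maximal fractional decrease of packing density after
#'   heating, in [0, 1); scaled by the heat-killed fraction.
#' @param looseningRecoveryDays linear recovery time of packing density (days).
#' @param mitoticDeathLagDays mean lag between irradiation and mitosis-linked
#'   death of doomed cells (days).
#' @param reoxygenationBoost fractional proliferation increase when the
#'   necrotic core is below the size-matched untreated reference.
#' @param rho packing density (cells/um^3); default gives ~4800 cells at
#'   300 um diameter.
#' @param survivalParams a [SurvivalParams-class] driving treatment kill.
#' @param dtHours simulation step (hours), default 4 (the imaging cadence).
#' @param durationDays observation period (days), default 21.
#' @param seed integer seed consumed by the (stochastic) renderer and dataset
#'   generators; the population simulation itself is deterministic.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(initialDiameterUm = 300, lambda = 0.30,
                      rimDepthUm = 75, coreOnsetDepthUm = 275,
                      shedRateHT = 1.2, shedDelayHT = 2,
                      shedRateRT = 0.15, shedDelayRT = 0.5,
                      looseningFactor = 0.3, looseningRecoveryDays = 4,
                      mitoticDeathLagDays = 2.5, reoxygenationBoost = 0.3,
                      rho = 4800 / (4 / 3 * pi * 150^3),
                      survivalParams = spheroTx::survivalParams(),
                      dtHours = 4, durationDays = 21, seed = 1L) {
  cfg <- list(initialDiameterUm = initialDiameterUm, lambda = lambda,
              rimDepthUm = rimDepthUm, coreOnsetDepthUm = coreOnsetDepthUm,
              shedRateHT = shedRateHT, shedDelayHT = shedDelayHT,
              shedRateRT = shedRateRT, shedDelayRT = shedDelayRT,
              looseningFactor = looseningFactor,
              looseningRecoveryDays = looseningRecoveryDays,
              mitoticDeathLagDays = mitoticDeathLagDays,
              reoxygenationBoost = reoxygenationBoost, rho = rho,
              survivalParams = survivalParams, dtHours = dtHours,
              durationDays = durationDays, seed = as.integer(seed))
  rates <- c(lambda, rimDepthUm, coreOnsetDepthUm, shedRateHT, shedDelayHT,
             shedRateRT, shedDelayRT, looseningRecoveryDays,
             mitoticDeathLagDays, reoxygenationBoost, rho)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates, depths and delays must be finite and >= 0")
  if (initialDiameterUm <= 0) stop("initialDiameterUm must be > 0")
  if (looseningFactor < 0 || looseningFactor >= 1)
    stop("looseningFactor must lie in [0, 1)")
  if (dtHours <= 0 || durationDays <= 0)
    stop("dtHours and durationDays must be > 0")
  stopifnot(is(survivalParams, "SurvivalParams"))
  validObject(survivalParams)
  class(cfg) <- "SimConfig"
  cfg
}

.radiusFromCount <- function(n, rho) unname((3 * n / (4 * pi * rho))^(1 / 3))

# volume fraction of the rim shell and of the necrotic core for radius r
.shellFractions <- function(r, rimDepth, coreDepth) {
  r <- unname(r)
  fracRim <- 1 - (max(r - rimDepth, 0) / r)^3
  fracCore <- (max(r - coreDepth, 0) / r)^3
  c(rim = fracRim, core = fracCore)
}

#' Simulate a treated spheroid population
#'
#' Deterministic compartmental simulation at \code{dtHours} resolution over
#' \code{durationDays}. The state at t = 0 is the pre-treatment configuration;
#' the treatment pulse is applied at the start of the first step:
#' \enumerate{
#'   \item heating moves the fraction 1 - S_HT of P, Q and C alike into the
#'     dead-attached pool Aht (heat kill is independent of position and
#'     proliferation status) and transiently reduces packing density by
#'     \code{looseningFactor} scaled by the killed fraction, recovering
#'     linearly over \code{looseningRecoveryDays};
#'   \item radiation marks the fraction 1 - S_RT (with heat-sensitized alpha)
#'     of surviving P as doomed (Dm); doomed cells stop proliferating and die
#'     into Art with exponential timing (mean \code{mitoticDeathLagDays});
#'   \item each step, surviving P proliferates at \code{lambda}, boosted by
#'     \code{reoxygenationBoost} when the necrotic core is smaller than in a
#'     size-matched untreated spheroid; cells deeper than the rim become
#'     quiescent and cells beyond the core-onset depth necrose;
#'   \item dead-attached cells shed into the corona pool at the
#'     modality-specific rate after the modality-specific onset delay.
#' }
#' Cell counts are conserved exactly: the total over all pools (including
#' shed) changes only by births.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @param treatment a [TreatmentSpec-class] applied at t = 0.
#' @return A [SpheroidSim-class]; its series has columns \code{t_hours, P, Q,
#'   C, Dm, Aht, Art, shed, birthsCum, rho, nAttached, radius_um, diameter_um}.
#' @export
simulateSpheroid <- function(config, treatment) {
  if (!inherits(config, "SimConfig")) stop("config must come from simConfig()")
  stopifnot(is(treatment, "TreatmentSpec"))
  validObject(treatment)
  sp <- config$survivalParams
  dt <- config$dtHours / 24                   # days
  nSteps <- ceiling(config$durationDays / dt)
  rho0 <- config$rho

  r0 <- config$initialDiameterUm / 2
  N0 <- rho0 * 4 / 3 * pi * r0^3
  fr <- .shellFractions(r0, config$rimDepthUm, config$coreOnsetDepthUm)
  P <- unname(fr["rim"]) * N0
  C <- unname(fr["core"]) * N0
  Q <- N0 - P - C
  Dm <- 0; Aht <- 0; Art <- 0; Shed <- 0; births <- 0

  H <- treatment@cem43; D <- treatment@radiationGy
  Sht <- exp(-(sp@aThermal * H + sp@bThermal * H^2))
  killHT <- 1 - Sht
  alphaS <- sp@alpha0 * (1 + sp@cSens * H)
  Srt <- exp(-(alphaS * D + sp@beta * D^2))
  loosenAmp <- config$looseningFactor * killHT

  out <- matrix(NA_real_, nrow = nSteps + 1L, ncol = 13L)
  colnames(out) <- c("t_hours", "P", "Q", "C", "Dm", "Aht", "Art", "shed",
                     "birthsCum", "rho", "nAttached", "radius_um",
                     "diameter_um")
  record <- function(i, t, rhoT) {
    nAtt <- P + Q + C + Dm + Aht + Art
    r <- .radiusFromCount(nAtt, rhoT)
    out[i, ] <<- c(t * 24, P, Q, C, Dm, Aht, Art, Shed, births, rhoT, nAtt,
                   r, 2 * r)
  }
  record(1L, 0, rho0)                          # pre-treatment state

  # treatment pulse
  Aht <- killHT * (P + Q + C)
  P <- Sht * P; Q <- Sht * Q; C <- Sht * C
  Dm <- (1 - Srt) * P
  P <- Srt * P

  for (i in seq_len(nSteps)) {
    t <- i * dt
    rhoT <- rho0 * (1 - loosenAmp *
                      max(0, 1 - t / max(config$looseningRecoveryDays, 1e-9)))
    # reoxygenation boost: core deficit vs size-matched untreated reference
    nAtt <- P + Q + C + Dm + Aht + Art
    rNow <- .radiusFromCount(nAtt, rhoT)
    cRef <- unname(.shellFractions(rNow, config$rimDepthUm,
                                   config$coreOnsetDepthUm)["core"]) * nAtt
    deficit <- if (cRef > 0) max(0, 1 - C / cRef) else 0
    lambdaEff <- config$lambda * (1 + config$reoxygenationBoost * deficit)

    b <- P * lambdaEff * dt
    P <- P + b
    births <- births + b

    dDm <- Dm * min(1, dt / config$mitoticDeathLagDays)
    Dm <- Dm - dDm
    Art <- Art + dDm

    if (t > config$shedDelayHT) {
      s <- Aht * min(1, config$shedRateHT * dt)
      Aht <- Aht - s; Shed <- Shed + s
    }
    if (t > config$shedDelayRT) {
      s <- Art * min(1, config$shedRateRT * dt)
      Art <- Art - s; Shed <- Shed + s
    }

    # geometric reclassification at the new size
    nAtt <- P + Q + C + Dm + Aht + Art
    r <- .radiusFromCount(nAtt, rhoT)
    frt <- .shellFractions(r, config$rimDepthUm, config$coreOnsetDepthUm)
    pCap <- max(0, unname(frt["rim"]) * nAtt - Dm)
    moveQ <- max(0, P - pCap)
    P <- P - moveQ; Q <- Q + moveQ
    cTarget <- unname(frt["core"]) * nAtt
    moveC <- min(Q, max(0, cTarget - C))
    Q <- Q - moveC; C <- C + moveC

    record(i + 1L, t, rhoT)
  }
  new("SpheroidSim", series = as.data.frame(out), config = unclass(config),
      treatment = treatment)
}

#' Extract the simulated state nearest a given day
#'
#' @param sim a [SpheroidSim-class].
#' @param day day post treatment.
#' @return One-row data.frame of the series at the step closest to \code{day}.
#' @export
stateAtDay <- function(sim, day) {
  stopifnot(is(sim, "SpheroidSim"))
  s <- sim@series
  s[which.min(abs(s$t_hours - day * 24)), , drop = FALSE]
}

#' Renderer configuration
#'
#' Settings of the two-channel frame renderer: canvas geometry, phase-contrast
#' texture, PI intensities per dead-cell class with centre- or edge-weighted
#' radial ramps, corona annulus geometry and additive Gaussian noise.
#'
#' @param imageSizePx canvas side in pixels, or \code{"auto"} (resolved by
#'   [generateTimeLapse()] from the maximal spheroid extent).
#' @param pixelSizeUm microns per pixel (default 1, the reference resolution).
#' @param background phase background level.
#' @param discIntensity phase intensity of the spheroid body.
#' @param textureSd multiplicative speckle SD on the spheroid body.
#' @param edgeSoftnessPx sigmoid softness of the spheroid edge (pixels).
#' @param noiseSigma additive Gaussian noise SD on both channels.
#' @param piDeadHT,piDeadRT PI intensity per unit dead-attached fraction for
#'   heat- and radiation-origin deaths.
#' @param piCore PI intensity per unit necrotic-core fraction.
#' @param piRampSteepness steepness of the linear radial PI weighting
#'   (centre-weighted for heat deaths and the core, edge-weighted for
#'   radiation deaths).
#' @param coronaGapUm,coronaWidthUm gap between spheroid edge and corona, and
#'   corona annulus width (um).
#' @param coronaPhase,coronaPi peak phase/PI intensity of the corona annulus,
#'   scaled by the shed-cell fraction. The phase value is kept well below the
#'   spheroid body intensity so segmentation excludes the corona.
#' @param marginUm canvas margin beyond the corona (um).
#' @return A list of class \code{RenderConfig}.
#' @export
renderConfig <- function(imageSizePx = "auto", pixelSizeUm = 1,
                         background = 0.1, discIntensity = 1.0,
                         textureSd = 0.06, edgeSoftnessPx = 1.0,
                         noiseSigma = 0.02, piDeadHT = 1.0, piDeadRT = 0.7,
                         piCore = 0.5, piRampSteepness = 0.8,
                         coronaGapUm = 20, coronaWidthUm = 40,
                         coronaPhase = 0.25, coronaPi = 0.6, marginUm = 30) {
  cfg <- as.list(environment())
  if (!identical(imageSizePx, "auto") &&
      (!is.numeric(imageSizePx) || imageSizePx < 16))
    stop("imageSizePx must be 'auto' or a number >= 16")
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be > 0")
  num <- unlist(cfg[c("background", "discIntensity", "textureSd",
                      "edgeSoftnessPx", "noiseSigma", "piDeadHT", "piDeadRT",
                      "piCore", "piRampSteepness", "coronaGapUm",
                      "coronaWidthUm", "coronaPhase", "coronaPi", "marginUm")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all renderer intensities and geometry values must be >= 0")
  class(cfg) <- "RenderConfig"
  cfg
}

#' Render one two-channel frame from a simulated state
#'
#' Phase channel: textured disc of the state's radius plus a faint corona
#' annulus whose intensity scales with the shed-cell fraction. PI channel:
#' dead-attached intensity with a centre-weighted radial ramp for heat-origin
#' deaths and the necrotic core, an edge-weighted ramp for radiation-origin
#' deaths, plus the corona ring. Additive Gaussian noise is drawn from the
#' given seed; the biological content of the frame is fully determined by the
#' state.
#'
#' @param state one-row data.frame from a [SpheroidSim-class] series.
#' @param rcfg a \code{RenderConfig}; \code{imageSizePx} must be numeric here.
#' @param seed integer seed for the noise draws (NULL: use current RNG state).
#' @return list with \code{frame} (a [SpheroidFrame-class]), \code{mask}
#'   (ground-truth logical disc mask) and \code{diameterUm} (ground truth).
#' @export
renderFrame <- function(state, rcfg, seed = NULL) {
  if (!inherits(rcfg, "RenderConfig")) stop("rcfg must come from renderConfig()")
  if (identical(rcfg$imageSizePx, "auto"))
    stop("renderFrame needs a numeric imageSizePx; use generateTimeLapse() for 'auto'")
  n <- as.integer(rcfg$imageSizePx)
  px <- rcfg$pixelSizeUm
  r <- state$radius_um
  extent <- r + rcfg$coronaGapUm + rcfg$coronaWidthUm + rcfg$marginUm
  if (2 * extent > n * px)
    stop(sprintf("spheroid (+corona) extent %.0f um exceeds the %.0f um canvas; increase imageSizePx",
                 2 * extent, n * px))
  if (!is.null(seed)) set.seed(as.integer(seed))

  ctr <- (n + 1) / 2
  rad <- sqrt((row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2) * px
  soft <- max(rcfg$edgeSoftnessPx * px, 1e-6)
  disc <- 1 / (1 + exp((rad - r) / soft))
  mask <- rad <= r

  nAtt <- state$nAttached
  total <- nAtt + state$shed
  shedFrac <- if (total > 0) state$shed / total else 0
  ann <- rad >= r + rcfg$coronaGapUm &
         rad <= r + rcfg$coronaGapUm + rcfg$coronaWidthUm

  phase <- rcfg$background + (rcfg$discIntensity - rcfg$background) * disc
  phase <- phase + disc * matrix(rnorm(n * n, 0, rcfg$textureSd), n, n)
  phase <- phase + ann * rcfg$coronaPhase * shedFrac

  fHT <- if (nAtt > 0) state$Aht / nAtt else 0
  fRT <- if (nAtt > 0) state$Art / nAtt else 0
  fC <- if (nAtt > 0) state$C / nAtt else 0
  u <- pmin(rad / max(r, 1e-9), 1)
  s <- rcfg$piRampSteepness
  wCenter <- pmax(0, 1 + s * (1 - 2 * u))
  wEdge <- pmax(0, 1 + s * (2 * u - 1))
  piCh <- disc * (rcfg$piDeadHT * fHT * wCenter +
                  rcfg$piDeadRT * fRT * wEdge +
                  rcfg$piCore * fC * wCenter)
  piCh <- piCh + ann * rcfg$coronaPi * shedFrac

  phase <- pmax(phase + matrix(rnorm(n * n, 0, rcfg$noiseSigma), n, n), 0)
  piCh <- pmax(piCh + matrix(rnorm(n * n, 0, rcfg$noiseSigma), n, n), 0)

  list(frame = spheroidFrame(phase, piCh, pixelSize = px,
                             timeHours = state$t_hours),
       mask = mask, diameterUm = state$diameter_um)
}

#' Generate a synthetic spheroid time-lapse
#'
#' Composes [simulateSpheroid()] and [renderFrame()] at a configurable scan
#' cadence. All stochasticity lives in the renderer: different seeds give
#' distinct noise realizations over identical ground-truth dynamics. Per-frame
#' noise seeds are drawn from the global seed so runs are reproducible.
#'
#' @param config a \code{SimConfig}.
#' @param treatment a [TreatmentSpec-class].
#' @param rcfg a \code{RenderConfig}; \code{imageSizePx = "auto"} sizes the
#'   canvas from the maximal rendered extent.
#' @param scanDays days post treatment at which frames are rendered (default
#'   daily 0..21). Scan times snap to the nearest simulation step.
#' @param seed integer seed for the renderer noise streams (default
#'   \code{config$seed}).
#' @param frameCallback optional \code{function(frame, truthRow)} invoked per
#'   frame; when given, frames are not accumulated in memory.
#' @return list with \code{frames} (list of [SpheroidFrame-class], or NULL
#'   when a callback is used), \code{truth} (data.frame with
#'   \code{frame_id, time_h, day, diameter_um} and the population columns)
#'   and \code{sim} (the full [SpheroidSim-class]).
#' @export
generateTimeLapse <- function(config, treatment, rcfg = renderConfig(),
                              scanDays = 0:21, seed = config$seed,
                              frameCallback = NULL) {
  sim <- simulateSpheroid(config, treatment)
  s <- sim@series
  idx <- vapply(scanDays, function(d) which.min(abs(s$t_hours - d * 24)),
                integer(1))
  states <- s[idx, , drop = FALSE]

  if (identical(rcfg$imageSizePx, "auto")) {
    maxExt <- max(states$radius_um) + rcfg$coronaGapUm + rcfg$coronaWidthUm +
      rcfg$marginUm
    n <- 2 * ceiling(maxExt / rcfg$pixelSizeUm) + 8
    rcfg$imageSizePx <- n + (n %% 2)
  }

  set.seed(as.integer(seed))
  frameSeeds <- sample.int(.Machine$integer.max - 1L, nrow(states))
  frames <- if (is.null(frameCallback)) vector("list", nrow(states)) else NULL
  truth <- cbind(data.frame(frame_id = sprintf("f%03d", seq_len(nrow(states)) - 1L),
                            day = states$t_hours / 24),
                 states)
  for (i in seq_len(nrow(states))) {
    rf <- renderFrame(states[i, ], rcfg, seed = frameSeeds[i])
    if (is.null(frameCallback)) frames[[i]] <- rf$frame
    else frameCallback(rf$frame, truth[i, ])
  }
  list(frames = frames, truth = truth, sim = sim,
       renderConfig = rcfg)
}

#' Canonical treatment scenarios
#'
#' The four canonical study conditions with their expected qualitative growth
#' regimes: untreated control (sustained growth), high thermal dose (transient
#' swelling from structural loosening, then shedding-driven shrinkage, with
#' regrowth of survivors), high radiation dose (gradual outside-in shrinkage /
#' growth control), and an intermediate radiation dose (shrinkage followed by
#' regrowth).
#'
#' @return Named list; each element has \code{treatment} (a
#'   [TreatmentSpec-class]) and \code{expectedRegimes} (character vector of
#'   acceptable [classifyRegime()] labels).
#' @export
canonicalScenarios <- function() {
  list(
    control = list(treatment = treatmentSpec(0, cem43 = 0, label = "control"),
                   expectedRegimes = "control-like growth"),
    ht_high = list(treatment = treatmentSpec(0, cem43 = 80, label = "80 CEM43"),
                   expectedRegimes = "transient-swelling-then-shrinkage"),
    rt_high = list(treatment = treatmentSpec(20, cem43 = 0, label = "20 Gy"),
                   expectedRegimes = c("monotone-shrinkage", "growth-control")),
    rt_mid = list(treatment = treatmentSpec(5, cem43 = 0, label = "5 Gy"),
                  expectedRegimes = "shrinkage-then-regrowth")
  )
}

#' Generate a synthetic clonogenic-survival dataset
#'
#' Colony counts are drawn by binomial thinning: each plated cell forms a
#' colony with probability \code{platingEfficiency * S(treatment)}, so the
#' expected count is \code{nPlated * platingEfficiency * S}. At the low
#' survival levels of interest this is indistinguishable from the Poisson
#' colony-count model while guaranteeing \code{n_colonies <= n_plated}. With
#' \code{noiseless = TRUE} the expected counts are returned instead (useful
#' for exact round-trip fitting checks).
#'
#' @param params a [SurvivalParams-class].
#' @param treatments list of [TreatmentSpec-class].
#' @param nPlated cells plated per dish.
#' @param platingEfficiency untreated colony-forming fraction, in (0, 1].
#' @param nReps replicate dishes per treatment.
#' @param seed integer seed.
#' @param cellLine label column value (default from params).
#' @param noiseless logical; skip the Poisson draw.
#' @return data.frame in the clonogenic CSV dialect (\code{cell_line, dose_gy,
#'   cem43, n_plated, n_colonies, plating_efficiency}).
#' @export
generateClonogenicDataset <- function(params, treatments, nPlated = 1e5,
                                      platingEfficiency = 0.7, nReps = 3,
                                      seed = 1, cellLine = params@cellLine,
                                      noiseless = FALSE) {
  stopifnot(is(params, "SurvivalParams"))
  validObject(params)
  if (platingEfficiency <= 0 || platingEfficiency > 1)
    stop("platingEfficiency must lie in (0, 1]")
  set.seed(as.integer(seed))
  rows <- lapply(treatments, function(tr) {
    S <- survivalFraction(tr, params)
    lam <- nPlated * platingEfficiency * S
    counts <- if (noiseless) rep(lam, nReps)
              else stats::rbinom(nReps, nPlated, platingEfficiency * S)
    data.frame(cell_line = cellLine, dose_gy = tr@radiationGy,
               cem43 = tr@cem43, n_plated = nPlated, n_colonies = counts,
               plating_efficiency = platingEfficiency)
  })
  do.call(rbind, rows)
}

#' Generate a relative-viability dataset
#'
#' Emulates the numeric endpoint of a luminescence/fluorescence viability
#' assay: viability of a treated spheroid relative to the untreated control at
#' the same day, defined on the metabolically active pool (P + Q + doomed Dm,
#' since radiation-doomed cells remain active until mitosis-linked death),
#' multiplied by mean-one lognormal noise of the stated coefficient of
#' variation.
#'
#' @param treatedStates named list of one-row state data.frames (from
#'   [stateAtDay()]).
#' @param controlState the control state at the same day.
#' @param noiseCv coefficient of variation of the lognormal noise (0 disables).
#' @param nReps replicates per condition.
#' @param seed integer seed.
#' @return data.frame with columns \code{label, rep, viability}.
#' @export
generateViabilityDataset <- function(treatedStates, controlState,
                                     noiseCv = 0.1, nReps = 3, seed = 1) {
  if (missing(controlState) || is.null(controlState))
    stop("a control state is required")
  live <- function(st) st$P + st$Q + st$Dm
  lc <- live(controlState)
  if (lc <= 0) stop("control state has no live cells")
  set.seed(as.integer(seed))
  sdlog <- sqrt(log(1 + noiseCv^2))
  rows <- lapply(names(treatedStates), function(nm) {
    ratio <- live(treatedStates[[nm]]) / lc
    noise <- if (noiseCv > 0) exp(rnorm(nReps, -sdlog^2 / 2, sdlog)) else rep(1, nReps)
    data.frame(label = nm, rep = seq_len(nReps), viability = ratio * noise)
  })
  do.call(rbind, rows)
}
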