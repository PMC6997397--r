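test_that("untreated simulation grows monotonically and is reproducible", {
  cfg <- simConfig()
  sim <- simulateSpheroid(cfg, treatmentSpec(0, cem43 = 0))
  s <- as.data.frame(sim)
  expect_true(all(diff(s$diameter_um) >= -1e-9))
  expect_gt(s$diameter_um[nrow(s)], s$diameter_um[1])
  expect_equal(s$diameter_um[1], cfg$initialDiameterUm)
  sim2 <- simulateSpheroid(cfg, treatmentSpec(0, cem43 = 0))
  expect_identical(as.data.frame(sim2), s)
})

test_that("a null-effect thermal exposure leaves the trajectory at control", {
  nullHeat <- survivalParams(alpha0 = 0.5, beta = 0.042, aThermal = 0,
                             bThermal = 0, cSens = 0.01)
  cfg <- simConfig(survivalParams = nullHeat)
  ctrl <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(0, cem43 = 0)))
  heated <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(0, cem43 = 300)))
  expect_equal(heated$diameter_um, ctrl$diameter_um, tolerance = 1e-12)
  expect_equal(heated$P, ctrl$P, tolerance = 1e-12)
})

test_that("cell counts are conserved exactly up to births", {
  cfg <- simConfig()
  for (tr in list(treatmentSpec(0), treatmentSpec(0, cem43 = 160),
                  treatmentSpec(10), treatmentSpec(5, cem43 = 80))) {
    s <- as.data.frame(simulateSpheroid(cfg, tr))
    total <- s$P + s$Q + s$C + s$Dm + s$Aht + s$Art + s$shed
    # bookkeeping oracle: the only source term is the recorded births
    expect_lt(max(abs(total - (total[1] + s$birthsCum)) / total[1]), 1e-10)
    expect_true(all(s[, c("P", "Q", "C", "Dm", "Aht", "Art", "shed")] >= -1e-9))
  }
})

test_that("high thermal dose swells, sheds below baseline, then regrows", {
  cfg <- simConfig()
  s <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(0, cem43 = 80)))
  daily <- s[s$t_hours %% 24 == 0, ]
  d0 <- daily$diameter_um[1]
  expect_gt(max(daily$diameter_um[2:5]), d0)          # transient swelling
  expect_lt(min(daily$diameter_um), d0 * 0.85)        # deep shrinkage
  expect_gt(daily$diameter_um[22], min(daily$diameter_um) * 1.5)  # regrowth
})

test_that("radiation shrinks gradually without a loosening transient", {
  cfg <- simConfig()
  s <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(20)))
  expect_true(all(diff(s$diameter_um) <= 1e-6))
  expect_lt(s$diameter_um[nrow(s)], s$diameter_um[1])
  # rho never drops below baseline without heat
  expect_true(all(abs(s$rho - cfg$rho) < 1e-18))
})

test_that("dead-attached cells peak earlier after heat than after radiation", {
  cfg <- simConfig()
  sH <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(0, cem43 = 178)))
  sR <- as.data.frame(simulateSpheroid(cfg, treatmentSpec(7.4)))
  peakDay <- function(s) {
    f <- (s$Aht + s$Art) / s$nAttached
    s$t_hours[which.max(f)] / 24
  }
  expect_gte(peakDay(sR) - peakDay(sH), 2)
})

test_that("rendering reflects the population state", {
  cfg <- simConfig()
  sim <- simulateSpheroid(cfg, treatmentSpec(0, cem43 = 80))
  rcfg <- renderConfig(imageSizePx = 400, pixelSizeUm = 2)

  # nothing dead and nothing shed: PI stays at the noise floor
  st0 <- stateAtDay(sim, 0)
  expect_equal(st0$Aht + st0$Art + st0$C, 0)
  rf0 <- renderFrame(st0, rcfg, seed = 1)
  expect_lt(mean(rf0$frame@pi), 3 * rcfg$noiseSigma)

  # more shed cells -> brighter corona at identical interior
  st <- stateAtDay(sim, 3)
  stMore <- st; stMore$shed <- st$shed * 3
  noiseless <- renderConfig(imageSizePx = 400, pixelSizeUm = 2,
                            noiseSigma = 0, textureSd = 0)
  r1 <- renderFrame(st, noiseless, seed = 1)
  r2 <- renderFrame(stMore, noiseless, seed = 1)
  n <- 400
  rad <- sqrt((row(matrix(0, n, n)) - 200.5)^2 +
                (col(matrix(0, n, n)) - 200.5)^2) * 2
  ann <- rad >= st$radius_um + 20 & rad <= st$radius_um + 60
  expect_gt(mean(r2$frame@pi[ann]), mean(r1$frame@pi[ann]))
  inner <- rad <= st$radius_um * 0.8
  expect_equal(r1$frame@pi[inner], r2$frame@pi[inner], tolerance = 1e-12)

  # ground-truth diameter agrees with measurement on the rendered mask
  m <- measureDiameters(rf0$mask, pixelSize = 2)
  expect_lt(abs(m$meanDiameter - rf0$diameterUm) / rf0$diameterUm, 0.02)

  # canvas bound checking
  tiny <- renderConfig(imageSizePx = 64, pixelSizeUm = 1)
  expect_error(renderFrame(st0, tiny, seed = 1), "exceeds")
})

test_that("time-lapse generation isolates noise in the renderer", {
  cfg <- simConfig(initialDiameterUm = 300)
  rcfg <- renderConfig(pixelSizeUm = 4)
  tr <- treatmentSpec(0, cem43 = 0)
  tl1 <- generateTimeLapse(cfg, tr, rcfg, scanDays = c(0, 7, 14), seed = 1)
  tl2 <- generateTimeLapse(cfg, tr, rcfg, scanDays = c(0, 7, 14), seed = 2)
  # identical ground truth, distinct noise realizations
  expect_identical(tl1$truth$diameter_um, tl2$truth$diameter_um)
  expect_false(identical(tl1$frames[[1]]@phase, tl2$frames[[1]]@phase))
  # same seed reproduces frames exactly
  tl1b <- generateTimeLapse(cfg, tr, rcfg, scanDays = c(0, 7, 14), seed = 1)
  expect_identical(tl1$frames[[2]]@phase, tl1b$frames[[2]]@phase)

  # daily scans subsample the 4-hourly simulation exactly
  s <- as.data.frame(tl1$sim)
  expect_equal(tl1$truth$diameter_um,
               s$diameter_um[match(c(0, 7, 14) * 24, s$t_hours)])
})

test_that("clonogenic datasets follow the Poisson colony model", {
  ideal <- survivalParams(alpha0 = 0, beta = 0, aThermal = 0, bThermal = 0,
                          cSens = 0)
  rec <- generateClonogenicDataset(ideal, list(treatmentSpec(0)),
                                   nPlated = 500, platingEfficiency = 1,
                                   nReps = 1000, seed = 8)
  # S = 1, PE = 1: mean colonies = nPlated within 3 standard errors
  se <- sqrt(500 / 1000)
  expect_lt(abs(mean(rec$n_colonies) - 500), 3 * se)

  # S ~ 0: counts almost surely zero
  hot <- survivalParams(alpha0 = 2, beta = 0.1, aThermal = 0, bThermal = 0,
                        cSens = 0)
  rec0 <- generateClonogenicDataset(hot, list(treatmentSpec(20)),
                                    nPlated = 1e4, nReps = 50, seed = 9)
  expect_true(all(rec0$n_colonies == 0))

  # round-trip: Poisson-noise fit recovers alpha0 within 10%
  truth <- survivalParams(alpha0 = 0.45, beta = 0.035, aThermal = 0,
                          bThermal = 0, cSens = 0)
  trts <- lapply(c(0, 2, 5, 10), treatmentSpec)
  recP <- generateClonogenicDataset(truth, trts, nPlated = 1e5,
                                    platingEfficiency = 0.7, nReps = 3,
                                    seed = 10)
  fit <- fitSurvivalParams(recP, fixed = list(aThermal = 0, bThermal = 0,
                                              cSens = 0))
  expect_lt(abs(fit$params@alpha0 - 0.45) / 0.45, 0.1)
})

test_that("viability tables are live-cell ratios with calibrated noise", {
  cfg <- simConfig()
  ctrl <- stateAtDay(simulateSpheroid(cfg, treatmentSpec(0)), 4)
  # self-ratio without noise is exactly 1
  v <- generateViabilityDataset(list(ctrl = ctrl), ctrl, noiseCv = 0, nReps = 2)
  expect_equal(v$viability, c(1, 1))
  # halved live pool gives 0.5
  half <- ctrl
  half$P <- ctrl$P / 2; half$Q <- ctrl$Q / 2; half$Dm <- ctrl$Dm / 2
  v2 <- generateViabilityDataset(list(half = half), ctrl, noiseCv = 0, nReps = 1)
  expect_equal(v2$viability, 0.5)
  # lognormal noise CV calibration over many draws
  v3 <- generateViabilityDataset(list(ctrl = ctrl), ctrl, noiseCv = 0.1,
                                 nReps = 1000, seed = 11)
  cv <- sd(v3$viability) / mean(v3$viability)
  expect_gt(cv, 0.08); expect_lt(cv, 0.12)
  expect_error(generateViabilityDataset(list(ctrl = ctrl), NULL), "control")
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(simConfig(looseningFactor = 1.2), "looseningFactor")
  expect_error(simConfig(lambda = -1), ">= 0")
  expect_error(simConfig(initialDiameterUm = 0), "initialDiameterUm")
  expect_error(renderConfig(pixelSizeUm = 0), "pixelSizeUm")
  expect_error(renderConfig(imageSizePx = 4), "imageSizePx")
  expect_error(simulateSpheroid(list(), treatmentSpec(0)), "simConfig")
})
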