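test_that("CEM43 matches closed-form Sapareto sums and rejects invalid input", {
  # reference temperature: identity
  expect_equal(computeCEM43(thermalExposure(43, 30)), 30)
  # one degree-compounded segment: 15 * 0.5^(43-47) = 240
  expect_equal(computeCEM43(thermalExposure(47, 15)), 240)
  # mixed segments with both breakpoint factors: 10*0.5^-2 + 16*0.25^2 = 41
  expect_equal(computeCEM43(thermalExposure(c(45, 41), c(10, 16))), 41)
  # custom factors
  expect_equal(computeCEM43(thermalExposure(47, 15), rAbove = 0.4),
               15 * 0.4^(-4))

  expect_error(thermalExposure(numeric(0), numeric(0)), "at least one segment")
  expect_error(thermalExposure(55, 10), "\\[20, 50\\]")
  expect_error(thermalExposure(45, -1), "> 0")
  expect_error(computeCEM43(thermalExposure(45, 10), rAbove = 0), "rAbove")
})

test_that("CEM43 is additive over segment concatenation", {
  set.seed(11)
  for (i in 1:25) {
    nA <- sample(1:4, 1); nB <- sample(1:4, 1)
    tA <- runif(nA, 20, 50); dA <- runif(nA, 0.5, 60)
    tB <- runif(nB, 20, 50); dB <- runif(nB, 0.5, 60)
    whole <- computeCEM43(thermalExposure(c(tA, tB), c(dA, dB)))
    parts <- computeCEM43(thermalExposure(tA, dA)) +
      computeCEM43(thermalExposure(tB, dB))
    expect_equal(whole, parts, tolerance = 1e-12)
  }
})

test_that("survival model evaluates its closed form and honours S(0,0)=1", {
  spLQ <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0,
                         bThermal = 0, cSens = 0)
  expect_identical(survivalFraction(treatmentSpec(0, cem43 = 0), spLQ), 1)
  expect_equal(survivalFraction(treatmentSpec(10), spLQ), exp(-6))
  # combined treatment with sensitization: exp(-(2 + 0.3*2*2 + 0.03*4))
  sp <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0.02,
                       bThermal = 0, cSens = 0.01)
  expect_equal(survivalFraction(treatmentSpec(2, cem43 = 100), sp),
               exp(-3.32))
  expect_error(survivalParams(alpha0 = -0.1), "negative")
})

test_that("survival is monotone non-increasing in dose and thermal dose", {
  sp <- survivalParams()
  D <- seq(0, 20, length.out = 30)
  H <- seq(0, 780, length.out = 30)
  S <- outer(D, H, function(d, h) mapply(function(dd, hh)
    survivalFraction(treatmentSpec(dd, cem43 = hh), sp), d, h))
  expect_true(all(diff(S) <= 1e-15))        # along D
  expect_true(all(t(diff(t(S))) <= 1e-15))  # along H
  E <- -log(S)
  expect_true(all(diff(E) >= -1e-12))
})

test_that("biological effect is -ln S with domain checks", {
  expect_equal(biologicalEffect(1), 0)
  expect_equal(biologicalEffect(1e-4), 4 * log(10))
  expect_equal(biologicalEffect(exp(-6)), 6)
  expect_error(biologicalEffect(0), "\\(0, 1\\]")
  expect_error(biologicalEffect(1.2), "\\(0, 1\\]")
})

test_that("beqd solves the LQ quadratic and is the identity on pure RT", {
  sp <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0.025,
                       bThermal = 0, cSens = 0)
  # thermal-only at 240 CEM43: E = 6 -> (-0.3 + sqrt(0.09 + 0.72)) / 0.06 = 10
  expect_equal(beqd(treatmentSpec(0, cem43 = 240), sp), 10)
  # cross-check with a numeric root-finder oracle
  num <- uniroot(function(x) 0.3 * x + 0.03 * x^2 - 6, c(0, 100),
                 tol = 1e-12)$root
  expect_equal(beqd(treatmentSpec(0, cem43 = 240), sp), num, tolerance = 1e-9)

  for (D in c(0.5, 2, 7.3, 10, 20))
    expect_equal(beqd(treatmentSpec(D), sp), D, tolerance = 1e-9)
  expect_equal(beqd(treatmentSpec(0, cem43 = 0), sp), 0)

  # beta = 0 falls back to linear inversion
  spLin <- survivalParams(alpha0 = 0.5, beta = 0, aThermal = 0.02,
                          bThermal = 0, cSens = 0)
  expect_equal(beqd(treatmentSpec(0, cem43 = 100), spLin), 2 / 0.5)
  spNone <- survivalParams(alpha0 = 0, beta = 0, aThermal = 0.02,
                           bThermal = 0, cSens = 0)
  expect_error(beqd(treatmentSpec(0, cem43 = 10), spNone),
               "no radiation response")
})

test_that("isoeffect pairs reproduce the target effect and match bisection", {
  sp <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0.025,
                       bThermal = 0, cSens = 0.05)
  target <- 6
  tab <- suppressMessages(
    isoeffectCombinations(target, sp, c(0, 2, 5, 8, 10, 12)))
  # 12 Gy exceeds the target effect and is omitted
  expect_false(12 %in% tab$dose_gy)
  # the pure-RT boundary dose (E(10 Gy) = 6) pairs with H = 0
  expect_equal(tab$cem43[tab$dose_gy == 10], 0, tolerance = 1e-9)
  # every pair reproduces the target effect through the survival model
  for (i in seq_len(nrow(tab))) {
    E <- biologicalEffect(survivalFraction(
      treatmentSpec(tab$dose_gy[i], cem43 = tab$cem43[i]), sp))
    expect_lt(abs(E - target), 1e-9)
  }
  # independent bisection oracle at D = 2 (effect formula coded by hand)
  Hor <- bisectionOracle(function(H)
    0.025 * H + 0.3 * (1 + 0.05 * H) * 2 + 0.03 * 4 - target, 0, 1e4)
  expect_equal(tab$cem43[tab$dose_gy == 2], Hor, tolerance = 1e-6)

  # thermal-only linear inversion: H = E / a
  spA <- survivalParams(alpha0 = 0.3, beta = 0.03, aThermal = 0.025,
                        bThermal = 0, cSens = 0)
  tabA <- isoeffectCombinations(5, spA, 0)
  expect_equal(tabA$cem43, 5 / 0.025, tolerance = 1e-7)
  expect_error(isoeffectCombinations(0, sp, 0), "targetEffect")
})

test_that("noiseless survival fitting recovers the generating parameters", {
  truth <- survivalParams(alpha0 = 0.45, beta = 0.035, aThermal = 0.018,
                          bThermal = 6e-5, cSens = 0.012)
  trts <- list()
  for (D in c(0, 2, 5, 10))
    for (H in c(0, 60, 120, 240))
      trts[[length(trts) + 1L]] <- treatmentSpec(D, cem43 = H)
  rec <- generateClonogenicDataset(truth, trts, nPlated = 1e5,
                                   platingEfficiency = 0.7, nReps = 1,
                                   seed = 1, noiseless = TRUE)
  fit <- fitSurvivalParams(rec)
  tv <- c(alpha0 = 0.45, beta = 0.035, aThermal = 0.018, bThermal = 6e-5,
          cSens = 0.012)
  expect_lt(max(abs(fit$estimates[names(tv)] - tv) / tv), 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$se >= 0, na.rm = TRUE))

  # radiation-only design with thermal terms fixed at 0
  recRT <- rec[rec$cem43 == 0, ]
  fitRT <- fitSurvivalParams(recRT, fixed = list(aThermal = 0, bThermal = 0,
                                                 cSens = 0))
  expect_lt(abs(fitRT$params@alpha0 - 0.45) / 0.45, 1e-6)
  expect_lt(abs(fitRT$params@beta - 0.035) / 0.035, 1e-6)
})

test_that("degenerate clonogenic designs are rejected", {
  truth <- survivalParams()
  rec0 <- generateClonogenicDataset(truth, list(treatmentSpec(0)),
                                    nPlated = 1000, nReps = 5, seed = 2)
  expect_error(fitSurvivalParams(rec0), "degenerate|informative")
  expect_error(fitSurvivalParams(data.frame()), "missing column|empty")
  bad <- data.frame(cell_line = "x", dose_gy = 1, cem43 = 0, n_plated = 10,
                    n_colonies = 20, plating_efficiency = 0.5)
  expect_error(validateClonogenicRecords(bad), "exceed")
})

test_that("clonogenic CSV round-trips through the documented dialect", {
  truth <- survivalParams()
  rec <- generateClonogenicDataset(
    truth, list(treatmentSpec(0), treatmentSpec(2), treatmentSpec(5)),
    nPlated = 2000, nReps = 2, seed = 3)
  path <- tempfile(fileext = ".csv")
  writeClonogenicCSV(rec, path)
  back <- readClonogenicCSV(path)
  expect_equal(back$n_colonies, rec$n_colonies)
  expect_equal(back$dose_gy, rec$dose_gy)
})
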