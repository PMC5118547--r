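test_that("a noiseless single exponential is recovered to machine-level accuracy", {
  surf <- oneExpSurface(tau = 1e-3)
  fit <- fitGlobalMultiexp(surf, 1, withOffset = FALSE, nRestarts = 3)
  expect_equal(timeConstants(fit), 1e-3, tolerance = 1e-6)
  amp <- sin(seq(0.3, 2.8, length.out = 11))
  expect_equal(unname(amplitudeSpectra(fit)[1, ]), amp, tolerance = 1e-6)
  expect_lt(residualSS(fit), 1e-20)
})

test_that("four photocycle phases are recovered from the noisy synthetic surface", {
  surf <- makeTransientDataset(scenarioConfig(seed = 11L))
  fit <- fitGlobalMultiexp(surf, 4, withOffset = TRUE, nRestarts = 8,
                           seed = 11)
  tau <- timeConstants(fit)
  truth <- c(2e-6, 210e-6, 6.0e-3, 0.2)
  expect_equal(length(tau), 4L)
  expect_true(all(abs(tau - truth) / truth < 0.10))
  ## the long-lived 13-cis photoproduct appears as a non-zero offset
  expect_gt(max(abs(offsetSpectrum(fit))), 1e-3)
})

test_that("nested models: fewer components can only raise the RSS", {
  surf <- makeTransientDataset(scenarioConfig(seed = 11L))
  fit4 <- fitGlobalMultiexp(surf, 4, nRestarts = 4, seed = 1)
  fit2 <- fitGlobalMultiexp(surf, 2, nRestarts = 4, seed = 1)
  expect_gt(residualSS(fit2), residualSS(fit4))
})

test_that("too few time points for the parameter count is rejected", {
  surf <- transientSurface(c(1, 2, 3, 4), c(500, 510),
                           matrix(rnorm(8), 4))
  expect_error(fitGlobalMultiexp(surf, 2), "time points")
})

test_that("nearly equal recovered time constants trigger an unresolved warning", {
  times <- 10^seq(-5, 0, length.out = 60)
  wl <- seq(400, 500, 10)
  Y <- outer(exp(-times / 1e-3), rep(0.5, length(wl))) +
       outer(exp(-times / 1.03e-3), seq(0.2, 0.8, length.out = length(wl)))
  surf <- transientSurface(times, wl, Y)
  expect_warning(fitGlobalMultiexp(surf, 2, withOffset = FALSE,
                                   tauInit = c(9e-4, 1.1e-3),
                                   nRestarts = 1),
                 "unresolved")
})

test_that("model-order selection finds the generating component count", {
  sel1 <- selectNComponents(oneExpSurface(), nMax = 3, withOffset = FALSE)
  expect_identical(sel1$selected, 1L)

  surf <- makeTransientDataset(scenarioConfig(seed = 11L))
  sel4 <- selectNComponents(surf, nMax = 6, nRestarts = 4, seed = 2)
  expect_identical(sel4$selected, 4L)
  expect_true(all(diff(sel4$table$rss) <= 1e-9))

  noise <- withr::with_seed(5, matrix(rnorm(50 * 8, sd = 1e-3), 50))
  pure <- transientSurface(seq(0.1, 5, length.out = 50),
                           seq(400, 470, 10), noise)
  sel0 <- selectNComponents(pure, nMax = 3, nRestarts = 3, seed = 2)
  expect_identical(sel0$selected, 0L)
})

test_that("reconstructed slices obey the model limits", {
  surf <- makeTransientDataset(scenarioConfig(seed = 11L))
  fit <- fitGlobalMultiexp(surf, 4, nRestarts = 4, seed = 1)
  expect_equal(absorbance(reconstructSlice(fit, 1e9)),
               offsetSpectrum(fit), tolerance = 1e-12)
  expect_equal(absorbance(reconstructSlice(fit, 0)),
               colSums(amplitudeSpectra(fit)) + offsetSpectrum(fit),
               tolerance = 1e-12)
  expect_error(reconstructSlice(fit, -1), "non-negative")
})

test_that("the 2 s reconstruction matches the generating terminal difference spectrum", {
  cfg <- scenarioConfig(seed = 11L)
  surf <- makeTransientDataset(cfg)
  fit <- fitGlobalMultiexp(surf, 4, nRestarts = 4, seed = 1)
  spec <- defaultSpeciesSpectra()
  want <- cfg@excitedFraction * exp(-2 / 91) *
    (spec@profiles[, "P13C"] - spec@ground)
  got <- absorbance(reconstructSlice(fit, 2))
  expect_lt(max(abs(got - want)), 5e-3)
})

test_that("variable projection leaves no linear descent direction", {
  surf <- oneExpSurface(tau = 1e-3)
  dA <- deltaA(surf) + withr::with_seed(3,
          matrix(rnorm(length(deltaA(surf)), sd = 1e-3),
                 nrow(deltaA(surf))))
  noisy <- transientSurface(timePoints(surf), wavelengths(surf), dA)
  fit <- fitGlobalMultiexp(noisy, 1, withOffset = TRUE, nRestarts = 3)
  X <- cbind(exp(-timePoints(noisy) / timeConstants(fit)), 1)
  B <- rbind(amplitudeSpectra(fit), offsetSpectrum(fit))
  rss0 <- sum((dA - X %*% B)^2)
  expect_equal(rss0, residualSS(fit), tolerance = 1e-10)
  for (delta in c(1e-4, -1e-4)) {
    for (idx in list(c(1, 1), c(2, 5), c(1, 11))) {
      Bp <- B
      Bp[idx[1], idx[2]] <- Bp[idx[1], idx[2]] + delta
      expect_gt(sum((dA - X %*% Bp)^2), rss0)
    }
  }
})

test_that("fits are invariant to column permutation and amplitude rescaling", {
  surf <- makeTransientDataset(scenarioConfig(seed = 11L))
  fit <- fitGlobalMultiexp(surf, 4, nRestarts = 3, seed = 5)
  perm <- rev(seq_along(wavelengths(surf)))
  surfP <- transientSurface(timePoints(surf), wavelengths(surf),
                            deltaA(surf)[, perm])
  fitP <- fitGlobalMultiexp(surfP, 4, nRestarts = 3, seed = 5)
  expect_equal(timeConstants(fitP), timeConstants(fit), tolerance = 1e-6)
  expect_equal(amplitudeSpectra(fitP)[, perm], amplitudeSpectra(fit),
               tolerance = 1e-4)
  surfS <- transientSurface(timePoints(surf), wavelengths(surf),
                            10 * deltaA(surf))
  fitS <- fitGlobalMultiexp(surfS, 4, nRestarts = 3, seed = 5)
  expect_equal(timeConstants(fitS), timeConstants(fit), tolerance = 1e-6)
  expect_equal(amplitudeSpectra(fitS), 10 * amplitudeSpectra(fit),
               tolerance = 1e-4)
})

test_that("time-constant recovery is stable over stochastic replicates", {
  truth <- c(2e-6, 210e-6, 6.0e-3, 0.2)
  errs <- matrix(NA_real_, 12, 4)
  for (r in 1:12) {
    surf <- makeTransientDataset(scenarioConfig(seed = 100L + r))
    tau <- timeConstants(fitGlobalMultiexp(surf, 4, nRestarts = 4,
                                           seed = r))
    errs[r, ] <- abs(tau - truth) / truth
    ## no replicate may swap component ordering: each recovered constant is
    ## nearest (in log space) to its own generator
    near <- apply(abs(outer(log10(tau), log10(truth), "-")), 1, which.min)
    expect_identical(near, 1:4)
  }
  expect_true(all(apply(errs, 2, stats::median) < 0.10))
})

test_that("single-trace fits recover slow recovery and well-separated pairs", {
  tr <- makeDarkAdaptationTrace(scenarioConfig(seed = 21L))
  fit <- fitTrace(tr$time, tr$absorbance, 1)
  expect_equal(timeConstants(fit), 91, tolerance = 0.05)

  tt <- seq(0.5, 400, by = 0.5)
  y <- 0.4 * exp(-tt / 2) + 0.2 * exp(-tt / 200) + 0.05
  fit2 <- fitTrace(tt, y, 2, nRestarts = 6)
  expect_equal(timeConstants(fit2), c(2, 200), tolerance = 0.02)
  expect_equal(amplitudeSpectra(fit2), c(0.4, 0.2), tolerance = 0.02)

  flat <- fitTrace(seq_len(50), rep(3.3, 50), 0)
  expect_identical(length(timeConstants(flat)), 0L)
  expect_equal(offsetSpectrum(flat), 3.3)
  expect_lt(residualSS(flat), 1e-20)
})

test_that("pH-independent M decay is classified as an internal proton donor", {
  traces <- lapply(c(5, 7, 9), riseDecayTrace, tauRise = 2e-4,
                   tauDecay = 0.2)
  res <- analyzeMPhDependence(traces)
  expect_identical(res$classification, "internal donor")
  expect_equal(res$table$tauDecay, rep(0.2, 3), tolerance = 1e-3)
  expect_equal(res$table$tauRise, rep(2e-4, 3), tolerance = 1e-3)
})

test_that("M decay slowing 10x per pH unit is classified as aqueous uptake", {
  traces <- Map(riseDecayTrace, pH = c(5, 6, 7),
                tauDecay = 0.002 * 10^(c(5, 6, 7) - 5), tauRise = 2e-5)
  res <- analyzeMPhDependence(traces)
  expect_identical(res$classification, "aqueous uptake")
})

test_that("non-monotonic M-decay patterns are indeterminate", {
  traces <- Map(riseDecayTrace, pH = c(5, 6, 7, 8), tauRise = 2e-4,
                tauDecay = c(0.05, 0.3, 0.05, 0.3))
  res <- analyzeMPhDependence(traces)
  expect_identical(res$classification, "indeterminate")
})
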