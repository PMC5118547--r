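test_that("a linear light-phase pH rise gives its exact slope", {
  tt <- seq(-50, 300)
  pH <- 7 + 0.001 * pmax(tt, 0) * (tt <= 150) + 0.15 * (tt > 150)
  tr <- phTrace(tt, pH, lightOn = 0, lightOff = 150)
  expect_equal(initialSlope(tr), 0.001, tolerance = 1e-10)
})

test_that("the initial slope of a saturating rise recovers the initial derivative", {
  s0 <- 0.002; tauCell <- 200
  tt <- seq(-50, 300)
  rise <- ifelse(tt >= 0 & tt <= 150,
                 s0 * tauCell * (1 - exp(-tt / tauCell)), 0)
  pH <- withr::with_seed(41, 7 + rise + stats::rnorm(length(tt), sd = 0.002))
  tr <- phTrace(tt, pH, lightOn = 0, lightOff = 150)
  expect_equal(initialSlope(tr), s0, tolerance = 0.10)
})

test_that("slope preconditions: dark traces and out-of-window requests are rejected", {
  tr <- phTrace(seq(0, 100), rep(7, 101))
  expect_error(initialSlope(tr), "no illumination")
  lit <- phTrace(seq(0, 100), rep(7, 101), lightOn = 10, lightOff = 30)
  expect_error(initialSlope(lit, windowS = 30), "beyond the illumination")
})

test_that("bleach-referenced extinction follows the oxime ratio", {
  wl <- 300:700
  pig <- absorptionSpectrum(wl, gaussianBand(wl, 568, height = 0.5))
  ox <- absorptionSpectrum(wl, gaussianBand(wl, 360, height = 0.336))
  ex <- extinctionFromBleach(pig, ox)
  expect_equal(ex@epsilon, 50000, tolerance = 1e-6)

  exSame <- extinctionFromBleach(pig,
              absorptionSpectrum(wl, gaussianBand(wl, 360, height = 0.5)))
  expect_equal(exSame@epsilon, 33600, tolerance = 1e-6)

  expect_error(extinctionFromBleach(pig,
                 absorptionSpectrum(wl, numeric(length(wl)))),
               "oxime band")
})

test_that("the two amount routes agree and scale with the oxime band", {
  wl <- 300:700
  pig <- absorptionSpectrum(wl, gaussianBand(wl, 568, height = 0.0333))
  ox <- absorptionSpectrum(wl, gaussianBand(wl, 360, height = 0.0224))
  ex <- extinctionFromBleach(pig, ox, volume = 0.003)
  expect_equal(ex@amount, 0.0224 / 33600 * 0.003, tolerance = 1e-6)
})

test_that("normalized activity divides by amount and scales accordingly", {
  ex <- new("ExpressionResult", epsilon = 50000, amount = 1e-9)
  expect_equal(normalizedActivity(0.001, ex), 1e6)
  ex2 <- new("ExpressionResult", epsilon = 50000, amount = 2e-9)
  expect_equal(normalizedActivity(0.001, ex2),
               normalizedActivity(0.001, ex) / 2)
  act <- normalizedActivity(0.001, ex, slopeSd = 1e-4)
  expect_equal(attr(act, "sd"), 1e5)
})

test_that("activity ratios are invariant to rescaling the oxime reference", {
  wl <- 300:700
  mk <- function(hPig, hOx, eps)
    extinctionFromBleach(
      absorptionSpectrum(wl, gaussianBand(wl, 568, height = hPig)),
      absorptionSpectrum(wl, gaussianBand(wl, 360, height = hOx)),
      epsilonOxime = eps)
  r1 <- normalizedActivity(0.003, mk(0.04, 0.025, 33600)) /
        normalizedActivity(0.001, mk(0.03, 0.020, 33600))
  r2 <- normalizedActivity(0.003, mk(0.04, 0.025, 20000)) /
        normalizedActivity(0.001, mk(0.03, 0.020, 20000))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the proton-pump panel is called: positive in all salts, abolished by CCCP", {
  pan <- makeAssayPanel(scenarioConfig(seed = 51L), "WT")
  call <- classifyTransport(pan$traces)
  expect_identical(transportMode(call), "inward H+ pump")
  sl <- conditionSlopes(call)
  expect_true(all(sl$slope[!sl$cccp] > 1e-4))
})

test_that("the chloride-pump panel is called: sulfate abolishes, CCCP accelerates", {
  pan <- makeAssayPanel(scenarioConfig(seed = 51L), "ClR")
  expect_identical(transportMode(classifyTransport(pan$traces)),
                   "inward Cl- pump")
})

test_that("an all-flat panel is indeterminate and incomplete panels are rejected", {
  tt <- seq(-50, 300)
  flat <- function(salt, cccp)
    phTrace(tt, withr::with_seed(7 + cccp, 7 + rnorm(length(tt), sd = 5e-4)),
            0, 150, salt, cccp)
  panel <- list(flat("NaCl", FALSE), flat("NaCl", TRUE),
                flat("CsCl", FALSE), flat("CsCl", TRUE))
  expect_identical(transportMode(classifyTransport(panel)),
                   "none/indeterminate")
  expect_error(classifyTransport(panel[c(1, 3)]), "CCCP counterpart")
  expect_error(classifyTransport(panel[1:2]), "2 salts")
})

test_that("classification is invariant to 2x subsampling and pH offsets", {
  pan <- makeAssayPanel(scenarioConfig(seed = 51L), "WT")
  sub <- lapply(pan$traces, function(tr) {
    idx <- seq(1, length(timePoints(tr)), by = 2)
    phTrace(timePoints(tr)[idx], tr@pH[idx] + 0.4, tr@lightOn, tr@lightOff,
            tr@salt, tr@cccp, tr@sample)
  })
  expect_identical(transportMode(classifyTransport(sub)), "inward H+ pump")
})

test_that("the D216E panel shows about threefold higher normalized activity", {
  cfg <- scenarioConfig(seed = 51L)
  act <- function(genotype) {
    pan <- makeAssayPanel(cfg, genotype)
    ex <- extinctionFromBleach(pan$pigment, pan$bleached,
                               volume = pan$volume)
    sl <- vapply(Filter(function(tr) !tr@cccp, pan$traces), initialSlope,
                 numeric(1))
    normalizedActivity(mean(sl), ex)
  }
  expect_equal(act("D216E") / act("WT"), 3, tolerance = 0.10)
  ## impaired mutants stay well below wild type
  expect_lt(act("D216N") / act("WT"), 0.2)
})
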