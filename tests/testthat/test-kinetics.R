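test_that("rate matrix of a two-state decay has the closed-form layout", {
  sch <- photocycleScheme(c("A", "B"),
                          data.frame(from = "A", to = "B", rate = 1))
  K <- buildRateMatrix(sch)
  expect_identical(unname(as(K, "matrix")), matrix(c(-1, 1, 0, 0), 2))
})

test_that("invalid schemes are rejected", {
  expect_error(photocycleScheme(c("A", "B"),
                 data.frame(from = c("A", "A"), to = c("B", "B"),
                            rate = c(1, 2))),
               "duplicate edge")
  expect_error(photocycleScheme(c("A", "B"),
                 data.frame(from = "A", to = "C", rate = 1)),
               "unknown state")
  expect_error(photocycleScheme(c("A", "B"),
                 data.frame(from = "A", to = "A", rate = 1)),
               "self-edges")
  expect_error(photocycleScheme(c("A", "B"),
                 data.frame(from = "A", to = "B", rate = -1)),
               "> 0")
})

test_that("default sequential chain is triangular with the five rates", {
  sch <- defaultPhotocycleScheme()
  K <- unclass(buildRateMatrix(sch))
  expect_identical(dim(K), c(6L, 6L))
  expect_true(all(K[upper.tri(K)] == 0))
  expect_equal(unname(sort(abs(diag(K)[1:5]), decreasing = TRUE)),
               unname(1 / c(2e-6, 210e-6, 6.0e-3, 0.2, 91)),
               tolerance = 1e-12)
  expect_equal(max(abs(colSums(K))), 0)
})

test_that("reversible edges populate both off-diagonals, columns still sum to zero", {
  sch <- photocycleScheme(c("L", "M", "ground"),
           data.frame(from = c("L", "M", "M"), to = c("M", "L", "ground"),
                      rate = c(2000, 500, 5)))
  K <- unclass(buildRateMatrix(sch))
  expect_gt(K["M", "L"], 0)
  expect_gt(K["L", "M"], 0)
  expect_equal(max(abs(colSums(K))), 0, tolerance = 1e-9 * max(abs(K)))
})

test_that("two-state propagation matches the closed form", {
  sch <- photocycleScheme(c("A", "B"),
                          data.frame(from = "A", to = "B", rate = 1))
  P <- propagatePopulations(buildRateMatrix(sch), c(A = 1, B = 0), 1)
  expect_equal(unname(P[1, ]), c(exp(-1), 1 - exp(-1)), tolerance = 1e-12)
})

test_that("analytic propagator agrees with dense ODE integration on random chains", {
  for (seed in 1:5) {
    nStates <- 3 + (seed %% 4)
    sch <- randomChainScheme(nStates, seed)
    K <- buildRateMatrix(sch)
    p0 <- initialPopulations(sch)
    times <- 10^seq(-6, 1, length.out = 100)
    P <- propagatePopulations(K, p0, times)
    expect_identical(attr(P, "propagation"), "eigen")
    expect_lt(max(abs(P - odeOracle(K, p0, times))), 1e-8)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P > -1e-10))
  }
})

test_that("population conservation holds for the default photocycle", {
  sch <- defaultPhotocycleScheme()
  P <- propagatePopulations(buildRateMatrix(sch), initialPopulations(sch),
                            10^seq(-7, 2, length.out = 120))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
})

test_that("terminal 13-cis state accumulates the excited fraction by 2 s", {
  sch <- defaultPhotocycleScheme()
  P <- propagatePopulations(buildRateMatrix(sch), initialPopulations(sch), 2)
  expect_gt(P[1, "P13C"], 0.95 * excitedFraction(sch))
})

test_that("degenerate eigensystems fall back to ODE integration and are flagged", {
  sch <- photocycleScheme(c("A", "B", "C"),
           data.frame(from = c("A", "B"), to = c("B", "C"), rate = c(1, 1)))
  times <- c(0.1, 1, 5)
  P <- propagatePopulations(buildRateMatrix(sch), c(1, 0, 0), times)
  expect_identical(attr(P, "propagation"), "ode")
  expect_lt(max(abs(P - cbind(exp(-times), times * exp(-times),
                              1 - exp(-times) - times * exp(-times)))),
            1e-8)
})

test_that("apparent time constants of the sequential chain equal the edge lifetimes", {
  K <- buildRateMatrix(defaultPhotocycleScheme())
  expect_equal(unname(apparentTimeConstants(K)),
               c(2e-6, 210e-6, 6.0e-3, 0.2, 91), tolerance = 1e-12)
  K1 <- buildRateMatrix(photocycleScheme(c("A", "B"),
          data.frame(from = "A", to = "B", rate = 5)))
  expect_equal(unname(apparentTimeConstants(K1)), 0.2, tolerance = 1e-12)
})

test_that("reversible-equilibrium phases match a characteristic-polynomial root finder", {
  sch <- photocycleScheme(c("L", "M", "ground"),
           data.frame(from = c("L", "M", "M"), to = c("M", "L", "ground"),
                      rate = c(2000, 500, 5)))
  K <- buildRateMatrix(sch)
  tau <- apparentTimeConstants(K)
  expect_equal(unname(tau), charpolyTimeConstants(K), tolerance = 1e-9)
  ## phases differ from the raw edge lifetimes once an equilibrium exists
  expect_false(any(abs(tau[1] - 1 / c(2000, 500, 5)) / tau[1] < 1e-3))
})

test_that("identical species spectra give an exactly zero surface", {
  sch <- defaultPhotocycleScheme()
  wl <- seq(360, 710, 10)
  g <- gaussianBand(wl, 568)
  prof <- sapply(schemeStates(sch), function(s) g)
  spec <- speciesSpectra(wl, prof, ground = g)
  surf <- simulateSurface(buildRateMatrix(sch), spec, c(1e-6, 1e-3, 1))
  expect_equal(max(abs(deltaA(surf))), 0)
})

test_that("the 2 s slice equals the terminal-minus-ground difference spectrum", {
  sch <- defaultPhotocycleScheme()
  spec <- defaultSpeciesSpectra()
  surf <- simulateSurface(buildRateMatrix(sch), spec,
                          c(1e-6, 1e-3, 2), excitedFraction = 0.05)
  ## by 2 s all fast phases are complete; only the slow 91 s recovery has
  ## eaten ~2% of the terminal-state population
  want <- 0.05 * (spec@profiles[, "P13C"] - spec@ground)
  expect_equal(unname(deltaA(surf)[3, ]), unname(want), tolerance = 0.05)
})

test_that("surface synthesis is linear in the excited fraction and in spectra", {
  sch <- defaultPhotocycleScheme()
  spec <- defaultSpeciesSpectra()
  K <- buildRateMatrix(sch)
  times <- 10^seq(-6, 0, length.out = 20)
  s1 <- simulateSurface(K, spec, times, excitedFraction = 0.02)
  s2 <- simulateSurface(K, spec, times, excitedFraction = 0.04)
  expect_equal(deltaA(s2), 2 * deltaA(s1), tolerance = 1e-10)
  spec2 <- speciesSpectra(spec@wavelength, 3 * spec@profiles,
                          ground = 3 * spec@ground)
  s3 <- simulateSurface(K, spec2, times, excitedFraction = 0.02)
  expect_equal(deltaA(s3), 3 * deltaA(s1), tolerance = 1e-10)
})

test_that("single-state decay gives a mono-exponential at every wavelength", {
  sch <- photocycleScheme(c("A", "ground"),
                          data.frame(from = "A", to = "ground", rate = 100),
                          excitedFraction = 1)
  wl <- seq(450, 650, 10)
  spec <- speciesSpectra(wl, cbind(A = gaussianBand(wl, 500),
                                   ground = gaussianBand(wl, 600)),
                         ground = gaussianBand(wl, 600))
  times <- 10^seq(-4, -0.5, length.out = 40)
  surf <- simulateSurface(buildRateMatrix(sch), spec, times,
                          excitedFraction = 1)
  dA <- deltaA(surf)
  j <- which.max(abs(dA[1, ]))
  co <- stats::lm(log(abs(dA[, j])) ~ times)$coefficients
  expect_equal(unname(-1 / co[2]), 0.01, tolerance = 1e-6)
})
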