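## Seeded generators for every input the pipeline consumes.  All randomness
## flows from one master seed through fixed per-generator substreams, so
## adding a generator never perturbs existing fixtures and identical
## (config, seed) pairs give bit-identical outputs.

.STREAMS <- c(surface = 1L, darkTrace = 2L, spectrum = 3L,
              chromatogram = 4L, assay = 5L)

## Derive a substream seed below 2^31 from the master seed, a generator
## stream id and a replicate index.
.substream <- function(master, stream, replicate = 1L) {
  as.integer((as.numeric(master) * 1009 + .STREAMS[[stream]] * 101003 +
                (replicate - 1L) * 7919) %% 2147483647)
}

#' Build a synthetic measurement scenario configuration
#'
#' All defaults encode the characterized inward-pump system; see
#' [ScenarioConfig-class] for the meaning of each group.  Any parameter can
#' be overridden, and the object plus its seed fully determine every
#' generated dataset.
#'
#' @param tau photocycle lifetimes (s), fastest first.
#' @param bands named band centres (nm).
#' @param bandFwhm band FWHM in wavenumber (cm^-1).
#' @param fDark,fLight dark- and light-adapted all-trans fractions.
#' @param excitedFraction flash conversion fraction.
#' @param noise named per-data-kind Gaussian noise s.d.
#' @param assay,darkAdapt,hplc parameter lists; supplied entries override
#'   the defaults entry-wise.
#' @param seed master RNG seed.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(tau = c(2e-6, 210e-6, 6.0e-3, 0.2, 91),
                           bands = c(ground = 568, K = 588, L = 538,
                                     M = 410, P13C = 549,
                                     pureAT = 568, pure13C = 549),
                           bandFwhm = 3800,
                           fDark = 0.92, fLight = 0.50,
                           excitedFraction = 0.05,
                           noise = c(surface = 5e-4, trace = 1e-3,
                                     spectrum = 0, chromatogram = 0.02,
                                     ph = 0.002),
                           assay = list(), darkAdapt = list(), hplc = list(),
                           seed = 42L) {
  assayDefaults <- list(
    baseSlope = 0.002,        # WT initial slope, pH s^-1
    tauCell = 200,            # saturation time constant of the suspension, s
    lightOn = 0, lightOff = 150,
    preLight = 50, postLight = 200, dt = 1,
    multipliers = c(WT = 1, D216E = 3, E35D = 0.10, E35Q = 0.05,
                    D74E = 0.12, D108E = 0.10, D108N = 0.06, D216N = 0.05),
    amounts = c(WT = 2e-9, D216E = 1.6e-9),  # mol; unlisted genotypes: WT
    cccpHFactor = 0.05,       # H+ pump signal with CCCP
    cccpClFactor = 2.0,       # Cl- pump signal with CCCP
    tauRelax = 250,           # post-illumination relaxation, s
    volume = 0.003,           # suspension volume, L
    epsilonTrue = 50000,      # pigment extinction used in generation
    basePH = 7.0)
  darkDefaults <- list(amplitude = 0.1, offset = 0.75, duration = 600,
                       dt = 1, wavelength = 585)
  hplcDefaults <- list(
    retention = c(5.5, 7.0, 12.0, 13.5),   # AT-syn, 13C-syn, AT-anti, 13C-anti
    isomer = c("all-trans", "13-cis", "all-trans", "13-cis"),
    peakSd = 0.15, synFraction = 0.65, totalArea = 10,
    windowHalf = 0.7, dt = 0.01, tMax = 20)
  new("ScenarioConfig",
      tau = tau, bands = bands, bandFwhm = bandFwhm,
      fDark = fDark, fLight = fLight, excitedFraction = excitedFraction,
      noise = noise,
      assay = utils::modifyList(assayDefaults, assay),
      darkAdapt = utils::modifyList(darkDefaults, darkAdapt),
      hplc = utils::modifyList(hplcDefaults, hplc),
      seed = as.integer(seed))
}

## log time grid: 30 points per decade from 100 ns to 2 s, the instrument's
## observation window
.defaultTimeGrid <- function(tMin = 1e-7, tMax = 2, perDecade = 30) {
  k <- 0:ceiling(perDecade * log10(tMax / tMin))
  tt <- tMin * 10^(k / perDecade)
  tt[length(tt)] <- tMax          # close exactly at the window edge
  unique(pmin(tt, tMax))
}

#' Generate a synthetic transient-absorption surface
#'
#' Simulates the configured photocycle on the instrument grids (probe
#' wavelengths 360--710 nm in 10 nm steps; logarithmic times, 30 points per
#' decade from 100 ns to 2 s) and adds Gaussian noise.
#'
#' @param cfg a [ScenarioConfig-class].
#' @return a [TransientSurface-class] with noise metadata set.
#' @export
makeTransientDataset <- function(cfg = scenarioConfig()) {
  stopifnot(is(cfg, "ScenarioConfig"))
  sch <- defaultPhotocycleScheme(cfg@tau, cfg@excitedFraction)
  spec <- defaultSpeciesSpectra(
    wavelength = seq(360, 710, by = 10),
    bands = cfg@bands[c("ground", "K", "L", "M", "P13C")],
    fwhm = cfg@bandFwhm)
  times <- .defaultTimeGrid()
  surf <- simulateSurface(buildRateMatrix(sch), spec, times,
                          excitedFraction = cfg@excitedFraction)
  sd <- cfg@noise[["surface"]]
  seed <- .substream(cfg@seed, "surface")
  dA <- deltaA(surf)
  if (sd > 0)
    dA <- dA + withr::with_seed(seed,
            matrix(stats::rnorm(length(dA), sd = sd), nrow(dA)))
  transientSurface(times, wavelengths(surf), dA, noiseSd = sd, seed = seed)
}

#' Generate a synthetic dark-adaptation recovery trace
#'
#' Single-exponential recovery of ground-state absorbance at the probe
#' wavelength (default 585 nm), sampled every second, with Gaussian noise.
#' The recovery lifetime is the last (slowest) entry of `cfg@tau`.
#'
#' @param cfg a [ScenarioConfig-class].
#' @return data.frame with columns `time` (s) and `absorbance`; attributes
#'   `wavelength`, `tau`, `noiseSd`, `seed`.
#' @export
makeDarkAdaptationTrace <- function(cfg = scenarioConfig()) {
  stopifnot(is(cfg, "ScenarioConfig"))
  p <- cfg@darkAdapt
  tauRec <- cfg@tau[length(cfg@tau)]
  tt <- seq(p$dt, p$duration, by = p$dt)
  y <- p$offset - p$amplitude * exp(-tt / tauRec)
  sd <- cfg@noise[["trace"]]
  seed <- .substream(cfg@seed, "darkTrace")
  if (sd > 0)
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), sd = sd))
  structure(data.frame(time = tt, absorbance = y),
            wavelength = p$wavelength, tau = tauRec, noiseSd = sd,
            seed = seed)
}

#' Generate dark- and light-adapted absorption spectra
#'
#' Composes wavenumber-Gaussian pure all-trans and 13-cis bands at the
#' configured fractions.  With the default zero spectrum noise the pair is
#' deterministic and unmixing recovers the pure spectra exactly.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param wavelength evaluation grid (nm).
#' @return list with [Spectrum-class] elements `dark`, `light`,
#'   `pureAllTrans`, `pure13Cis`.
#' @export
makeAbsorptionPair <- function(cfg = scenarioConfig(),
                               wavelength = seq(400, 700, by = 1)) {
  stopifnot(is(cfg, "ScenarioConfig"))
  ## the 13-cis chromophore absorbs slightly more weakly than all-trans
  at <- absorptionSpectrum(wavelength,
          gaussianBand(wavelength, cfg@bands[["pureAT"]], cfg@bandFwhm),
          "pure all-trans")
  c13 <- absorptionSpectrum(wavelength,
          gaussianBand(wavelength, cfg@bands[["pure13C"]], cfg@bandFwhm,
                       height = 0.85),
          "pure 13-cis")
  dark <- composeMixture(at, c13, cfg@fDark, "dark-adapted")
  light <- composeMixture(at, c13, cfg@fLight, "light-adapted")
  sd <- cfg@noise[["spectrum"]]
  if (sd > 0) {
    seed <- .substream(cfg@seed, "spectrum")
    noise <- withr::with_seed(seed,
               matrix(stats::rnorm(2L * length(wavelength), sd = sd), ncol = 2L))
    dark <- absorptionSpectrum(wavelength, absorbance(dark) + noise[, 1L],
                               "dark-adapted")
    light <- absorptionSpectrum(wavelength, absorbance(light) + noise[, 2L],
                                "light-adapted")
  }
  list(dark = dark, light = light, pureAllTrans = at, pure13Cis = c13)
}

#' Generate a synthetic HPLC chromatogram
#'
#' Gaussian peaks at fixed retention times: two windows per isomer (the syn
#' and anti oxime forms), with summed areas proportional to the condition's
#' isomer composition, plus Gaussian detector noise.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param condition `"dark"` or `"light"`, selecting `cfg@fDark` or
#'   `cfg@fLight`.
#' @param replicate replicate index (selects an independent noise
#'   substream).
#' @return a [Chromatogram-class] with assignment windows set.
#' @export
makeChromatogram <- function(cfg = scenarioConfig(),
                             condition = c("dark", "light"),
                             replicate = 1L) {
  stopifnot(is(cfg, "ScenarioConfig"))
  condition <- match.arg(condition)
  f <- if (condition == "dark") cfg@fDark else cfg@fLight
  p <- cfg@hplc
  tt <- seq(0, p$tMax, by = p$dt)
  split <- c(p$synFraction, p$synFraction, 1 - p$synFraction,
             1 - p$synFraction)
  frac <- ifelse(p$isomer == "all-trans", f, 1 - f)
  areas <- p$totalArea * frac * split
  s <- numeric(length(tt))
  for (k in seq_along(p$retention)) {
    h <- areas[k] / (p$peakSd * sqrt(2 * pi))
    s <- s + h * exp(-(tt - p$retention[k])^2 / (2 * p$peakSd^2))
  }
  sd <- cfg@noise[["chromatogram"]]
  if (sd > 0) {
    seed <- .substream(cfg@seed, "chromatogram", replicate)
    s <- s + withr::with_seed(seed, stats::rnorm(length(s), sd = sd))
  }
  win <- data.frame(isomer = p$isomer,
                    start = p$retention - p$windowHalf,
                    end = p$retention + p$windowHalf,
                    stringsAsFactors = FALSE)
  chromatogram(tt, s, win)
}

#' Generate a synthetic pumping-assay panel with bleach spectra
#'
#' Saturating alkalinization traces for each salt, with and without CCCP,
#' following the genotype's transport mode, plus matched pigment and
#' bleached (oxime) spectra for expression normalization.  The light is on
#' between 0 and 150 s.  Genotype activity multipliers default to wild type
#' 1x, the hyperactive acceptor mutant D216E 3x, and strongly reduced
#' values for the impaired mutants; raw slopes also scale with the
#' genotype's expression level, which the bleach spectra encode, so only
#' the normalized activities are comparable across genotypes.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param genotype a name in `cfg@assay$multipliers`, or `"ClR"` for an
#'   inward chloride-pump control panel.
#' @param salts bath salts to cover.
#' @return list with `traces` (list of [PHTrace-class]), `pigment` and
#'   `bleached` ([Spectrum-class]), `volume` (L) and `genotype`.
#' @export
makeAssayPanel <- function(cfg = scenarioConfig(), genotype = "WT",
                           salts = c("NaCl", "CsCl", "Na2SO4")) {
  stopifnot(is(cfg, "ScenarioConfig"))
  p <- cfg@assay
  isCl <- identical(genotype, "ClR")
  mult <- if (isCl) 1 else {
    if (!genotype %in% names(p$multipliers))
      stop("unknown genotype: ", genotype)
    p$multipliers[[genotype]]
  }
  amount <- if (genotype %in% names(p$amounts)) p$amounts[[genotype]]
            else p$amounts[["WT"]]
  relExpr <- amount / p$amounts[["WT"]]

  tt <- seq(-p$preLight, p$lightOff + p$postLight, by = p$dt)
  sdPh <- cfg@noise[["ph"]]
  gSeed <- .substream(cfg@seed, "assay",
                      replicate = sum(utf8ToInt(genotype))) %% 2000000000L
  traces <- list()
  idx <- 0L
  for (salt in salts) {
    for (cccp in c(FALSE, TRUE)) {
      idx <- idx + 1L
      s <- p$baseSlope * mult * relExpr
      if (isCl) {
        if (grepl("SO4", salt)) s <- 0
        if (cccp) s <- s * p$cccpClFactor
      } else {
        if (cccp) s <- s * p$cccpHFactor
      }
      amp <- s * p$tauCell
      rise <- ifelse(tt >= p$lightOn & tt <= p$lightOff,
                     amp * (1 - exp(-(tt - p$lightOn) / p$tauCell)), 0)
      after <- tt > p$lightOff
      endVal <- amp * (1 - exp(-(p$lightOff - p$lightOn) / p$tauCell))
      rise[after] <- endVal * exp(-(tt[after] - p$lightOff) / p$tauRelax)
      pH <- p$basePH + rise
      if (sdPh > 0)
        pH <- pH + withr::with_seed(gSeed + idx,
                                    stats::rnorm(length(tt), sd = sdPh))
      traces[[idx]] <- phTrace(tt, pH, p$lightOn, p$lightOff, salt, cccp,
                               sample = genotype)
    }
  }
  ## bleach pair: pigment band at its lambda-max and the 360 nm oxime band
  wl <- seq(300, 700, by = 1)
  lmax <- if (isCl) 560 else cfg@bands[["ground"]]
  conc <- amount / p$volume
  aPig <- p$epsilonTrue * conc * 1          # path 1 cm
  aOx <- aPig * 33600 / p$epsilonTrue
  pigment <- absorptionSpectrum(wl, gaussianBand(wl, lmax, cfg@bandFwhm,
                                                 height = aPig),
                                sprintf("%s pigment", genotype))
  bleached <- absorptionSpectrum(wl, gaussianBand(wl, 360, cfg@bandFwhm,
                                                  height = aOx),
                                 sprintf("%s bleached (oxime)", genotype))
  list(traces = traces, pigment = pigment, bleached = bleached,
       volume = p$volume, genotype = genotype)
}
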