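#' @import methods
NULL

## ---------------------------------------------------------------------------
## Kinetic model containers
## ---------------------------------------------------------------------------

#' PhotocycleScheme: a first-order kinetic scheme for a rhodopsin photocycle
#'
#' Ordered state names connected by irreversible (or reversible, as paired
#' edges) first-order transitions.  A flash promotes `excitedFraction` of the
#' molecules from the resting (ground) state into the initial photoproduct at
#' time zero; the remainder stays in the ground state and contributes no
#' absorbance change.
#'
#' @slot states ordered character vector of state names.
#' @slot edges data.frame with columns `from`, `to` (state names) and `rate`
#'   (first-order rate constant, s^-1).
#' @slot initialState name of the state populated by the flash (the primary
#'   photoproduct, e.g. the red-shifted K intermediate).
#' @slot groundState name of the resting state the cycle returns to.
#' @slot excitedFraction fraction of molecules entering the cycle per flash,
#'   in (0, 1].
#' @exportClass PhotocycleScheme
setClass("PhotocycleScheme",
  slots = c(
    states          = "character",
    edges           = "data.frame",
    initialState    = "character",
    groundState     = "character",
    excitedFraction = "numeric"
  )
)

setValidity("PhotocycleScheme", function(object) {
  msgs <- character()
  st <- object@states
  if (length(st) < 2L || anyDuplicated(st))
    msgs <- c(msgs, "states must be >= 2 unique names")
  ed <- object@edges
  if (!all(c("from", "to", "rate") %in% names(ed)))
    msgs <- c(msgs, "edges needs columns from, to, rate")
  else {
    if (!all(ed$from %in% st) || !all(ed$to %in% st))
      msgs <- c(msgs, "edge references an unknown state name")
    if (any(ed$from == ed$to))
      msgs <- c(msgs, "self-edges are not allowed")
    if (anyDuplicated(paste(ed$from, ed$to, sep = "\r")))
      msgs <- c(msgs, "duplicate edge between the same ordered state pair")
    if (!is.numeric(ed$rate) || any(!is.finite(ed$rate)) || any(ed$rate <= 0))
      msgs <- c(msgs, "all rates must be finite and > 0")
  }
  if (length(object@initialState) != 1L || !object@initialState %in% st)
    msgs <- c(msgs, "initialState must be one of the states")
  if (length(object@groundState) != 1L || !object@groundState %in% st)
    msgs <- c(msgs, "groundState must be one of the states")
  ef <- object@excitedFraction
  if (length(ef) != 1L || !is.finite(ef) || ef <= 0 || ef > 1)
    msgs <- c(msgs, "excitedFraction must lie in (0, 1]")
  ## every non-ground state must be reachable from the initial photoproduct
  if (length(msgs) == 0L) {
    reach <- object@initialState
    repeat {
      nxt <- unique(c(reach, ed$to[ed$from %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    miss <- setdiff(setdiff(st, object@groundState), reach)
    if (length(miss))
      msgs <- c(msgs, paste0("state(s) not reachable from the photoproduct: ",
                             paste(miss, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a photocycle scheme
#'
#' @param states ordered character vector of state names.
#' @param edges data.frame with columns `from`, `to`, `rate` (s^-1).
#' @param initialState state populated by the flash; defaults to the first
#'   state.
#' @param groundState resting state; defaults to the last state.
#' @param excitedFraction fraction of molecules photoexcited per flash.
#' @return a [PhotocycleScheme-class] object.
#' @examples
#' photocycleScheme(c("A", "B"),
#'                  data.frame(from = "A", to = "B", rate = 1))
#' @export
photocycleScheme <- function(states, edges,
                             initialState = states[1L],
                             groundState = states[length(states)],
                             excitedFraction = 1) {
  new("PhotocycleScheme",
      states = as.character(states),
      edges = as.data.frame(edges, stringsAsFactors = FALSE),
      initialState = initialState, groundState = groundState,
      excitedFraction = as.numeric(excitedFraction))
}

#' RateMatrix: first-order rate coefficient matrix of a kinetic scheme
#'
#' Square matrix K (s^-1) over the scheme's states such that dp/dt = K p.
#' Off-diagonal K[j, i] is the rate from state i to state j; each diagonal
#' entry is minus the sum of its column's off-diagonals, so total population
#' is conserved.
#'
#' @exportClass RateMatrix
setClass("RateMatrix", contains = "matrix")

setValidity("RateMatrix", function(object) {
  m <- unclass(object)
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "needs matching state dimnames")
  off <- m; diag(off) <- 0
  if (any(off < 0)) msgs <- c(msgs, "off-diagonal rates must be >= 0")
  scale <- max(abs(m), 1)
  if (any(abs(colSums(m)) > 1e-9 * scale))
    msgs <- c(msgs, "column sums must vanish (population conservation)")
  if (length(msgs)) msgs else TRUE
})

#' SpeciesSpectra: per-state molar absorption profiles on one wavelength grid
#'
#' @slot wavelength wavelength grid in nm, strictly increasing.
#' @slot profiles matrix (wavelength x state) of non-negative absorption
#'   profiles, columns named by state.
#' @slot ground reference resting-state profile on the same grid.
#' @exportClass SpeciesSpectra
setClass("SpeciesSpectra",
  slots = c(wavelength = "numeric", profiles = "matrix", ground = "numeric")
)

setValidity("SpeciesSpectra", function(object) {
  msgs <- character()
  wl <- object@wavelength
  if (length(wl) < 2L || any(diff(wl) <= 0))
    msgs <- c(msgs, "wavelength grid must be strictly increasing")
  p <- object@profiles
  if (nrow(p) != length(wl))
    msgs <- c(msgs, "profiles rows must match the wavelength grid")
  if (is.null(colnames(p)))
    msgs <- c(msgs, "profiles columns must be named by state")
  if (any(p < 0) || any(object@ground < 0))
    msgs <- c(msgs, "absorption profiles must be non-negative")
  if (length(object@ground) != length(wl))
    msgs <- c(msgs, "ground profile must match the wavelength grid")
  if (length(msgs)) msgs else TRUE
})

#' Construct a species-spectra set
#'
#' @param wavelength wavelength grid (nm).
#' @param profiles wavelength x state matrix with state column names.
#' @param ground reference ground-state profile; defaults to the column named
#'   `"ground"`.
#' @return a [SpeciesSpectra-class] object.
#' @export
speciesSpectra <- function(wavelength, profiles,
                           ground = profiles[, "ground"]) {
  new("SpeciesSpectra", wavelength = as.numeric(wavelength),
      profiles = as.matrix(profiles), ground = as.numeric(ground))
}

#' TransientSurface: a flash-photolysis absorbance-change surface
#'
#' Absorbance change after the flash, on a (time x wavelength) grid, with
#' optional noise metadata recording how a synthetic surface was generated.
#'
#' @slot time time grid in seconds, strictly increasing, all > 0.
#' @slot wavelength probe wavelength grid in nm, strictly increasing.
#' @slot deltaA matrix (time x wavelength) of absorbance changes.
#' @slot noiseSd Gaussian noise s.d. used in generation (NA for measured or
#'   unknown).
#' @slot seed RNG seed used in generation (NA if none).
#' @exportClass TransientSurface
setClass("TransientSurface",
  slots = c(time = "numeric", wavelength = "numeric", deltaA = "matrix",
            noiseSd = "numeric", seed = "numeric")
)

setValidity("TransientSurface", function(object) {
  msgs <- character()
  if (length(object@time) < 2L || any(diff(object@time) <= 0))
    msgs <- c(msgs, "time grid must be strictly increasing")
  if (any(object@time <= 0))
    msgs <- c(msgs, "time grid must be positive (post-flash)")
  if (length(object@wavelength) < 1L || any(diff(object@wavelength) <= 0))
    msgs <- c(msgs, "wavelength grid must be strictly increasing")
  if (!identical(dim(object@deltaA),
                 c(length(object@time), length(object@wavelength))))
    msgs <- c(msgs, "deltaA dimensions must match time x wavelength grids")
  if (any(!is.finite(object@deltaA)))
    msgs <- c(msgs, "deltaA must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a transient-absorption surface
#'
#' @param time time grid (s), strictly increasing, positive.
#' @param wavelength wavelength grid (nm), strictly increasing.
#' @param deltaA matrix (time x wavelength) of absorbance changes.
#' @param noiseSd,seed optional generation metadata.
#' @return a [TransientSurface-class] object.
#' @export
transientSurface <- function(time, wavelength, deltaA,
                             noiseSd = NA_real_, seed = NA_real_) {
  new("TransientSurface", time = as.numeric(time),
      wavelength = as.numeric(wavelength), deltaA = as.matrix(deltaA),
      noiseSd = as.numeric(noiseSd), seed = as.numeric(seed))
}

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' GlobalFitResult: shared time constants and decay-associated spectra
#'
#' Result of a global multi-exponential fit: time constants shared across all
#' probe wavelengths, one decay-associated spectrum (DAS) per time constant,
#' and an optional non-decaying offset spectrum.
#'
#' @slot tau time constants in seconds, strictly increasing.
#' @slot das matrix (component x wavelength) of pre-exponential amplitude
#'   spectra.
#' @slot offset non-decaying spectrum A_inf(lambda); length zero when the fit
#'   had no offset term.
#' @slot time,wavelength the grids of the fitted surface.
#' @slot residuals matrix (time x wavelength) of weighted residuals.
#' @slot rss residual sum of squares.
#' @slot meta list of convergence metadata (restarts, seed, iterations,
#'   warnings).
#' @exportClass GlobalFitResult
setClass("GlobalFitResult",
  slots = c(tau = "numeric", das = "matrix", offset = "numeric",
            time = "numeric", wavelength = "numeric",
            residuals = "matrix", rss = "numeric", meta = "list")
)

setValidity("GlobalFitResult", function(object) {
  msgs <- character()
  tau <- object@tau
  if (length(tau) && (any(tau <= 0) || any(diff(tau) <= 0)))
    msgs <- c(msgs, "tau must be positive and strictly increasing")
  if (nrow(object@das) != length(tau))
    msgs <- c(msgs, "one DAS row per time constant required")
  if (ncol(object@das) != length(object@wavelength))
    msgs <- c(msgs, "DAS columns must match the wavelength grid")
  if (length(object@offset) &&
      length(object@offset) != length(object@wavelength))
    msgs <- c(msgs, "offset spectrum must match the wavelength grid")
  rssre <- sum(object@residuals^2)
  if (abs(rssre - object@rss) > 1e-12 * max(object@rss, 1e-300))
    msgs <- c(msgs, "stored RSS inconsistent with stored residuals")
  if (length(msgs)) msgs else TRUE
})

#' TraceFitResult: multi-exponential fit of a single kinetic trace
#'
#' @slot tau time constants (s), strictly increasing.
#' @slot amplitudes pre-exponential amplitudes, one per time constant.
#' @slot offset additive constant (NA when the model had none).
#' @slot time,values the fitted trace.
#' @slot fitted model values on the trace's time grid.
#' @slot rss residual sum of squares.
#' @slot meta convergence metadata list.
#' @exportClass TraceFitResult
setClass("TraceFitResult",
  slots = c(tau = "numeric", amplitudes = "numeric", offset = "numeric",
            time = "numeric", values = "numeric", fitted = "numeric",
            rss = "numeric", meta = "list")
)

setValidity("TraceFitResult", function(object) {
  msgs <- character()
  if (length(object@tau) &&
      (any(object@tau <= 0) || any(diff(object@tau) <= 0)))
    msgs <- c(msgs, "tau must be positive and strictly increasing")
  if (length(object@amplitudes) != length(object@tau))
    msgs <- c(msgs, "one amplitude per time constant required")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Steady-state spectra and isomer composition
## ---------------------------------------------------------------------------

#' Spectrum: absorbance versus wavelength
#'
#' A steady-state absorption (or difference) spectrum.  Difference spectra
#' may be negative; non-negativity is only demanded of pure-species spectra
#' by the functions that produce them.
#'
#' @slot wavelength wavelength grid (nm), strictly increasing.
#' @slot absorbance absorbance values (dimensionless), finite.
#' @slot label free-text label.
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(wavelength = "numeric", absorbance = "numeric", label = "character")
)

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@wavelength) < 1L || any(diff(object@wavelength) <= 0))
    msgs <- c(msgs, "wavelength grid must be strictly increasing")
  if (length(object@absorbance) != length(object@wavelength))
    msgs <- c(msgs, "absorbance length must match wavelength grid")
  if (any(!is.finite(object@absorbance)))
    msgs <- c(msgs, "absorbance must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct an absorption spectrum
#'
#' @param wavelength wavelength grid (nm).
#' @param absorbance absorbance values.
#' @param label optional label.
#' @return a [Spectrum-class] object.
#' @export
absorptionSpectrum <- function(wavelength, absorbance, label = "") {
  new("Spectrum", wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance), label = as.character(label))
}

#' IsomerFractions: retinal isomer molar composition
#'
#' All-trans and 13-cis molar fractions of the retinal chromophore under a
#' given adaptation condition, with an optional replicate s.d.
#'
#' @slot fAT all-trans molar fraction in \[0, 1\]; the 13-cis fraction is
#'   1 - fAT.
#' @slot sd replicate standard deviation of fAT (NA if single measurement).
#' @slot condition condition label, e.g. "dark" or "light".
#' @exportClass IsomerFractions
setClass("IsomerFractions",
  slots = c(fAT = "numeric", sd = "numeric", condition = "character")
)

setValidity("IsomerFractions", function(object) {
  msgs <- character()
  if (length(object@fAT) != 1L || !is.finite(object@fAT) ||
      object@fAT < 0 || object@fAT > 1)
    msgs <- c(msgs, "fAT must be a single value in [0, 1]")
  if (length(object@sd) != 1L || (!is.na(object@sd) && object@sd < 0))
    msgs <- c(msgs, "sd must be NA or >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct an isomer-fraction record
#'
#' @param fAT all-trans molar fraction.
#' @param sd replicate s.d. (NA for a single measurement).
#' @param condition adaptation condition label.
#' @return an [IsomerFractions-class] object.
#' @export
isomerFractions <- function(fAT, sd = NA_real_, condition = NA_character_) {
  new("IsomerFractions", fAT = as.numeric(fAT), sd = as.numeric(sd),
      condition = as.character(condition))
}

## ---------------------------------------------------------------------------
## HPLC containers
## ---------------------------------------------------------------------------

#' Chromatogram: HPLC detector trace with isomer assignment windows
#'
#' @slot time retention-time grid in minutes, strictly increasing.
#' @slot signal detector signal (arbitrary units).
#' @slot windows data.frame with columns `isomer`, `start`, `end` giving the
#'   non-overlapping retention windows assigned to each retinal-oxime peak.
#' @exportClass Chromatogram
setClass("Chromatogram",
  slots = c(time = "numeric", signal = "numeric", windows = "data.frame")
)

setValidity("Chromatogram", function(object) {
  msgs <- character()
  if (length(object@time) < 2L || any(diff(object@time) <= 0))
    msgs <- c(msgs, "retention-time grid must be strictly increasing")
  if (length(object@signal) != length(object@time))
    msgs <- c(msgs, "signal length must match the time grid")
  w <- object@windows
  if (!all(c("isomer", "start", "end") %in% names(w)))
    msgs <- c(msgs, "windows needs columns isomer, start, end")
  else if (nrow(w)) {
    if (any(w$end <= w$start))
      msgs <- c(msgs, "each window must have start < end")
    o <- order(w$start)
    if (any(w$start[o][-1L] < w$end[o][-nrow(w)]))
      msgs <- c(msgs, "assignment windows must not overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a chromatogram
#'
#' @param time retention-time grid (min).
#' @param signal detector signal.
#' @param windows assignment windows data.frame (`isomer`, `start`, `end`).
#' @return a [Chromatogram-class] object.
#' @export
chromatogram <- function(time, signal,
                         windows = data.frame(isomer = character(),
                                              start = numeric(),
                                              end = numeric())) {
  new("Chromatogram", time = as.numeric(time), signal = as.numeric(signal),
      windows = as.data.frame(windows, stringsAsFactors = FALSE))
}

#' PeakTable: detected and integrated chromatogram peaks
#'
#' @slot peaks data.frame with columns `apex` (retention time, min), `area`
#'   (baseline-corrected area, >= 0), `isomer` (assignment or "unassigned")
#'   and `merged` (TRUE when several detected peaks shared one window).
#' @exportClass PeakTable
setClass("PeakTable", slots = c(peaks = "data.frame"))

setValidity("PeakTable", function(object) {
  p <- object@peaks
  msgs <- character()
  if (!all(c("apex", "area", "isomer", "merged") %in% names(p)))
    msgs <- c(msgs, "peaks needs columns apex, area, isomer, merged")
  else if (nrow(p) && any(p$area < 0))
    msgs <- c(msgs, "peak areas must be >= 0")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Pump-assay containers
## ---------------------------------------------------------------------------

#' PHTrace: pH of an illuminated cell suspension versus time
#'
#' @slot time time grid in seconds, strictly increasing.
#' @slot pH measured pH values.
#' @slot lightOn,lightOff illumination window bounds (s); both NA for a
#'   dark-only trace.
#' @slot salt bath salt, e.g. "NaCl", "CsCl", "Na2SO4".
#' @slot cccp TRUE when the protonophore CCCP was present.
#' @slot sample sample label (genotype etc.).
#' @exportClass PHTrace
setClass("PHTrace",
  slots = c(time = "numeric", pH = "numeric",
            lightOn = "numeric", lightOff = "numeric",
            salt = "character", cccp = "logical", sample = "character")
)

setValidity("PHTrace", function(object) {
  msgs <- character()
  if (length(object@time) < 2L || any(diff(object@time) <= 0))
    msgs <- c(msgs, "time grid must be strictly increasing")
  if (length(object@pH) != length(object@time))
    msgs <- c(msgs, "pH length must match the time grid")
  on <- object@lightOn; off <- object@lightOff
  if (is.na(on) != is.na(off))
    msgs <- c(msgs, "lightOn and lightOff must both be set or both NA")
  if (!is.na(on)) {
    if (on >= off) msgs <- c(msgs, "lightOn must precede lightOff")
    if (on < min(object@time) || off > max(object@time))
      msgs <- c(msgs, "illumination window must lie inside the trace")
  }
  if (length(object@cccp) != 1L || is.na(object@cccp))
    msgs <- c(msgs, "cccp must be TRUE or FALSE")
  if (length(msgs)) msgs else TRUE
})

#' Construct a pH trace
#'
#' @param time time grid (s).
#' @param pH pH values.
#' @param lightOn,lightOff illumination window (s); NA for dark-only.
#' @param salt bath salt label.
#' @param cccp logical, protonophore present.
#' @param sample sample label.
#' @return a [PHTrace-class] object.
#' @export
phTrace <- function(time, pH, lightOn = NA_real_, lightOff = NA_real_,
                    salt = "NaCl", cccp = FALSE, sample = "") {
  new("PHTrace", time = as.numeric(time), pH = as.numeric(pH),
      lightOn = as.numeric(lightOn), lightOff = as.numeric(lightOff),
      salt = as.character(salt), cccp = as.logical(cccp),
      sample = as.character(sample))
}

#' ExpressionResult: pigment extinction coefficient and expressed amount
#'
#' Derived from hydroxylamine bleaching: the pigment band is referenced to
#' the 360 nm retinal-oxime band of known molar extinction.
#'
#' @slot epsilon molar extinction coefficient of the pigment at its
#'   absorption maximum (M^-1 cm^-1), > 0.
#' @slot amount amount of pigment in the assayed suspension (mol), > 0.
#' @exportClass ExpressionResult
setClass("ExpressionResult", slots = c(epsilon = "numeric", amount = "numeric"))

setValidity("ExpressionResult", function(object) {
  msgs <- character()
  if (length(object@epsilon) != 1L || !is.finite(object@epsilon) ||
      object@epsilon <= 0)
    msgs <- c(msgs, "epsilon must be a single positive value")
  if (length(object@amount) != 1L || !is.finite(object@amount) ||
      object@amount <= 0)
    msgs <- c(msgs, "amount must be a single positive value")
  if (length(msgs)) msgs else TRUE
})

#' TransportCall: classified transport mode of a salt x CCCP assay panel
#'
#' @slot mode one of "inward H+ pump", "inward Cl- pump",
#'   "none/indeterminate".
#' @slot slopes data.frame of per-condition initial slopes (`salt`, `cccp`,
#'   `slope`).
#' @slot activity expression-normalized activity (pH s^-1 mol^-1); NA when no
#'   expression result was supplied.
#' @exportClass TransportCall
setClass("TransportCall",
  slots = c(mode = "character", slopes = "data.frame", activity = "numeric")
)

setValidity("TransportCall", function(object) {
  ok <- c("inward H+ pump", "inward Cl- pump", "none/indeterminate")
  if (length(object@mode) != 1L || !object@mode %in% ok)
    return(sprintf("mode must be one of: %s", paste(ok, collapse = ", ")))
  TRUE
})

## ---------------------------------------------------------------------------
## Scenario configuration for the synthetic generators
## ---------------------------------------------------------------------------

#' ScenarioConfig: parameters of the synthetic measurement scenario
#'
#' One object holds every tunable of the synthetic generators.  The defaults
#' encode the characterized inward-pump system: five photocycle lifetimes
#' (2 us, 210 us, 6.0 ms, 200 ms, 91 s), chromophore band centres (ground
#' 568 nm; K +20 nm; L -30 nm; M 410 nm; 13-cis photoproduct 549 nm), dark /
#' light isomer fractions 0.92 / 0.50, and an illumination window of
#' 0--150 s for the pumping assay.  Identical config + seed gives
#' bit-identical outputs; every generator draws from its own substream of
#' the master seed.
#'
#' @slot tau photocycle lifetimes in seconds, fastest first.
#' @slot bands named band centres (nm) for states `ground`, `K`, `L`, `M`,
#'   `P13C` and for the pure isomers `pureAT`, `pure13C`.
#' @slot bandFwhm band full width at half maximum in wavenumber (cm^-1).
#' @slot fDark,fLight all-trans fraction in the dark- and light-adapted
#'   states.
#' @slot excitedFraction fraction of molecules cycling per flash.
#' @slot noise named noise s.d. per data kind (`surface`, `trace`,
#'   `spectrum`, `chromatogram`, `ph`).
#' @slot assay list of pumping-assay parameters (base slope, cell time
#'   constant, illumination window, genotype activity multipliers, CCCP
#'   factors, expressed amounts, suspension volume).
#' @slot darkAdapt list of dark-adaptation trace parameters (amplitude,
#'   offset, duration, sampling interval, probe wavelength).
#' @slot hplc list of chromatogram parameters (retention times, peak width,
#'   syn/anti split, total area, grid).
#' @slot seed master RNG seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  slots = c(tau = "numeric", bands = "numeric", bandFwhm = "numeric",
            fDark = "numeric", fLight = "numeric",
            excitedFraction = "numeric", noise = "numeric",
            assay = "list", darkAdapt = "list", hplc = "list",
            seed = "integer")
)

setValidity("ScenarioConfig", function(object) {
  msgs <- character()
  if (length(object@tau) < 1L || any(object@tau <= 0) ||
      any(diff(object@tau) <= 0))
    msgs <- c(msgs, "tau must be positive and ascending")
  need <- c("ground", "K", "L", "M", "P13C", "pureAT", "pure13C")
  if (!all(need %in% names(object@bands)))
    msgs <- c(msgs, paste("bands must name:", paste(need, collapse = ", ")))
  for (f in c("fDark", "fLight")) {
    v <- slot(object, f)
    if (length(v) != 1L || v < 0 || v > 1)
      msgs <- c(msgs, paste(f, "must lie in [0, 1]"))
  }
  if (object@excitedFraction <= 0 || object@excitedFraction > 1)
    msgs <- c(msgs, "excitedFraction must lie in (0, 1]")
  if (any(object@noise < 0)) msgs <- c(msgs, "noise s.d. must be >= 0")
  if (length(msgs)) msgs else TRUE
})
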