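## Forward model for first-order photocycle kinetics: rate matrices,
## analytic population propagation, apparent time constants and synthesis of
## transient-absorption surfaces.

#' Default sequential photocycle scheme
#'
#' The strictly sequential, irreversible chain
#' `K -> L -> M1 -> M2 -> P13C -> ground` parameterized by five lifetimes.
#' The defaults are the characterized inward-pump cycle: K decays to the
#' blue-shifted L intermediate in 2 us, the deprotonated-Schiff-base M state
#' accumulates with two lifetimes (210 us via the L/M equilibrium state M1
#' and 6.0 ms into M2), M decays in 200 ms to the metastable 13-cis ground
#' state, which thermally reverts to the all-trans resting state in 91 s.
#'
#' @param tau five lifetimes in seconds, fastest first.
#' @param excitedFraction fraction of molecules photoexcited per flash.  The
#'   conversion per flash is instrument-dependent and enters only as an
#'   overall amplitude scale; the default 0.05 is a typical single-flash
#'   value.
#' @return a [PhotocycleScheme-class] for the six-state chain.
#' @seealso [photocycleScheme()] for arbitrary (including reversible)
#'   schemes.
#' @examples
#' sch <- defaultPhotocycleScheme()
#' apparentTimeConstants(buildRateMatrix(sch))
#' @export
defaultPhotocycleScheme <- function(tau = c(2e-6, 210e-6, 6.0e-3, 0.2, 91),
                                    excitedFraction = 0.05) {
  stopifnot(length(tau) == 5L, all(tau > 0))
  states <- c("K", "L", "M1", "M2", "P13C", "ground")
  edges <- data.frame(from = states[1:5], to = states[2:6], rate = 1 / tau,
                      stringsAsFactors = FALSE)
  photocycleScheme(states, edges, initialState = "K",
                   groundState = "ground",
                   excitedFraction = excitedFraction)
}

#' Build the first-order rate matrix of a scheme
#'
#' Assembles K with K\[j, i\] = rate(i -> j) and diagonal entries equal to
#' minus the column sums of the off-diagonals, so that dp/dt = K p conserves
#' total population.
#'
#' @param scheme a [PhotocycleScheme-class].
#' @return a [RateMatrix-class] (states x states, s^-1).
#' @examples
#' sch <- photocycleScheme(c("A", "B"),
#'                         data.frame(from = "A", to = "B", rate = 1))
#' buildRateMatrix(sch)
#' @export
buildRateMatrix <- function(scheme) {
  stopifnot(is(scheme, "PhotocycleScheme"))
  validObject(scheme)
  st <- scheme@states
  n <- length(st)
  K <- matrix(0, n, n, dimnames = list(st, st))
  ed <- scheme@edges
  for (i in seq_len(nrow(ed))) {
    K[ed$to[i], ed$from[i]] <- K[ed$to[i], ed$from[i]] + ed$rate[i]
    K[ed$from[i], ed$from[i]] <- K[ed$from[i], ed$from[i]] - ed$rate[i]
  }
  new("RateMatrix", K)
}

#' Initial population vector of a scheme
#'
#' Places `excitedFraction` in the initial photoproduct and the remainder in
#' the ground state.
#'
#' @param scheme a [PhotocycleScheme-class].
#' @return named numeric vector over the scheme's states, summing to 1.
#' @export
initialPopulations <- function(scheme) {
  p0 <- stats::setNames(numeric(length(scheme@states)), scheme@states)
  p0[scheme@initialState] <- scheme@excitedFraction
  p0[scheme@groundState] <- p0[scheme@groundState] + 1 - scheme@excitedFraction
  p0
}

## Eigenvalues of K.  Triangular matrices are handled exactly (their
## eigenvalues are the diagonal), everything else goes through LAPACK.
.rateEigen <- function(K) {
  m <- unclass(K)
  off <- m; diag(off) <- 0
  if (all(off[upper.tri(off)] == 0) || all(off[lower.tri(off)] == 0)) {
    ord <- order(diag(m))
    vals <- diag(m)[ord]
    list(values = vals, triangular = TRUE)
  } else {
    e <- eigen(m)
    list(values = e$values, vectors = e$vectors, triangular = FALSE)
  }
}

#' Propagate state populations analytically
#'
#' Solves dp/dt = K p by eigendecomposition, p(t) = V exp(D t) V^-1 p0,
#' which is exact and stable across the eight time decades a photocycle
#' spans.  When the eigensystem is defective or near-degenerate (minimum
#' relative eigenvalue gap below `degenerateTol`) the propagation falls back
#' to stiff ODE integration ([deSolve::ode()], `lsoda`, rtol 1e-10) and the
#' result is flagged.
#'
#' @param K a [RateMatrix-class].
#' @param p0 initial populations; non-negative, summing to 1.
#' @param times time grid (s), strictly increasing, >= 0 allowed.
#' @param degenerateTol relative eigenvalue-gap threshold triggering the ODE
#'   fallback.
#' @return matrix (time x states) of populations, with attribute
#'   `"propagation"` equal to `"eigen"` or `"ode"`.
#' @examples
#' sch <- photocycleScheme(c("A", "B"),
#'                         data.frame(from = "A", to = "B", rate = 1))
#' propagatePopulations(buildRateMatrix(sch), c(A = 1, B = 0), 1)
#' @export
propagatePopulations <- function(K, p0, times, degenerateTol = 1e-9) {
  m <- unclass(K)
  n <- nrow(m)
  stopifnot(length(p0) == n, all(p0 >= 0))
  if (abs(sum(p0) - 1) > 1e-8)
    stop("p0 must sum to 1")
  if (any(diff(times) <= 0) || any(times < 0))
    stop("times must be non-negative and strictly increasing")

  useODE <- FALSE
  e <- eigen(m)
  ev <- e$values
  scale <- max(abs(ev), .Machine$double.xmin)
  if (n > 1L) {
    gaps <- abs(outer(ev, ev, "-"))
    mingap <- min(gaps[upper.tri(gaps)])
    if (mingap < degenerateTol * scale) useODE <- TRUE
  }
  ## a numerically singular eigenvector basis indicates a defective system
  c0 <- NULL
  if (!useODE) {
    c0 <- tryCatch(solve(e$vectors, p0), error = function(err) NULL)
    if (is.null(c0)) useODE <- TRUE
  }

  if (!useODE) {
    P <- t(vapply(times,
                  function(t) Re(e$vectors %*% (c0 * exp(ev * t)))[, 1L],
                  numeric(n)))
    method <- "eigen"
  } else {
    t0 <- if (times[1L] > 0) c(0, times) else times
    sol <- deSolve::ode(y = as.numeric(p0), times = t0,
                        func = function(t, y, parms) list(as.vector(m %*% y)),
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    P <- unname(sol[match(times, sol[, 1L]), -1L, drop = FALSE])
    method <- "ode"
  }
  dimnames(P) <- list(NULL, rownames(m))
  ## numerical cleanup: clip tiny negatives from roundoff
  P[P < 0 & P > -1e-10] <- 0
  attr(P, "propagation") <- method
  P
}

#' Apparent time constants of a kinetic scheme
#'
#' The observable phases of first-order kinetics are the reciprocals of the
#' nonzero rate-matrix eigenvalues, returned ascending.  For an irreversible
#' sequential chain these equal the edge lifetimes exactly (the matrix is
#' triangular).  Complex eigenvalues are rejected: oscillatory kinetics are
#' unphysical for this model class.
#'
#' @param K a [RateMatrix-class].
#' @param zeroTol relative threshold below which an eigenvalue is treated as
#'   zero (the conserved mode).
#' @return numeric vector of time constants in seconds, ascending.
#' @export
apparentTimeConstants <- function(K, zeroTol = 1e-12) {
  e <- .rateEigen(K)
  ev <- e$values
  if (is.complex(ev)) {
    if (any(abs(Im(ev)) > 1e-9 * pmax(abs(Re(ev)), 1e-300)))
      stop("complex eigenvalues: oscillatory kinetics are not supported")
    ev <- Re(ev)
  }
  scale <- max(abs(ev))
  nz <- ev[abs(ev) > zeroTol * scale]
  sort(-1 / nz)
}

#' Synthesize a transient-absorption surface from a kinetic model
#'
#' Computes the absorbance change
#' deltaA(t, lambda) = sum_s p_s(t) (eps_s(lambda) - eps_ground(lambda)),
#' where the populations start with `excitedFraction` in the initial
#' photoproduct.  Molecules that stay in the ground state contribute nothing,
#' so the surface is proportional to the excited fraction and tends to the
#' (terminal state - ground) difference spectrum once all faster phases are
#' complete.
#'
#' @param K a [RateMatrix-class].
#' @param spectra a [SpeciesSpectra-class] covering every state of `K`.
#' @param times observation time grid (s), positive, strictly increasing.
#' @param excitedFraction fraction photoexcited per flash.
#' @param initialState,groundState state names; default first/last state of
#'   `K`.
#' @return a noiseless [TransientSurface-class].
#' @export
simulateSurface <- function(K, spectra, times, excitedFraction = 0.05,
                            initialState = rownames(K)[1L],
                            groundState = rownames(K)[nrow(K)]) {
  st <- rownames(unclass(K))
  if (!all(st %in% colnames(spectra@profiles)))
    stop("spectra must provide a profile for every state of the rate matrix")
  p0 <- stats::setNames(numeric(length(st)), st)
  p0[initialState] <- excitedFraction
  p0[groundState] <- p0[groundState] + 1 - excitedFraction
  P <- propagatePopulations(K, p0, times)
  D <- spectra@profiles[, st, drop = FALSE] - spectra@ground  # nwl x nstate
  dA <- P %*% t(D)                                            # nt x nwl
  transientSurface(times, spectra@wavelength, dA, noiseSd = 0)
}

#' Wavenumber-Gaussian absorption band
#'
#' Retinal-protein absorption bands are modelled as Gaussians in wavenumber
#' (1/lambda): `height * exp(-4 ln 2 ((1e7/lambda - 1e7/center) / fwhm)^2)`.
#' The band maximum in wavelength is exactly `center`.
#'
#' @param wavelength evaluation grid (nm).
#' @param center band centre (nm).
#' @param fwhm full width at half maximum in wavenumber (cm^-1); 3800 cm^-1
#'   is typical of retinal-protein visible bands.
#' @param height peak amplitude.
#' @return numeric vector of absorbances.
#' @export
gaussianBand <- function(wavelength, center, fwhm = 3800, height = 1) {
  nu <- 1e7 / wavelength
  nu0 <- 1e7 / center
  height * exp(-4 * log(2) * ((nu - nu0) / fwhm)^2)
}

#' Default species spectra for the sequential photocycle
#'
#' Wavenumber-Gaussian bands at the configured centres on a given wavelength
#' grid.  The mixed state M1 (the L/M equilibrium) is a 50/50 superposition
#' of the L and M bands, making the second M-formation phase spectrally
#' visible; the M band carries a reduced amplitude typical of
#' deprotonated-Schiff-base states.
#'
#' @param wavelength wavelength grid (nm); the instrument default is
#'   360--710 nm in 10 nm steps.
#' @param bands named centres (nm) for `ground`, `K`, `L`, `M`, `P13C`.
#' @param fwhm band FWHM in wavenumber (cm^-1).
#' @param mHeight relative amplitude of the M band.
#' @return a [SpeciesSpectra-class] for states K, L, M1, M2, P13C, ground.
#' @export
defaultSpeciesSpectra <- function(wavelength = seq(360, 710, by = 10),
                                  bands = c(ground = 568, K = 588, L = 538,
                                            M = 410, P13C = 549),
                                  fwhm = 3800, mHeight = 0.75) {
  g <- gaussianBand(wavelength, bands[["ground"]], fwhm)
  Kb <- gaussianBand(wavelength, bands[["K"]], fwhm)
  Lb <- gaussianBand(wavelength, bands[["L"]], fwhm)
  Mb <- gaussianBand(wavelength, bands[["M"]], fwhm, height = mHeight)
  Pb <- gaussianBand(wavelength, bands[["P13C"]], fwhm)
  prof <- cbind(K = Kb, L = Lb, M1 = 0.5 * Lb + 0.5 * Mb, M2 = Mb,
                P13C = Pb, ground = g)
  speciesSpectra(wavelength, prof, ground = g)
}
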