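## Linear spectral unmixing of chromophore isomer mixtures, band-maximum
## detection, and mixture composition.

.sameGrid <- function(a, b) {
  length(a@wavelength) == length(b@wavelength) &&
    all(abs(a@wavelength - b@wavelength) <
          1e-9 * pmax(abs(a@wavelength), 1))
}

.asFraction <- function(f) {
  if (is(f, "IsomerFractions")) f@fAT else as.numeric(f)
}

#' Unmix dark- and light-adapted spectra into pure isomer spectra
#'
#' Each observed spectrum is a linear mixture
#' `S_obs = f * S_AT + (1 - f) * S_13C` of the pure all-trans and 13-cis
#' chromophore spectra.  Given two observations with different all-trans
#' fractions the 2x2 system is solved per wavelength in closed form.  The
#' system becomes singular as the fractions approach each other; a
#' fraction difference below `minSeparation` is rejected with a
#' conditioning diagnostic.
#'
#' Negative values in the recovered pure spectra are reported with a
#' warning, not clipped: they diagnose incorrect input fractions.
#'
#' @param sDark,sLight observed [Spectrum-class] objects on one grid.
#' @param fDark,fLight all-trans fractions of the two conditions, as numbers
#'   or [IsomerFractions-class] objects.
#' @param minSeparation smallest acceptable |fDark - fLight| (default 0.05).
#' @return list with elements `allTrans` and `cis13`, the calculated
#'   100%-isomer [Spectrum-class] objects.
#' @examples
#' wl <- 400:700
#' at <- absorptionSpectrum(wl, gaussianBand(wl, 568))
#' c13 <- absorptionSpectrum(wl, gaussianBand(wl, 549))
#' dk <- composeMixture(at, c13, 0.92)
#' lt <- composeMixture(at, c13, 0.50)
#' pure <- unmixPureSpectra(dk, lt, 0.92, 0.50)
#' findLambdaMax(pure$allTrans)
#' @export
unmixPureSpectra <- function(sDark, sLight, fDark, fLight,
                             minSeparation = 0.05) {
  stopifnot(is(sDark, "Spectrum"), is(sLight, "Spectrum"))
  if (!.sameGrid(sDark, sLight))
    stop("spectra must share one wavelength grid")
  fD <- .asFraction(fDark)
  fL <- .asFraction(fLight)
  det <- fD - fL
  if (abs(det) < minSeparation)
    stop(sprintf(paste0(
      "ill-conditioned unmixing: |fDark - fLight| = %.3g < %.3g; the two ",
      "mixtures are too similar to separate"), abs(det), minSeparation))
  aD <- sDark@absorbance
  aL <- sLight@absorbance
  sAT <- ((1 - fL) * aD - (1 - fD) * aL) / det
  s13 <- (fD * aL - fL * aD) / det
  if (any(sAT < 0) || any(s13 < 0))
    warning(paste("negative absorbance in recovered pure spectra;",
                  "check the supplied isomer fractions"), call. = FALSE)
  list(allTrans = absorptionSpectrum(sDark@wavelength, sAT,
                                     "100% all-trans (calculated)"),
       cis13 = absorptionSpectrum(sDark@wavelength, s13,
                                  "100% 13-cis (calculated)"))
}

#' Locate the absorption maximum of a spectrum
#'
#' Parabolic interpolation through the maximal sample and its two
#' neighbours, reported at 0.1 nm resolution (fixed so results are
#' deterministic).  A maximum on the grid boundary is an error: the true
#' band maximum lies outside the scanned range.  A flat three-point plateau
#' returns its midpoint with a warning.
#'
#' @param spectrum a [Spectrum-class] with at least 3 points.
#' @return the wavelength of maximal absorbance (nm).
#' @export
findLambdaMax <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  wl <- spectrum@wavelength
  ab <- spectrum@absorbance
  if (length(wl) < 3L) stop("need at least 3 grid points")
  imax <- which(ab == max(ab))
  if (length(imax) > 1L && all(diff(imax) == 1L)) {
    warning("flat plateau at the maximum; returning its midpoint",
            call. = FALSE)
    return(round(mean(wl[imax]), 1))
  }
  i <- imax[1L]
  if (i == 1L || i == length(wl))
    stop("lambda-max outside scanned range (maximum at grid boundary)")
  x <- wl[(i - 1L):(i + 1L)]
  y <- ab[(i - 1L):(i + 1L)]
  ## vertex of the parabola through the three points (non-uniform grids ok)
  d1 <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d2 <- (y[3L] - y[2L]) / (x[3L] - x[2L])
  a <- (d2 - d1) / (x[3L] - x[1L])
  if (a == 0) {
    warning("degenerate curvature at the maximum; returning the grid point",
            call. = FALSE)
    return(round(x[2L], 1))
  }
  vertex <- (x[1L] + x[2L]) / 2 - d1 / (2 * a)
  round(vertex, 1)
}

#' Compose a mixture spectrum from pure isomer spectra
#'
#' `f_AT * S_AT + (1 - f_AT) * S_13C`, the inverse of
#' [unmixPureSpectra()].
#'
#' @param sAT,s13C pure-species [Spectrum-class] objects on one grid.
#' @param fAT all-trans fraction in \[0, 1\].
#' @param label label of the returned spectrum.
#' @return a [Spectrum-class].
#' @export
composeMixture <- function(sAT, s13C, fAT, label = "") {
  stopifnot(is(sAT, "Spectrum"), is(s13C, "Spectrum"))
  if (!.sameGrid(sAT, s13C))
    stop("spectra must share one wavelength grid")
  f <- .asFraction(fAT)
  if (f < 0 || f > 1) stop("fAT must lie in [0, 1]")
  absorptionSpectrum(sAT@wavelength,
                     f * sAT@absorbance + (1 - f) * s13C@absorbance,
                     label)
}
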