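## Quantification of light-driven transport from pH traces of cell
## suspensions: initial slopes, hydroxylamine-bleach expression
## normalization and transport-mode classification over a salt x CCCP
## condition panel.

#' Initial slope of the light-induced pH change
#'
#' Ordinary least-squares slope of pH versus time over a window starting at
#' light-on.  Positive values mean the medium alkalinizes, the signature of
#' inward proton transport (or of Cl- influx charge compensation).
#'
#' @param trace a [PHTrace-class] with an illumination window.
#' @param windowS slope-window length in seconds from light-on (default
#'   30 s); must fit inside the illumination period.
#' @return slope in pH units per second.
#' @export
initialSlope <- function(trace, windowS = 30) {
  stopifnot(is(trace, "PHTrace"))
  if (is.na(trace@lightOn))
    stop("trace has no illumination window; cannot take an initial slope")
  if (trace@lightOn + windowS > trace@lightOff)
    stop("slope window extends beyond the illumination period")
  sel <- trace@time >= trace@lightOn & trace@time <= trace@lightOn + windowS
  if (sum(sel) < 5L)
    stop("need at least 5 samples inside the slope window")
  x <- trace@time[sel]
  y <- trace@pH[sel]
  unname(stats::cov(x, y) / stats::var(x))
}

#' Pigment extinction coefficient and amount from hydroxylamine bleaching
#'
#' Hydroxylamine cleaves the retinal Schiff base, converting the pigment
#' into retinal oxime with a known molar extinction (33,600 M^-1 cm^-1 at
#' 360 nm).  The pigment extinction coefficient follows from the ratio of
#' the pigment band to the oxime band, and the expressed amount from either
#' band; the two routes are algebraically identical and both are computed
#' and checked.
#'
#' @param pigment [Spectrum-class] of the intact pigment.
#' @param bleached [Spectrum-class] of the oxime band produced by the
#'   bleach.
#' @param oximeWavelength oxime band position (nm), default 360.
#' @param epsilonOxime molar extinction of retinal oxime (M^-1 cm^-1),
#'   default 33,600.
#' @param path optical path length (cm).
#' @param volume assayed suspension volume (L).
#' @return an [ExpressionResult-class].
#' @examples
#' wl <- 300:700
#' pig <- absorptionSpectrum(wl, gaussianBand(wl, 568, height = 0.5))
#' ox <- absorptionSpectrum(wl, gaussianBand(wl, 360, height = 0.336))
#' extinctionFromBleach(pig, ox)  # epsilon = 50,000
#' @export
extinctionFromBleach <- function(pigment, bleached, oximeWavelength = 360,
                                 epsilonOxime = 33600, path = 1,
                                 volume = 1) {
  stopifnot(is(pigment, "Spectrum"), is(bleached, "Spectrum"))
  if (!.sameGrid(pigment, bleached))
    stop("pigment and bleached spectra must share one grid")
  lmax <- findLambdaMax(pigment)
  aPig <- stats::approx(pigment@wavelength, pigment@absorbance,
                        xout = lmax)$y
  aOx <- stats::approx(bleached@wavelength, bleached@absorbance,
                       xout = oximeWavelength)$y
  if (is.na(aOx) || aOx <= 0)
    stop("no positive oxime band at the reference wavelength")
  eps <- epsilonOxime * aPig / aOx
  amountOx <- aOx / (epsilonOxime * path) * volume
  amountPig <- aPig / (eps * path) * volume
  stopifnot(isTRUE(all.equal(amountOx, amountPig, tolerance = 1e-12)))
  new("ExpressionResult", epsilon = eps, amount = amountOx)
}

#' Expression-normalized pumping activity
#'
#' Initial slope divided by the expressed amount of pigment, so that
#' activities of samples with different expression levels are comparable.
#' A replicate s.d. on the slope, when given, propagates linearly.
#'
#' @param slope initial slope (pH s^-1).
#' @param expression an [ExpressionResult-class].
#' @param slopeSd optional s.d. of the slope.
#' @return activity in pH s^-1 mol^-1; when `slopeSd` is given the s.d. is
#'   attached as attribute `"sd"`.
#' @export
normalizedActivity <- function(slope, expression, slopeSd = NULL) {
  stopifnot(is(expression, "ExpressionResult"))
  act <- slope / expression@amount
  if (!is.null(slopeSd)) attr(act, "sd") <- slopeSd / expression@amount
  act
}

#' Classify the transport mode from a salt x CCCP condition panel
#'
#' Applies the standard condition logic for suspension assays:
#' * inward H+ pump — light alkalinizes the medium in every salt (the
#'   signal is salt-independent) and the protonophore CCCP, which
#'   short-circuits transmembrane H+ gradients, abolishes it (|slope| drops
#'   below `abolitionFraction` of the CCCP-free slope in every salt);
#' * inward Cl- pump — alkalinization occurs in Cl--containing salts but is
#'   abolished when sulfate replaces chloride, and CCCP accelerates the
#'   signal (slope grows beyond `accelerationFactor` of the CCCP-free
#'   value), because H+ influx compensates the pumped negative charge;
#' * anything else is `"none/indeterminate"`.
#'
#' @param panel list of [PHTrace-class] objects covering >= 2 salts, each
#'   salt with and without CCCP.
#' @param abolitionFraction slopes with CCCP below this fraction of the
#'   CCCP-free slope count as abolished (default 0.2).
#' @param accelerationFactor slopes with CCCP above this multiple of the
#'   CCCP-free slope count as accelerated (default 1.5).
#' @param minSlope smallest slope (pH s^-1) regarded as a real signal.
#' @param windowS slope window passed to [initialSlope()].
#' @return a [TransportCall-class].
#' @export
classifyTransport <- function(panel, abolitionFraction = 0.2,
                              accelerationFactor = 1.5, minSlope = 1e-4,
                              windowS = 30) {
  stopifnot(length(panel) >= 2L,
            all(vapply(panel, is, logical(1), "PHTrace")))
  tab <- do.call(rbind, lapply(panel, function(tr)
    data.frame(salt = tr@salt, cccp = tr@cccp,
               slope = initialSlope(tr, windowS))))
  salts <- unique(tab$salt)
  if (length(salts) < 2L)
    stop("panel must cover at least 2 salts")
  for (s in salts) {
    have <- tab$cccp[tab$salt == s]
    if (!any(have) || !all(c(TRUE, FALSE) %in% have))
      stop(sprintf("salt %s is missing its CCCP counterpart", s))
  }
  ## mean slope per condition (replicates averaged)
  agg <- stats::aggregate(slope ~ salt + cccp, data = tab, FUN = mean)
  s0 <- stats::setNames(agg$slope[!agg$cccp], agg$salt[!agg$cccp])[salts]
  s1 <- stats::setNames(agg$slope[agg$cccp], agg$salt[agg$cccp])[salts]

  clSalts <- salts[grepl("Cl", salts)]
  so4 <- salts[grepl("SO4", salts, ignore.case = TRUE)]

  mode <- "none/indeterminate"
  if (all(s0 > minSlope) &&
      all(abs(s1) < abolitionFraction * abs(s0))) {
    mode <- "inward H+ pump"
  } else if (length(clSalts) >= 1L && length(so4) >= 1L &&
             all(s0[clSalts] > minSlope) &&
             all(abs(s0[so4]) < pmax(minSlope,
                                     abolitionFraction * min(s0[clSalts]))) &&
             all(s1[clSalts] > accelerationFactor * s0[clSalts])) {
    mode <- "inward Cl- pump"
  }
  new("TransportCall", mode = mode, slopes = tab, activity = NA_real_)
}
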