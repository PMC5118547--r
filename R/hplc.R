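## HPLC chromatogram analysis: peak detection with a prominence criterion,
## baseline-corrected trapezoidal integration over assignment windows, and
## isomer molar-fraction statistics over replicates.

## Local maxima of a numeric vector (strict rise, non-strict fall so flat
## tops count once).
.localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

## Topographic prominence of each candidate peak: walk outwards until a
## higher sample is met (or the boundary); the prominence is the peak height
## above the higher of the two intervening minima.
.prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    hl <- which(left > h)
    leftMin <- if (length(hl)) min(left[(max(hl) + 1L):(i - 1L)])
               else min(left)
    right <- x[(i + 1L):length(x)]
    hr <- which(right > h)
    rightMin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)])
                else min(right)
    h - max(leftMin, rightMin)
  }, numeric(1))
}

.trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Detect and integrate chromatogram peaks
#'
#' Detects local maxima whose topographic prominence exceeds
#' `minProminence` (default 3x the noise level, estimated as the median
#' absolute deviation of the first-differenced signal scaled by sqrt(2)).
#' Each assignment window is then integrated by the trapezoidal rule after
#' subtracting a linear baseline anchored at the window edges; the area is
#' attached to the tallest detected peak in the window.  Several detected
#' peaks inside one window are merged into a single flagged entry.  Peaks
#' outside every window are integrated between their flanking local minima
#' and labelled "unassigned".
#'
#' @param chrom a [Chromatogram-class].
#' @param minProminence detection threshold in signal units; NULL (default)
#'   uses 3x the estimated noise s.d.
#' @param baselineMode `"linear"` (default; straight line between window
#'   edges) or `"none"`.
#' @return a [PeakTable-class].  An empty table, with a warning, when no
#'   peak exceeds the threshold.
#' @export
detectAndIntegrate <- function(chrom, minProminence = NULL,
                               baselineMode = c("linear", "none")) {
  stopifnot(is(chrom, "Chromatogram"))
  baselineMode <- match.arg(baselineMode)
  tt <- chrom@time
  s <- chrom@signal
  if (length(s) < 10L) stop("signal too short (need >= 10 samples)")

  if (is.null(minProminence)) {
    noise <- stats::mad(diff(s)) / sqrt(2)
    minProminence <- 3 * noise
  }
  cand <- .localMaxima(s)
  keep <- if (length(cand)) .prominence(s, cand) > minProminence else logical(0)
  pk <- cand[keep]
  if (!length(pk)) {
    warning("no peaks found above the prominence threshold", call. = FALSE)
    return(new("PeakTable",
               peaks = data.frame(apex = numeric(), area = numeric(),
                                  isomer = character(), merged = logical())))
  }

  win <- chrom@windows
  rows <- list()
  assigned <- logical(length(pk))
  for (k in seq_len(nrow(win))) {
    sel <- which(tt[pk] >= win$start[k] & tt[pk] <= win$end[k])
    if (!length(sel)) next
    assigned[sel] <- TRUE
    idx <- which(tt >= win$start[k] & tt <= win$end[k])
    base <- if (baselineMode == "linear") {
      stats::approx(tt[idx][c(1L, length(idx))],
                    s[idx][c(1L, length(idx))], xout = tt[idx])$y
    } else 0
    area <- max(0, .trapz(tt[idx], s[idx] - base))
    apex <- tt[pk[sel]][which.max(s[pk[sel]])]
    merged <- length(sel) > 1L
    if (merged)
      message(sprintf("window %s [%g, %g]: %d peaks merged",
                      win$isomer[k], win$start[k], win$end[k], length(sel)))
    rows[[length(rows) + 1L]] <-
      data.frame(apex = apex, area = area, isomer = win$isomer[k],
                 merged = merged)
  }
  ## unassigned peaks: integrate between flanking local minima
  for (j in which(!assigned)) {
    i <- pk[j]
    lo <- i; while (lo > 1L && s[lo - 1L] <= s[lo]) lo <- lo - 1L
    hi <- i; while (hi < length(s) && s[hi + 1L] <= s[hi]) hi <- hi + 1L
    idx <- lo:hi
    base <- if (baselineMode == "linear") {
      stats::approx(tt[c(lo, hi)], s[c(lo, hi)], xout = tt[idx])$y
    } else 0
    rows[[length(rows) + 1L]] <-
      data.frame(apex = tt[i], area = max(0, .trapz(tt[idx], s[idx] - base)),
                 isomer = "unassigned", merged = FALSE)
  }
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$apex), , drop = FALSE]
  rownames(peaks) <- NULL
  new("PeakTable", peaks = peaks)
}

#' Retinal isomer molar fractions from integrated peak areas
#'
#' The molar fraction of each isomer is its summed assigned peak area over
#' the total assigned area.  The syn and anti oxime peaks of one isomer
#' occupy different retention windows and are summed before ratioing.
#' Equal molar detector response across oxime isomers is assumed, i.e.
#' areas are ratioed directly.
#'
#' @param peaks a [PeakTable-class] with at least one assigned peak.
#' @param condition condition label stored on the result.
#' @return an [IsomerFractions-class] (fraction all-trans; s.d. NA).
#' @export
molarFractions <- function(peaks, condition = NA_character_) {
  stopifnot(is(peaks, "PeakTable"))
  p <- peaks@peaks
  asg <- p[p$isomer %in% c("all-trans", "13-cis"), , drop = FALSE]
  if (!nrow(asg)) stop("no assigned peaks; cannot compute molar fractions")
  total <- sum(asg$area)
  if (total <= 0) stop("total assigned area must be > 0")
  fAT <- sum(asg$area[asg$isomer == "all-trans"]) / total
  isomerFractions(fAT, condition = condition)
}

#' Replicate statistics of isomer fractions
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' all-trans fraction over replicate measurements of one condition.
#'
#' @param fractions list of [IsomerFractions-class] objects (n >= 2) sharing
#'   a condition label.
#' @return an [IsomerFractions-class] holding mean and s.d.
#' @export
replicateStats <- function(fractions) {
  if (length(fractions) < 2L)
    stop("need at least 2 replicates")
  stopifnot(all(vapply(fractions, is, logical(1), "IsomerFractions")))
  cond <- vapply(fractions, function(f) f@condition, character(1))
  if (length(unique(cond)) != 1L)
    stop("replicates mix condition labels: ",
         paste(unique(cond), collapse = ", "))
  f <- vapply(fractions, fractionAllTrans, numeric(1))
  isomerFractions(mean(f), sd = stats::sd(f), condition = cond[1L])
}
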