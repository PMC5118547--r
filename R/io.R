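## Plain-text serialization: long-format delimited surfaces, two-column
## spectra, pH traces with a YAML metadata sidecar, schemes as YAML and fit
## reports as JSON.

#' Write / read a transient surface as long-format delimited text
#'
#' Columns `time_s`, `wavelength_nm`, `delta_A`, tab-separated with a
#' header.
#'
#' @param surface a [TransientSurface-class].
#' @param path file path.
#' @return `writeTransientSurface` returns `path` invisibly;
#'   `readTransientSurface` returns a [TransientSurface-class].
#' @export
writeTransientSurface <- function(surface, path) {
  stopifnot(is(surface, "TransientSurface"))
  long <- data.frame(
    time_s = rep(surface@time, times = length(surface@wavelength)),
    wavelength_nm = rep(surface@wavelength, each = length(surface@time)),
    delta_A = as.vector(surface@deltaA))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeTransientSurface
#' @export
readTransientSurface <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("time_s", "wavelength_nm", "delta_A") %in% names(long)))
  tt <- sort(unique(long$time_s))
  wl <- sort(unique(long$wavelength_nm))
  dA <- matrix(NA_real_, length(tt), length(wl))
  dA[cbind(match(long$time_s, tt), match(long$wavelength_nm, wl))] <-
    long$delta_A
  transientSurface(tt, wl, dA)
}

#' Write / read a spectrum as two-column delimited text
#'
#' Columns `wavelength_nm`, `absorbance`.
#'
#' @param spectrum a [Spectrum-class].
#' @param path file path.
#' @param label label for the read spectrum.
#' @return `writeSpectrum` returns `path` invisibly; `readSpectrum` returns
#'   a [Spectrum-class].
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  utils::write.table(
    data.frame(wavelength_nm = spectrum@wavelength,
               absorbance = spectrum@absorbance),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path, label = "") {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  absorptionSpectrum(d$wavelength_nm, d$absorbance, label)
}

#' Write / read a pH trace with a YAML metadata sidecar
#'
#' The data file holds columns `time_s`, `pH`; the sidecar `<path>.yml`
#' holds salt, CCCP flag, illumination window and sample label.
#'
#' @param trace a [PHTrace-class].
#' @param path data file path (the sidecar gets `.yml` appended).
#' @return `writePHTrace` returns `path` invisibly; `readPHTrace` returns a
#'   [PHTrace-class].
#' @export
writePHTrace <- function(trace, path) {
  stopifnot(is(trace, "PHTrace"))
  utils::write.table(data.frame(time_s = trace@time, pH = trace@pH),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(salt = trace@salt, cccp = trace@cccp,
               light_on = if (is.na(trace@lightOn)) NULL else trace@lightOn,
               light_off = if (is.na(trace@lightOff)) NULL else trace@lightOff,
               sample = trace@sample)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname writePHTrace
#' @export
readPHTrace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  phTrace(d$time_s, d$pH,
          lightOn = if (is.null(meta$light_on)) NA_real_ else meta$light_on,
          lightOff = if (is.null(meta$light_off)) NA_real_ else meta$light_off,
          salt = meta$salt %||% "NaCl", cccp = isTRUE(meta$cccp),
          sample = meta$sample %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a photocycle scheme as YAML
#'
#' @param scheme a [PhotocycleScheme-class].
#' @param path file path.
#' @return `writeScheme` returns `path` invisibly; `readScheme` returns a
#'   [PhotocycleScheme-class].
#' @export
writeScheme <- function(scheme, path) {
  stopifnot(is(scheme, "PhotocycleScheme"))
  yaml::write_yaml(list(
    states = as.list(scheme@states),
    initial_state = scheme@initialState,
    ground_state = scheme@groundState,
    excited_fraction = scheme@excitedFraction,
    edges = lapply(seq_len(nrow(scheme@edges)), function(i)
      list(from = scheme@edges$from[i], to = scheme@edges$to[i],
           rate = scheme@edges$rate[i]))), path, precision = 15L)
  invisible(path)
}

#' @rdname writeScheme
#' @export
readScheme <- function(path) {
  y <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(y$edges, function(e)
    data.frame(from = e$from, to = e$to, rate = e$rate)))
  photocycleScheme(unlist(y$states), edges,
                   initialState = y$initial_state,
                   groundState = y$ground_state,
                   excitedFraction = y$excited_fraction)
}

#' Serialize a global fit result as a JSON report
#'
#' Records time constants, RSS, convergence metadata, the wavelength grid,
#' the decay-associated spectra and the offset spectrum.
#'
#' @param fit a [GlobalFitResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitReport <- function(fit, path) {
  stopifnot(is(fit, "GlobalFitResult"))
  rep <- list(
    tau_s = fit@tau,
    rss = fit@rss,
    wavelength_nm = fit@wavelength,
    das = unname(fit@das),
    offset = if (length(fit@offset)) fit@offset else NULL,
    meta = fit@meta[c("restarts", "seed", "iterations", "warnings")])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
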