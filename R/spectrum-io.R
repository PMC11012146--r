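#' Read a resonance spectrum from JSON
#'
#' The spectrum interchange format is
#' \code{{"label": str, "resonances": [{"amp": x, "phase": x, "freq": x,
#' "decay": x}, ...]}}. A zero decay anywhere is rejected.
#'
#' @param path Path to a JSON file.
#' @return A \code{\link{resonance_spectrum}}.
#' @export
read_spectrum_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(obj$resonances) || NROW(obj$resonances) < 1L)
    stop("spectrum JSON must contain at least one resonance: ", path)
  r <- as.data.frame(obj$resonances)
  need <- c("amp", "phase", "freq", "decay")
  if (!all(need %in% names(r)))
    stop("spectrum JSON resonances need fields amp, phase, freq, decay: ", path)
  if (any(r$decay == 0))
    stop("spectrum JSON contains a resonance with decay == 0: ", path)
  spectrum_from_params(r$amp, r$phase, r$freq, r$decay,
                       label = if (is.null(obj$label)) "" else obj$label)
}

#' Write a resonance spectrum to JSON
#'
#' @param f A \code{\link{resonance_spectrum}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_json <- function(f, path) {
  stopifnot(inherits(f, "resonance_spectrum"))
  p <- spectrum_params(f)
  obj <- list(
    label = f$label,
    resonances = data.frame(amp = p$amp_mag, phase = p$phase,
                            freq = p$freq, decay = p$decay)
  )
  # 17 significant digits: lossless decimal round trip for doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
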