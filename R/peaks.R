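#' ROI-averaged TRF waveform
#'
#' Mean across a set of region-of-interest channels of one feature's
#' kernel; the lag axis is preserved.
#'
#' @param model a `trf_model`.
#' @param feature feature name (e.g. `"envelope"`, `"word_surprisal"`).
#' @param channels character vector of ROI channel labels.
#' @return list with `lags_ms` and `amplitude`.
#' @export
roi_waveform <- function(model, feature, channels) {
  if (!length(channels)) stop("empty ROI", call. = FALSE)
  miss <- setdiff(channels, model$labels)
  if (length(miss))
    stop("ROI channels not in model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  f <- match(feature, model$features)
  if (is.na(f)) stop("unknown feature: ", feature, call. = FALSE)
  W <- model$weights[f, , match(channels, model$labels), drop = FALSE]
  list(lags_ms = model$lags_ms,
       amplitude = apply(W, 2L, mean))
}

# earliest global extremum within a lag window; flat windows return the
# window start with amplitude of the flat level
window_extremum <- function(lags_ms, amp, window, minimum = TRUE) {
  sel <- which(lags_ms >= window[1L] & lags_ms <= window[2L])
  if (!length(sel)) stop("search window outside lag axis", call. = FALSE)
  v <- amp[sel]
  i <- if (minimum) which(v <= min(v) + 0)[1L] else which(v >= max(v))[1L]
  list(latency = lags_ms[sel[i]], amplitude = v[i], index = sel[i])
}

#' Extract sensory TRF components (N1, P2) from an envelope waveform
#'
#' TRF-N1 is the global minimum in the 50-150 ms lag window, TRF-P2 the
#' global maximum in 150-250 ms; the N1-P2 peak-to-peak amplitude is P2
#' minus N1. Ties break toward the earlier lag.
#'
#' @param waveform a [roi_waveform()] result (or list with `lags_ms`,
#'   `amplitude`).
#' @param n1_window,p2_window search windows in ms.
#' @return list with `N1` and `P2` (latency ms, amplitude) and `n1p2`.
#' @export
extract_sensory_peaks <- function(waveform, n1_window = c(50, 150),
                                  p2_window = c(150, 250)) {
  n1 <- window_extremum(waveform$lags_ms, waveform$amplitude, n1_window, TRUE)
  p2 <- window_extremum(waveform$lags_ms, waveform$amplitude, p2_window, FALSE)
  list(N1 = list(latency = n1$latency, amplitude = n1$amplitude,
                 window = n1_window),
       P2 = list(latency = p2$latency, amplitude = p2$amplitude,
                 window = p2_window),
       n1p2 = p2$amplitude - n1$amplitude)
}

#' Extract the TRF-N400 from a condition difference waveform
#'
#' The semantic incongruity response is isolated by subtracting the
#' control-condition surprisal TRF from the altered-story TRF, averaging
#' the difference over the parietal ROI, taking the global minimum in the
#' 200-1000 ms window as the peak latency, and reporting the amplitude as
#' the ROI-mean difference averaged over latency +- 10 ms.
#'
#' @param trf_e45 surprisal TRF of the altered (high-surprisal) condition.
#' @param trf_control surprisal TRF of the control condition.
#' @param roi parietal ROI channel labels.
#' @param feature feature carrying the semantic kernel.
#' @param window search window, ms.
#' @param mean_halfwidth half-width of the amplitude window, ms.
#' @return list with `latency` (ms), `amplitude`, and the ROI difference
#'   `waveform`.
#' @export
extract_n400 <- function(trf_e45, trf_control, roi,
                         feature = "word_surprisal",
                         window = c(200, 1000), mean_halfwidth = 10) {
  if (!isTRUE(all.equal(trf_e45$lags_ms, trf_control$lags_ms)))
    stop("models must share the lag axis", call. = FALSE)
  if (!setequal(trf_e45$labels, trf_control$labels))
    stop("models must share channels", call. = FALSE)
  if (max(trf_e45$lags_ms) < window[2L] || min(trf_e45$lags_ms) > window[1L])
    stop("lag axis does not cover the search window", call. = FALSE)
  we <- roi_waveform(trf_e45, feature, roi)
  wc <- roi_waveform(trf_control, feature, roi)
  diff_amp <- we$amplitude - wc$amplitude
  pk <- window_extremum(we$lags_ms, diff_amp, window, minimum = TRUE)
  sel <- we$lags_ms >= pk$latency - mean_halfwidth &
         we$lags_ms <= pk$latency + mean_halfwidth
  list(latency = pk$latency, amplitude = mean(diff_amp[sel]),
       window = window,
       waveform = list(lags_ms = we$lags_ms, amplitude = diff_amp))
}

#' Default ROI channel sets
#'
#' Six frontal-central channels for the sensory (envelope) components and
#' nine parietal channels for the semantic (surprisal) component, on the
#' bundled 10-20/10-10 layout. Both are configuration, not hard-coded into
#' any operation.
#'
#' @param which `"frontocentral"` or `"parietal"`.
#' @export
default_roi <- function(which = c("frontocentral", "parietal")) {
  which <- match.arg(which)
  switch(which,
         frontocentral = c("FC1", "FC2", "FCz", "Fz", "C3", "C4"),
         parietal = c("P3", "Pz", "P4", "CP1", "CP2", "CPz", "P7", "P8", "POz"))
}
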