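#' Audio track container
#'
#' @param samples numeric vector of amplitudes (mono).
#' @param rate sampling rate, Hz.
#' @export
audio_track <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(!is.finite(samples))) stop("audio samples must be finite", call. = FALSE)
  structure(list(samples = samples, rate = rate), class = "audio_track")
}

# analytic signal via frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Broadband speech envelope
#'
#' Magnitude of the analytic (Hilbert) signal of the audio, low-pass
#' filtered with an 8th-order Butterworth anti-alias filter at 0.4 times
#' the target rate and resampled to the EEG analysis rate. Captures the
#' slow amplitude fluctuations of speech that cortical activity tracks.
#'
#' @param audio an [audio_track()].
#' @param target_rate output sampling rate, Hz (must be at most half the
#'   audio rate).
#' @return numeric envelope at `target_rate`, non-negative.
#' @export
compute_envelope <- function(audio, target_rate) {
  stopifnot(inherits(audio, "audio_track"))
  if (target_rate > audio$rate / 2)
    stop("target_rate must be <= audio rate / 2", call. = FALSE)
  env <- Mod(analytic_signal(audio$samples))
  if (target_rate == audio$rate) return(env)
  bf <- signal::butter(8, (0.4 * target_rate) / (audio$rate / 2), type = "low")
  env <- signal::filtfilt(bf, env)
  idx <- resample_index(length(env), audio$rate, target_rate)
  pmax(env[idx], 0)
}

# nearest-sample decimation grid mapping n samples at `from` Hz to `to` Hz
resample_index <- function(n, from, to) {
  n_out <- floor(n / from * to)
  t_out <- (seq_len(n_out) - 1L) / to
  pmin(round(t_out * from) + 1L, n)
}

#' Align an audio soundtrack to an auxiliary recording channel
#'
#' Finds the sample offset at which the soundtrack starts within the
#' auxiliary channel by maximizing the cross-covariance between the two
#' (both demeaned). Ties are broken toward the smallest lag.
#'
#' @param aux auxiliary channel samples (recorded alongside the EEG).
#' @param soundtrack reference soundtrack samples, same rate, not longer
#'   than `aux`.
#' @return non-negative integer sample offset of the soundtrack within
#'   `aux`.
#' @export
align_offset <- function(aux, soundtrack) {
  aux <- as.numeric(aux); soundtrack <- as.numeric(soundtrack)
  if (length(soundtrack) > length(aux))
    stop("soundtrack longer than auxiliary channel", call. = FALSE)
  if (all(aux == 0) || all(soundtrack == 0))
    stop("alignment undefined for all-zero input", call. = FALSE)
  a <- aux - mean(aux)
  s <- soundtrack - mean(soundtrack)
  n_lag <- length(a) - length(s) + 1L
  # cross-covariance via FFT: conv(a, rev(s)) evaluated at the valid lags
  L <- stats::nextn(length(a) + length(s) - 1L, 2)
  cc <- Re(stats::fft(stats::fft(c(a, numeric(L - length(a)))) *
                      Conj(stats::fft(c(s, numeric(L - length(s))))),
                      inverse = TRUE)) / L
  cc <- cc[seq_len(n_lag)]
  which(cc >= max(cc) - 1e-9 * max(abs(cc)))[1L] - 1L
}

#' Step-function word regressor
#'
#' Builds the word-onset or word-surprisal regressor as a step function:
#' the channel takes its value at each word's onset sample and holds it
#' until the onset of the next word (1 in onset mode, the word's surprisal
#' in surprisal mode), and is 0 before the first word. Adjacent words form
#' a continuous step with no gap. Onsets are mapped to samples by
#' nearest-sample rounding (half away from zero).
#'
#' @param tokens a [token_table()] (surprisal annotated for surprisal mode).
#' @param rate sampling rate of the regressor, Hz.
#' @param duration total duration, seconds (must cover the last offset).
#' @param amplitude_mode `"onset"` or `"surprisal"`.
#' @return numeric vector of length `round(duration * rate)`.
#' @export
step_regressor <- function(tokens, rate, duration,
                           amplitude_mode = c("onset", "surprisal")) {
  amplitude_mode <- match.arg(amplitude_mode)
  validate_token_table(tokens)
  n <- round(duration * rate)
  out <- numeric(n)
  if (nrow(tokens) == 0L) return(out)
  if (max(tokens$offset) > duration + 1e-9)
    stop("token beyond regressor duration", call. = FALSE)
  if (amplitude_mode == "surprisal" && any(is.na(tokens$surprisal)))
    stop("surprisal mode requires annotated tokens", call. = FALSE)
  on_smp <- pmin(floor(tokens$onset * rate + 0.5) + 1L, n)
  off_smp <- pmin(floor(tokens$offset * rate + 0.5) + 1L, n + 1L)
  # each step spans the word duration; contiguous words (offset == next
  # onset) merge into one continuous step, silent pauses leave gaps
  end_smp <- pmax(off_smp, on_smp)
  amp <- if (amplitude_mode == "onset") rep(1, nrow(tokens)) else tokens$surprisal
  for (i in seq_len(nrow(tokens)))
    if (end_smp[i] > on_smp[i]) out[on_smp[i]:(end_smp[i] - 1L)] <- amp[i]
  out
}

#' Bundle regressor channels into a feature set
#'
#' @param envelope,word_onset,word_surprisal equal-length numeric channels.
#' @param rate common sampling rate, Hz.
#' @return object of class `regressor_set`: a named list of channels with
#'   `rate` and `duration` attributes.
#' @export
regressor_set <- function(envelope, word_onset, word_surprisal, rate) {
  chans <- list(envelope = as.numeric(envelope),
                word_onset = as.numeric(word_onset),
                word_surprisal = as.numeric(word_surprisal))
  len <- unique(vapply(chans, length, integer(1)))
  if (length(len) != 1L)
    stop("regressor channels must have equal length", call. = FALSE)
  if (any(!is.finite(unlist(chans, use.names = FALSE))))
    stop("regressor channels must be finite", call. = FALSE)
  structure(list(channels = chans, rate = rate, n = len,
                 duration = len / rate),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat(sprintf("<regressor_set> %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), x$n, x$rate, x$duration))
  invisible(x)
}

# regressor channels as samples x features matrix
regressor_matrix <- function(rs, features = names(rs$channels)) {
  mat <- do.call(cbind, rs$channels[features])
  colnames(mat) <- features
  mat
}

#' Write / read a regressor set as a TSV table
#'
#' Single-table plain-text persistence (time column plus one column per
#' channel) for auditability; the round trip is value-exact at the printed
#' precision.
#'
#' @param rs a [regressor_set()].
#' @param path file path.
#' @export
write_regressors <- function(rs, path) {
  df <- data.frame(time = (seq_len(rs$n) - 1L) / rs$rate)
  for (nm in names(rs$channels)) df[[nm]] <- rs$channels[[nm]]
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regressors
#' @export
read_regressors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rate <- 1 / stats::median(diff(df$time))
  regressor_set(df$envelope, df$word_onset, df$word_surprisal,
                rate = round(rate, 6))
}
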