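#' Multichannel EEG recording container
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate, Hz.
#' @param labels character vector of unique channel labels (rownames of
#'   `data` if missing).
#' @param positions optional channels x 3 matrix of head-centered 3-D
#'   electrode coordinates in meters (rownames = labels).
#' @param bad character vector of bad-channel labels (excluded from ROIs
#'   and adjacency downstream, kept in the data).
#' @export
eeg_recording <- function(data, rate, labels = rownames(data),
                          positions = NULL, bad = character(0)) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != nrow(data))
    stop("labels length must match channel count", call. = FALSE)
  if (any(!is.finite(data))) stop("non-finite EEG samples", call. = FALSE)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(ncol(positions) == 3L, nrow(positions) == nrow(data))
    rownames(positions) <- labels
  }
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 positions = positions, bad = as.character(bad),
                 log = character(0)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              if (length(x$bad)) paste0(", bad: ", paste(x$bad, collapse = ","))
              else ""))
  invisible(x)
}

log_stage <- function(rec, msg) {
  rec$log <- c(rec$log, msg)
  rec
}

#' Standard 10-20/10-10 montage positions
#'
#' Head-centered 3-D coordinates (meters, sphere radius 0.095 m) for a set
#' of standard electrode labels, computed from their spherical angles
#' (inclination from the vertex, signed toward the left hemisphere, and
#' azimuthal rotation). Used for synthetic layouts and adjacency graphs.
#'
#' @param labels labels to return (default: all bundled).
#' @param radius head radius in meters.
#' @return matrix labels x 3 (columns x = right, y = anterior, z = up).
#' @export
montage_1020 <- function(labels = NULL, radius = 0.095) {
  ang <- montage_angles()
  if (!is.null(labels)) {
    miss <- setdiff(labels, rownames(ang))
    if (length(miss))
      stop("no bundled position for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    ang <- ang[labels, , drop = FALSE]
  }
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  pos <- cbind(x = radius * sin(th) * cos(ph),
               y = radius * sin(th) * sin(ph),
               z = radius * cos(th))
  rownames(pos) <- rownames(ang)
  pos
}

montage_angles <- function() {
  # (inclination, azimuth) in degrees; negative inclination = left
  a <- rbind(
    Fp1 = c(-92,  72), Fpz = c( 92,  90), Fp2 = c( 92,  72),
    AF3 = c(-74,  65), AF4 = c( 74,  65),
    F7  = c(-92,  36), F3  = c(-60,  51), Fz  = c( 46,  90),
    F4  = c( 60,  51), F8  = c( 92,  36),
    FC5 = c(-72,  21), FC1 = c(-32,  45), FC2 = c( 32,  45), FC6 = c( 72,  21),
    FCz = c( 23,  90),
    T7  = c(-92,   0), C3  = c(-46,   0), Cz  = c(  0,   0),
    C4  = c( 46,   0), T8  = c( 92,   0),
    CP5 = c(-72, -21), CP1 = c(-32, -45), CP2 = c( 32, -45), CP6 = c( 72, -21),
    CPz = c( 23, -90),
    P7  = c(-92, -36), P3  = c(-60, -51), Pz  = c( 46, -90),
    P4  = c( 60, -51), P8  = c( 92, -36),
    PO3 = c(-74, -65), PO4 = c( 74, -65), POz = c( 69, -90),
    O1  = c(-92, -72), Oz  = c( 92, -90), O2  = c( 92, -72))
  colnames(a) <- c("inclination", "azimuth")
  a
}

#' Zero-phase Butterworth band-pass filter
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges, Hz (`0 < low < high < rate/2`).
#' @param order filter order (applied forward and backward when
#'   `zero_phase`, doubling the effective order).
#' @param zero_phase forward-backward filtering (no phase distortion).
#' @return the filtered recording (length preserved).
#' @export
bandpass_filter <- function(rec, low, high, order = 2, zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$rate / 2))
    stop("require 0 < low < high < rate/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (rec$rate / 2), type = "pass")
  filt <- if (zero_phase) function(x) signal::filtfilt(bf, x)
          else function(x) as.numeric(signal::filter(bf, x))
  rec$data <- t(apply(rec$data, 1L, filt))
  log_stage(rec, sprintf("bandpass %g-%g Hz order %d%s", low, high, order,
                         if (zero_phase) " zero-phase" else ""))
}

#' Resample a recording with anti-alias filtering
#'
#' Low-pass filters at 0.4 times the target rate (8th-order Butterworth,
#' zero-phase) and picks nearest samples on the target grid. Resampling to
#' the current rate is the identity.
#'
#' @param rec an [eeg_recording()].
#' @param target target rate, Hz (at most the current rate).
#' @export
resample_recording <- function(rec, target) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target > rec$rate) stop("target rate exceeds current rate", call. = FALSE)
  if (target == rec$rate) return(rec)
  bf <- signal::butter(8, (0.4 * target) / (rec$rate / 2), type = "low")
  idx <- resample_index(ncol(rec$data), rec$rate, target)
  rec$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)[idx]))
  old <- rec$rate
  rec$rate <- target
  log_stage(rec, sprintf("resampled %g -> %g Hz", old, target))
}

#' Joint z-scoring of EEG and regressors
#'
#' Standardizes every EEG channel and every regressor channel to mean 0 and
#' SD 1 over the full recording (not per epoch). Zero-variance channels are
#' flagged, logged, and added to the bad-channel list rather than divided
#' by zero.
#'
#' @param rec an [eeg_recording()].
#' @param rs a [regressor_set()] at the same rate/length (optional).
#' @return list with elements `recording` and `regressors`.
#' @export
standardize <- function(rec, rs = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  sds <- apply(rec$data, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    rec$bad <- union(rec$bad, rec$labels[flat])
    rec <- log_stage(rec, paste("zero-variance channels excluded:",
                                paste(rec$labels[flat], collapse = ",")))
    sds[flat] <- 1
  }
  rec$data <- (rec$data - rowMeans(rec$data)) / sds
  rec <- log_stage(rec, "z-scored EEG channels")
  if (!is.null(rs)) {
    for (nm in names(rs$channels)) {
      x <- rs$channels[[nm]]
      s <- stats::sd(x)
      if (s == 0) {
        warning("zero-variance regressor channel left unscaled: ", nm)
        next
      }
      rs$channels[[nm]] <- (x - mean(x)) / s
    }
    rec <- log_stage(rec, "z-scored regressor channels")
  }
  list(recording = rec, regressors = rs)
}

#' Joint standardization across runs of one participant
#'
#' Computes per-channel means and SDs over the concatenation of all runs
#' (conditions merged, as in a per-participant session) and applies the
#' same affine transform to every run, so that EEG and regressor units are
#' identical across conditions.
#'
#' @param runs list of runs, each a list with `recording`
#'   (an [eeg_recording()]) and `regressors` (a [regressor_set()]).
#' @return the same structure, standardized.
#' @export
standardize_runs <- function(runs) {
  eeg_all <- do.call(cbind, lapply(runs, function(r) r$recording$data))
  mu <- rowMeans(eeg_all)
  sds <- apply(eeg_all, 1L, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  sds[flat] <- 1
  ch_names <- names(runs[[1L]]$regressors$channels)
  reg_stats <- lapply(ch_names, function(nm) {
    x <- unlist(lapply(runs, function(r) r$regressors$channels[[nm]]),
                use.names = FALSE)
    list(mu = mean(x), sd = if (stats::sd(x) > 0) stats::sd(x) else 1)
  })
  names(reg_stats) <- ch_names
  lapply(runs, function(r) {
    r$recording$data <- (r$recording$data - mu) / sds
    if (any(flat))
      r$recording$bad <- union(r$recording$bad, r$recording$labels[flat])
    r$recording <- log_stage(r$recording,
                             "z-scored jointly across participant runs")
    for (nm in ch_names) {
      st <- reg_stats[[nm]]
      r$regressors$channels[[nm]] <-
        (r$regressors$channels[[nm]] - st$mu) / st$sd
    }
    r
  })
}

#' Epoch a recording (with regressors) into fixed-length trials
#'
#' Cuts consecutive non-overlapping trials of `trial_s` seconds; a trailing
#' remainder shorter than one trial is discarded (logged). EEG and
#' regressor segments stay aligned sample-for-sample.
#'
#' @param rec an [eeg_recording()].
#' @param rs a [regressor_set()] of the same rate and length.
#' @param trial_s trial duration, seconds.
#' @param condition condition label applied to all trials of this run.
#' @return object of class `epoched_data`: list of trials, each with `eeg`
#'   (channels x samples), `reg` (samples x features), and `condition`.
#' @export
epoch_trials <- function(rec, rs, trial_s = 60, condition = "Control") {
  stopifnot(inherits(rec, "eeg_recording"), inherits(rs, "regressor_set"))
  if (rec$rate != rs$rate) stop("rate mismatch", call. = FALSE)
  n <- ncol(rec$data)
  if (n != rs$n) stop("EEG/regressor length mismatch", call. = FALSE)
  len <- round(trial_s * rec$rate)
  n_trials <- n %/% len
  if (n_trials == 0L) stop("recording shorter than one trial", call. = FALSE)
  dropped <- n - n_trials * len
  reg <- regressor_matrix(rs)
  trials <- lapply(seq_len(n_trials), function(i) {
    sel <- ((i - 1L) * len + 1L):(i * len)
    list(eeg = rec$data[, sel, drop = FALSE],
         reg = reg[sel, , drop = FALSE],
         condition = condition)
  })
  structure(list(trials = trials, rate = rec$rate,
                 labels = rec$labels, positions = rec$positions,
                 bad = rec$bad, trial_s = trial_s,
                 log = c(rec$log, sprintf(
                   "epoched into %d x %g-s trials (%d samples dropped)",
                   n_trials, trial_s, dropped))),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf("<epoched_data> %d trials x %g s, %d channels @ %g Hz\n",
              length(x$trials), x$trial_s, length(x$labels), x$rate))
  invisible(x)
}

# concatenate epoched_data objects (same layout/rate)
bind_epochs <- function(...) {
  eps <- list(...)
  if (length(eps) == 1L && is.list(eps[[1]]) && !inherits(eps[[1]], "epoched_data"))
    eps <- eps[[1]]
  base <- eps[[1]]
  base$trials <- do.call(c, lapply(eps, `[[`, "trials"))
  base$log <- do.call(c, lapply(eps, `[[`, "log"))
  base
}
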