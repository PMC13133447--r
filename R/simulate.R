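# Synthetic stories, regressors, and multichannel EEG with known
# ground-truth kernels, so that every stage of the pipeline (surprisal,
# features, preprocessing, TRF, clusters, peaks, group statistics) can be
# validated against a known answer without any external recordings.

#' Ground-truth TRF kernels for simulation
#'
#' Kernel shapes are sums of Gaussians in lag space: an N1/P2-shaped
#' biphasic envelope kernel (negative then positive lobe), a small early
#' onset kernel, and an N400-shaped negative surprisal kernel whose
#' amplitude scales with surprisal (gain per bit). A group latency shift
#' delays every component, emulating slower cortical responses under
#' degraded (cochlear-implant-like) hearing.
#'
#' @param n1_latency,p2_latency envelope component latencies, ms.
#' @param n1_amp,p2_amp envelope component amplitudes (arbitrary units).
#' @param sensory_width Gaussian SD of the envelope/onset components, ms.
#' @param onset_latency,onset_amp onset kernel parameters.
#' @param n400_latency,n400_width center and SD of the surprisal kernel,
#'   ms (427 ms emulates typical normal-hearing semantic responses; pass
#'   a later center for implant-like groups).
#' @param n400_gain kernel amplitude per bit of surprisal (negative).
#' @param incongruity_gain multiplicative boost of the surprisal response
#'   for altered (semantically incongruent, high-surprisal) words: those
#'   words drive `(1 + incongruity_gain)` times the linear-surprisal
#'   response. This super-linearity is what makes the altered-story
#'   surprisal TRF differ from control and is the source of the
#'   condition-difference N400.
#' @param sensory_shift,n400_shift additive group latency shifts, ms.
#' @return object of class `ground_truth_kernels`.
#' @export
ground_truth_kernels <- function(n1_latency = 100, n1_amp = -1,
                                 p2_latency = 200, p2_amp = 1.2,
                                 sensory_width = 25,
                                 onset_latency = 120, onset_amp = 0.4,
                                 n400_latency = 427.2, n400_width = 60,
                                 n400_gain = -0.08, incongruity_gain = 2,
                                 sensory_shift = 0, n400_shift = 0) {
  structure(list(
    envelope = list(n1_latency = n1_latency + sensory_shift, n1_amp = n1_amp,
                    p2_latency = p2_latency + sensory_shift, p2_amp = p2_amp,
                    width = sensory_width),
    onset = list(latency = onset_latency + sensory_shift, amp = onset_amp,
                 width = sensory_width),
    surprisal = list(latency = n400_latency + n400_shift,
                     width = n400_width, gain = n400_gain,
                     incongruity_gain = incongruity_gain)),
    class = "ground_truth_kernels")
}

#' Group-typical kernel presets
#'
#' `"NH"` uses the defaults of [ground_truth_kernels()]; `"CI"` delays the
#' sensory components by 40 ms and the N400 center to 554.3 ms, with a
#' smaller N1 / larger P2 asymmetry reversed.
#'
#' @param group `"NH"` or `"CI"`.
#' @export
group_kernels <- function(group = c("NH", "CI")) {
  group <- match.arg(group)
  if (group == "NH") ground_truth_kernels()
  else ground_truth_kernels(n1_amp = -1.3, p2_amp = 0.8,
                            sensory_shift = 40,
                            n400_latency = 554.3)
}

gaussian_bump <- function(t_ms, center, sd, amp) {
  amp * exp(-0.5 * ((t_ms - center) / sd)^2)
}

#' Evaluate a ground-truth kernel on a lag axis
#'
#' @param kernels a [ground_truth_kernels()].
#' @param feature `"envelope"`, `"onset"`/`"word_onset"`, or
#'   `"surprisal"`/`"word_surprisal"`.
#' @param lags_ms lag axis in ms.
#' @return numeric kernel waveform.
#' @export
kernel_waveform <- function(kernels, feature, lags_ms) {
  feature <- sub("^word_", "", feature)
  k <- kernels[[feature]]
  if (is.null(k)) stop("unknown feature: ", feature, call. = FALSE)
  if (feature == "envelope")
    gaussian_bump(lags_ms, k$n1_latency, k$width, k$n1_amp) +
      gaussian_bump(lags_ms, k$p2_latency, k$width, k$p2_amp)
  else if (feature == "onset")
    gaussian_bump(lags_ms, k$latency, k$width, k$amp)
  else
    gaussian_bump(lags_ms, k$latency, k$width, k$gain)
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 15-min
#' stories at 170 words/min, one altered high-surprisal word (> 20 bits)
#' roughly every 45 s, EEG at 250 Hz, 1/f plus white channel noise at
#' 0 dB SNR (RMS signal / RMS noise over the recording).
#'
#' @param n_per_group subjects per group.
#' @param channels channel labels from the bundled montage.
#' @param rate sampling rate, Hz.
#' @param duration_s run duration, seconds.
#' @param word_rate words per minute.
#' @param altered_interval_s spacing of altered words, seconds.
#' @param surprisal_floor minimum surprisal of altered words, bits.
#' @param noise_exponent 1/f power-spectral exponent of the colored noise.
#' @param white_sd white noise SD relative to the colored noise RMS.
#' @param snr_db signal-to-noise ratio, dB (RMS ratio over the recording).
#' @param latency_jitter_sd per-subject kernel latency jitter, ms.
#' @param gain_jitter_sd per-subject multiplicative gain jitter (SD of a
#'   lognormal).
#' @param behavior_link strength of the monotone (logistic) link from a
#'   subject's surprisal-kernel gain to semantic-judgment accuracy.
#' @param seed mandatory RNG seed; all randomness derives from it.
#' @export
sim_config <- function(n_per_group = 20,
                       channels = default_sim_channels(),
                       rate = 250, duration_s = 900, word_rate = 170,
                       altered_interval_s = 45, surprisal_floor = 20,
                       noise_exponent = 1, white_sd = 0.5, snr_db = 0,
                       latency_jitter_sd = 10, gain_jitter_sd = 0.25,
                       behavior_link = 3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(n_per_group = n_per_group, channels = channels, rate = rate,
              duration_s = duration_s, word_rate = word_rate,
              altered_interval_s = altered_interval_s,
              surprisal_floor = surprisal_floor,
              noise_exponent = noise_exponent, white_sd = white_sd,
              snr_db = snr_db, latency_jitter_sd = latency_jitter_sd,
              gain_jitter_sd = gain_jitter_sd,
              behavior_link = behavior_link, seed = as.integer(seed))
  stopifnot(all(vapply(cfg[c("rate", "duration_s", "word_rate",
                             "altered_interval_s")], function(v) v > 0,
                       logical(1))))
  structure(cfg, class = "sim_config")
}

default_sim_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CPz", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "O2")
}

#' Packaged toy training corpus
#'
#' Small plain-text corpus (one sentence per line) bundled for training
#' the n-gram model that drives story generation and surprisal annotation
#' in simulations and examples.
#'
#' @return character vector of sentences.
#' @export
toy_corpus <- function() {
  readLines(system.file("extdata", "toy_corpus.txt", package = "speechTRF"),
            encoding = "UTF-8")
}

# words guaranteed out of the toy vocabulary, used as high-surprisal
# replacements (mapped to the unknown symbol by the model)
rare_replacements <- function() {
  c("chinchilla", "submarine", "kaleidoscope", "accordion", "flamingo",
    "typhoon", "harmonica", "asteroid", "cactus", "trombone")
}

#' Generate a synthetic story with control and altered variants
#'
#' Samples a word sequence from the n-gram model at the configured word
#' rate with jittered word durations, annotates surprisal, and creates an
#' altered (high-surprisal) variant in which one word per
#' `altered_interval_s` window is replaced by an out-of-vocabulary word
#' whose surprisal in context exceeds the configured floor. The control
#' variant is identical except for the replacements.
#'
#' @param config a [sim_config()].
#' @param lm an [ngram_model][train_ngram] trained on the packaged corpus.
#' @param seed RNG seed (default derived from the config seed).
#' @return list with `control` and `e45` [token_table()]s.
#' @export
gen_story <- function(config, lm, seed = config$seed) {
  set.seed(seed)
  n_words <- round(config$duration_s / 60 * config$word_rate)
  gap <- 60 / config$word_rate
  if (n_words < 2L) stop("word rate incompatible with duration", call. = FALSE)

  # stitch the story from sampled corpus sentences, so that most words are
  # predictable in context (low surprisal) the way connected speech is
  sentences <- strsplit(tolower(toy_corpus()), "\\s+")
  words <- character(0)
  while (length(words) < n_words)
    words <- c(words, sentences[[sample.int(length(sentences), 1L)]])
  words <- words[seq_len(n_words)]

  iois <- gap * stats::rlnorm(n_words, meanlog = 0, sdlog = 0.2)
  iois <- iois * (config$duration_s * 0.98) / sum(iois)
  onsets <- cumsum(c(gap / 2, iois[-n_words]))
  durations <- pmin(iois * 0.9, 0.6)
  tok <- token_table(words, onsets, onsets + durations)

  control <- annotate_tokens(lm, tok)

  e45 <- tok
  repl_pool <- rare_replacements()
  idx <- integer(0)
  target <- config$altered_interval_s / 4
  repeat {
    cand <- which(tok$onset >= target)
    if (!length(cand)) break
    idx <- c(idx, cand[1L])
    target <- tok$onset[cand[1L]] + config$altered_interval_s
  }
  ctx_len <- lm$order - 1L
  for (j in seq_along(idx)) {
    i <- idx[j]
    ctx <- if (i > 1L) tolower(e45$word[max(1L, i - ctx_len):(i - 1L)])
           else character(0)
    cand <- repl_pool[(j - 1L + seq_along(repl_pool) - 1L) %%
                        length(repl_pool) + 1L]
    s_cand <- vapply(cand, function(w) surprisal_of(lm, ctx, w), numeric(1))
    ok <- which(s_cand > config$surprisal_floor)
    e45$word[i] <- cand[if (length(ok)) ok[1L] else which.max(s_cand)]
  }
  e45 <- annotate_tokens(lm, e45)
  e45$altered <- seq_len(nrow(e45)) %in% idx
  list(control = control, e45 = e45)
}

# FFT-shaped 1/f^exponent noise, unit variance
pink_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)              # two-sided frequency index
  shape <- f ^ (-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# positive speech-like envelope channel: rectified 1/f noise, so the
# modulation spectrum is dominated by slow fluctuations (as in speech)
# while retaining broadband content that keeps the lagged design
# well-conditioned
synth_envelope <- function(n, rate) {
  env <- abs(pink_noise(n, 1))
  pmax(env - stats::quantile(env, 0.05), 0)
}

#' Simulate a multichannel EEG recording from known kernels
#'
#' Forward model of the TRF framework: each regressor channel is convolved
#' with its ground-truth kernel, projected onto a smooth scalp topography
#' (frontal-central for envelope/onset, central-parietal for surprisal),
#' and summed; 1/f plus white noise is added at the configured SNR.
#'
#' @param tokens a surprisal-annotated [token_table()].
#' @param kernels a [ground_truth_kernels()].
#' @param config a [sim_config()].
#' @param seed RNG seed (default derived from the config seed).
#' @return list with `recording` (an [eeg_recording()]), `regressors`
#'   (a [regressor_set()]), and `truth` (kernels, topographies, config).
#' @export
simulate_recording <- function(tokens, kernels, config, seed = config$seed) {
  set.seed(seed)
  rate <- config$rate
  n <- round(config$duration_s * rate)
  env <- synth_envelope(n, rate)
  onset <- step_regressor(tokens, rate, config$duration_s, "onset")
  surp <- step_regressor(tokens, rate, config$duration_s, "surprisal")
  rs <- regressor_set(env, onset, surp, rate)

  pos <- montage_1020(config$channels)
  topo <- cbind(
    envelope = scalp_topography(pos, "FCz"),
    word_onset = scalp_topography(pos, "FCz"),
    word_surprisal = scalp_topography(pos, "CPz"))

  t_ms <- seq(-100, 1000, by = 1000 / rate)
  feats <- c("envelope", "word_onset", "word_surprisal")
  sig <- matrix(0, length(config$channels), n)
  off <- round(-100 / 1000 * rate)
  for (f in feats) {
    kern <- kernel_waveform(kernels, f, t_ms)
    comp <- conv_lagged(rs$channels[[f]], kern, lag_offset = off)
    sig <- sig + tcrossprod(topo[, f], comp)
  }
  # super-linear semantic response: altered (incongruent) words drive an
  # additional surprisal-kernel response on top of the linear component
  ig <- kernels$surprisal$incongruity_gain %||% 0
  if (ig != 0 && any(tokens$altered)) {
    alt <- tokens[tokens$altered, , drop = FALSE]
    class(alt) <- "data.frame"
    alt_step <- step_regressor(
      token_table(alt$word, alt$onset, alt$offset,
                  surprisal = alt$surprisal),
      rate, config$duration_s, "surprisal")
    kern <- kernel_waveform(kernels, "surprisal", t_ms)
    sig <- sig + ig * tcrossprod(topo[, "word_surprisal"],
                                 conv_lagged(alt_step, kern, lag_offset = off))
  }

  if (is.finite(config$snr_db)) {
    noise <- t(vapply(seq_len(nrow(sig)), function(i)
      pink_noise(n, config$noise_exponent) +
        config$white_sd * stats::rnorm(n), numeric(n)))
    rms_sig <- sqrt(mean(sig^2))
    rms_noise <- sqrt(mean(noise^2))
    target <- rms_sig / 10^(config$snr_db / 20)
    if (rms_sig == 0) stop("zero-signal simulation cannot attain SNR",
                           call. = FALSE)
    sig <- sig + noise * (target / rms_noise)
  }

  rec <- eeg_recording(sig, rate, labels = config$channels, positions = pos)
  list(recording = rec, regressors = rs,
       truth = list(kernels = kernels, topographies = topo,
                    lags_ms = t_ms, config = config, seed = seed))
}

# convolution of a regressor with a kernel whose support starts at
# lag_offset samples (negative = acausal part)
conv_lagged <- function(x, kern, lag_offset) {
  n <- length(x); L <- length(kern)
  full <- stats::convolve(c(x, numeric(L)), rev(kern), type = "open")
  start <- 1L - lag_offset           # y[t] = sum_j kern[j] x[t - offset - j + 1]
  full[start:(start + n - 1L)]
}

# smooth Gaussian scalp weighting centered on a montage electrode
scalp_topography <- function(pos, center_label, sigma = 0.055) {
  center <- montage_1020(center_label)
  d2 <- rowSums(sweep(pos, 2L, as.numeric(center))^2)
  w <- exp(-d2 / (2 * sigma^2))
  w / max(w)
}

#' Simulate a two-group cohort with behavioral scores
#'
#' Per subject: group kernels with lognormal gain jitter and Gaussian
#' latency jitter, a control and an altered story run, EEG simulated by
#' [simulate_recording()], standardized and epoched into 60-s trials, and
#' behavioral semantic-judgment scores generated through a logistic link
#' from the subject's (negated) surprisal-kernel gain plus binomial trial
#' noise, so that stronger semantic kernels yield better judgment scores.
#'
#' @param config a [sim_config()].
#' @param nh_kernels,ci_kernels group-level [ground_truth_kernels()].
#' @param lm optional [ngram_model][train_ngram] (default: trained on the
#'   packaged corpus).
#' @param trial_s epoch length, seconds.
#' @param analysis_band band-pass applied to the EEG before
#'   standardization (the 1-20 Hz analysis band; `NULL` to skip).
#' @return list of subjects, each with `epochs`, `group`, `kernels`
#'   (subject truth), and `behavior` (judgment_pct, recall_pct).
#' @export
simulate_cohort <- function(config, nh_kernels = group_kernels("NH"),
                            ci_kernels = group_kernels("CI"),
                            lm = NULL, trial_s = 60,
                            analysis_band = c(1, 20)) {
  if (config$n_per_group < 2L) stop("need >= 2 subjects per group",
                                    call. = FALSE)
  if (is.null(lm)) lm <- train_ngram(tokenize_text(toy_corpus()), order = 5)
  subjects <- vector("list", 2L * config$n_per_group)
  for (s in seq_along(subjects)) {
    grp <- if (s <= config$n_per_group) "NH" else "CI"
    base <- if (grp == "NH") nh_kernels else ci_kernels
    sub_seed <- config$seed + 1000L * s
    set.seed(sub_seed)
    gain_mult <- stats::rlnorm(1, 0, config$gain_jitter_sd)
    lat_jit <- stats::rnorm(1, 0, config$latency_jitter_sd)
    kern <- base
    kern$surprisal$gain <- kern$surprisal$gain * gain_mult
    kern$surprisal$latency <- kern$surprisal$latency + lat_jit
    story <- gen_story(config, lm, seed = sub_seed + 1L)
    sims <- lapply(c(control = "control", e45 = "e45"), function(v)
      simulate_recording(story[[v]], kern, config,
                         seed = sub_seed + if (v == "e45") 3L else 2L))
    if (!is.null(analysis_band))
      sims <- lapply(sims, function(s) {
        s$recording <- bandpass_filter(s$recording, analysis_band[1L],
                                       analysis_band[2L], order = 2)
        s
      })
    std <- standardize_runs(sims)
    runs <- lapply(names(std), function(v)
      epoch_trials(std[[v]]$recording, std[[v]]$regressors, trial_s,
                   condition = if (v == "e45") "E45" else "Control"))
    names(runs) <- names(std)
    # judgment accuracy linked to semantic kernel strength (gain is
    # negative: stronger response -> more negative -> higher accuracy)
    strength <- -kern$surprisal$gain / abs(base$surprisal$gain %||% 1)
    p_correct <- stats::plogis(config$behavior_link * (strength - 1) + 1)
    n_sent <- 45L
    judgment <- 100 * stats::rbinom(1, n_sent, p_correct) / n_sent
    recall <- 100 * stats::rbinom(1, 60L, stats::plogis(
      0.5 * config$behavior_link * (strength - 1))) / 60
    subjects[[s]] <- list(
      epochs = bind_epochs(runs$control, runs$e45),
      group = grp, kernels = kern,
      behavior = list(judgment_pct = judgment, recall_pct = recall),
      seed = sub_seed)
  }
  subjects
}
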