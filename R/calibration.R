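# Monte-Carlo calibration utilities: type-I error of the cluster test,
# power on planted effects, and the null behavior of the added-value
# (surprisal) model comparison. These drive the package's statistical
# validation; repeats redraw only the noise, reusing story, regressors,
# and the (EEG-independent) Gram matrices and their per-fold
# eigendecompositions across repeats.

grid_positions <- function(n_channels, spacing = 0.03, n_cols = 4) {
  n_rows <- ceiling(n_channels / n_cols)
  pos <- cbind(rep(seq_len(n_cols) - 1L, n_rows)[seq_len(n_channels)] * spacing,
               rep(seq_len(n_rows) - 1L, each = n_cols)[seq_len(n_channels)] * spacing,
               0)
  rownames(pos) <- sprintf("g%02d", seq_len(n_channels))
  pos
}

#' Family-wise error rate of the cluster test under an exchangeable null
#'
#' Simulates cohorts of i.i.d. standard normal channel x time waveforms,
#' runs the paired spatiotemporal cluster permutation test against zero,
#' and reports the fraction of simulations with any corrected p below
#' `alpha`.
#'
#' @param n_sims number of simulated null datasets.
#' @param n_subjects,n_channels,n_times data dimensions per dataset.
#' @param n_perm permutations per test.
#' @param cluster_alpha cluster-forming alpha.
#' @param alpha family-wise significance level tallied.
#' @param spacing grid inter-electrode distance, m (4-column grid layout;
#'   the default 0.03 with a 0.04 radius links lattice neighbors only).
#' @param seed RNG seed.
#' @return list with `fwer`, `min_p` per simulation.
#' @export
cluster_null_fwer <- function(n_sims = 500, n_subjects = 16,
                              n_channels = 12, n_times = 250,
                              n_perm = 200, cluster_alpha = 0.05,
                              alpha = 0.05, spacing = 0.03, seed = 1) {
  adj <- build_adjacency(grid_positions(n_channels, spacing), 0.04)
  zeros <- array(0, c(n_subjects, n_channels, n_times))
  set.seed(seed)
  sim_seeds <- sample.int(2^30, n_sims)
  min_p <- vapply(seq_len(n_sims), function(i) {
    set.seed(sim_seeds[i])
    A <- array(stats::rnorm(n_subjects * n_channels * n_times),
               c(n_subjects, n_channels, n_times))
    min_cluster_p(cluster_perm_test(A, zeros, "paired", adj,
                                    cluster_alpha = cluster_alpha,
                                    n_perm = n_perm,
                                    seed = sim_seeds[i] + 1L))
  }, numeric(1))
  list(fwer = mean(min_p < alpha), min_p = min_p)
}

#' Detection rate for a planted spatiotemporal effect
#'
#' Adds a constant offset (in units of the noise SD) to a block of
#' adjacent channels over a contiguous time span and reports how often the
#' cluster test detects a significant cluster overlapping the planted
#' block.
#'
#' @inheritParams cluster_null_fwer
#' @param n_repeats number of simulated datasets.
#' @param effect_sd planted offset in noise-SD units.
#' @param effect_channels channel indices carrying the effect (grid
#'   neighbors).
#' @param effect_times time-sample indices carrying the effect.
#' @return list with `power`, logical `detected` per repeat.
#' @export
cluster_planted_power <- function(n_repeats = 100, n_subjects = 16,
                                  n_channels = 12, n_times = 250,
                                  effect_sd = 1,
                                  effect_channels = 1:4,
                                  effect_times = 101:150,
                                  n_perm = 200, cluster_alpha = 0.05,
                                  alpha = 0.05, spacing = 0.03, seed = 1) {
  adj <- build_adjacency(grid_positions(n_channels, spacing), 0.04)
  zeros <- array(0, c(n_subjects, n_channels, n_times))
  set.seed(seed)
  sim_seeds <- sample.int(2^30, n_repeats)
  detected <- vapply(seq_len(n_repeats), function(i) {
    set.seed(sim_seeds[i])
    A <- array(stats::rnorm(n_subjects * n_channels * n_times),
               c(n_subjects, n_channels, n_times))
    A[, effect_channels, effect_times] <-
      A[, effect_channels, effect_times] + effect_sd
    res <- cluster_perm_test(A, zeros, "paired", adj,
                             cluster_alpha = cluster_alpha,
                             n_perm = n_perm, seed = sim_seeds[i] + 1L)
    any(vapply(res$clusters, function(cl)
      cl$p < alpha && any(cl$channels %in% effect_channels) &&
        any(cl$time_idx %in% effect_times), logical(1)))
  }, logical(1))
  list(power = mean(detected), detected = detected)
}

# fixed, EEG-independent design material for one subject: per-trial
# regressor Grams, per-fold eigendecompositions for both feature sets,
# and the clean (noise-free) signal
build_null_subject <- function(config, lm, kernels, lags, trial_s,
                               lambdas, sub_seed, band) {
  story <- gen_story(config, lm, seed = sub_seed)
  sim <- simulate_recording(story$e45, kernels, config, seed = sub_seed + 1L)
  sim$recording <- bandpass_filter(sim$recording, band[1L], band[2L], 2)
  std <- standardize(sim$recording, sim$regressors)
  ep <- epoch_trials(std$recording, std$regressors, trial_s, "E45")
  n_tr <- length(ep$trials)
  full <- c("envelope", "word_onset", "word_surprisal")
  L <- length(lags$lags)
  ss <- lapply(ep$trials, function(tr) trial_suffstats(tr$reg, tr$eeg, lags))
  acoustic_idx <- c(1L, 1L + seq_len(2L * L))
  models <- list(full = seq_len(3L * L + 1L), acoustic = acoustic_idx)
  Gtot <- Reduce(`+`, lapply(ss, `[[`, "G"))
  n_tot <- sum(vapply(ss, `[[`, numeric(1), "n"))
  eigs <- lapply(models, function(idx)
    lapply(seq_len(n_tr), function(i) {
      Gtr <- (Gtot - ss[[i]]$G)[idx, idx]
      center_gram_eigen(Gtr, n_tot - ss[[i]]$n)
    }))
  list(trials = ep$trials, ss_G = lapply(ss, `[[`, "G"),
       models = models, eigs = eigs,
       signal = vapply(ep$trials, function(tr) tr$eeg,
                       matrix(0, nrow(ep$trials[[1L]]$eeg),
                              ncol(ep$trials[[1L]]$eeg))),
       rms_sig = sqrt(mean(unlist(lapply(ep$trials,
                                         function(tr) tr$eeg^2)))))
}

# cross-validated accuracy difference (full - acoustic) for one subject
# given freshly drawn EEG trials, using the cached Grams/eigens
cached_delta_r <- function(sub, eeg_trials, lags, lambdas) {
  n_tr <- length(sub$trials)
  bs <- lapply(seq_len(n_tr), function(i)
    trial_bstats(sub$trials[[i]]$reg, eeg_trials[[i]], lags))
  Btot <- Reduce(`+`, lapply(bs, `[[`, "B"))
  n_tot <- sum(vapply(bs, `[[`, numeric(1), "n"))
  sy_tot <- Reduce(`+`, lapply(bs, `[[`, "sy"))
  syy_tot <- Reduce(`+`, lapply(bs, `[[`, "syy"))
  acc <- vapply(names(sub$models), function(mod) {
    idx <- sub$models[[mod]]
    fold_r <- matrix(NA_real_, n_tr, length(lambdas))
    for (i in seq_len(n_tr)) {
      train <- list(B = (Btot - bs[[i]]$B)[idx, , drop = FALSE],
                    n = n_tot - bs[[i]]$n)
      W <- solve_ridge_grid(train, lambdas, eig = sub$eigs[[mod]][[i]])
      test <- list(G = sub$ss_G[[i]][idx, idx],
                   B = bs[[i]]$B[idx, , drop = FALSE],
                   n = bs[[i]]$n, sy = bs[[i]]$sy, syy = bs[[i]]$syy)
      for (j in seq_along(lambdas))
        fold_r[i, j] <- mean(score_from_suffstats(test, W[, , j]))
    }
    max(colMeans(fold_r))
  }, numeric(1))
  acc[["full"]] - acc[["acoustic"]]
}

#' Single-subject kernel recovery study
#'
#' Simulates one subject (group-typical normal-hearing kernels, no
#' between-subject jitter) with a control and an altered story run at the
#' given SNR, runs the standard pipeline (1-20 Hz analysis filter, joint
#' standardization, 60-s epochs, cross-validated lambda, per-condition
#' TRFs), and quantifies recovery: the correlation between the estimated
#' and true envelope kernel (topography-weighted channel average) and the
#' error of the recovered TRF-N400 peak latency.
#'
#' @param seed RNG seed.
#' @param duration_s seconds per condition run (default 300, i.e. ten
#'   60-s trials across the two conditions).
#' @param snr_db simulation SNR.
#' @param rate sampling rate, Hz.
#' @param lambdas CV grid.
#' @return list with `envelope_r`, `n400_latency`, `n400_latency_true`,
#'   `latency_error_ms`, `lambda`, `accuracy`, `n_trials`.
#' @export
kernel_recovery_study <- function(seed = 11, duration_s = 300, snr_db = 0,
                                  rate = 250,
                                  lambdas = default_lambda_grid()) {
  lm <- train_ngram(tokenize_text(toy_corpus()), order = 5)
  kern <- group_kernels("NH")
  cfg <- sim_config(rate = rate, duration_s = duration_s, snr_db = snr_db,
                    seed = seed)
  story <- gen_story(cfg, lm)
  sims <- list(
    control = simulate_recording(story$control, kern, cfg, seed = seed + 2L),
    e45 = simulate_recording(story$e45, kern, cfg, seed = seed + 1L))
  sims <- lapply(sims, function(s) {
    s$recording <- bandpass_filter(s$recording, 1, 20, 2)
    s
  })
  std <- standardize_runs(sims)
  eps <- lapply(names(std), function(v)
    epoch_trials(std[[v]]$recording, std[[v]]$regressors, 60,
                 condition = if (v == "e45") "E45" else "Control"))
  ep <- bind_epochs(eps)
  lags <- lag_spec(rate = rate)
  cv <- cross_validate_lambda(ep, lambdas, lags)
  trf_e <- condition_trf(ep, cv$best_lambda, "E45", lags)
  trf_c <- condition_trf(ep, cv$best_lambda, "Control", lags)

  avg <- average_trf(list(trf_e, trf_c))
  truth <- kernel_waveform(kern, "envelope", lags$lags_ms)
  truth <- truth - mean(truth[lags$lags_ms >= -100 & lags$lags_ms <= -4])
  topo <- sims$e45$truth$topographies[, "envelope"]
  est <- apply(avg$weights["envelope", , ], 1,
               function(row) sum(row * topo))
  n4 <- extract_n400(trf_e, trf_c,
                     intersect(default_roi("parietal"), ep$labels))
  true_lat <- kern$surprisal$latency
  list(envelope_r = stats::cor(est, truth),
       n400_latency = n4$latency, n400_latency_true = true_lat,
       latency_error_ms = abs(n4$latency - true_lat),
       lambda = cv$best_lambda, accuracy = cv$accuracy,
       n_trials = length(ep$trials))
}

#' Added-value detection study
#'
#' Simulates a cohort with the group-typical (non-zero) surprisal kernels
#' and tests whether word surprisal adds predictive value beyond the
#' acoustic regressors via [added_value()].
#'
#' @param seed RNG seed.
#' @param n_per_group subjects per group (two groups are simulated).
#' @param rate analysis rate, Hz.
#' @param duration_s run length per condition, seconds.
#' @param trial_s epoch length, seconds.
#' @return the [added_value()] result plus `n_subjects`.
#' @export
added_value_study <- function(seed = 5, n_per_group = 10, rate = 64,
                              duration_s = 120, trial_s = 30) {
  chans <- c("Fz", "FCz", "Cz", "CPz", "Pz", "C3", "C4", "POz")
  cfg <- sim_config(n_per_group = n_per_group, channels = chans,
                    rate = rate, duration_s = duration_s, seed = seed)
  cohort <- simulate_cohort(cfg, trial_s = trial_s)
  lags <- lag_spec(rate = rate)
  av <- added_value(lapply(cohort, `[[`, "epochs"), lags = lags)
  av$n_subjects <- length(cohort)
  av
}

#' Group latency-shift recovery study
#'
#' Simulates a two-group cohort whose N400 kernel centers differ by the
#' configured shift (default 554.3 - 427.2 = 127.1 ms), runs the pipeline
#' (group-level lambda from CV on a subsample, per-condition TRFs,
#' condition-difference waveforms), and measures the between-group latency
#' difference of the grand-average difference waveform over the parietal
#' ROI.
#'
#' @param seed RNG seed.
#' @param n_per_group subjects per group.
#' @param duration_s run length per condition, seconds.
#' @param rate sampling rate, Hz.
#' @param n_cv_subjects subjects used for the group-level lambda curve.
#' @return list with `shift_est`, `shift_true`, `nh_latency`,
#'   `ci_latency`, `lambda`.
#' @export
latency_shift_study <- function(seed = 101, n_per_group = 20,
                                duration_s = 240, rate = 250,
                                n_cv_subjects = 4) {
  roi <- c("P3", "Pz", "P4", "CP1", "CP2", "CPz", "P7", "P8", "POz")
  chans <- c(roi, "Fz", "Cz", "FCz")
  cfg <- sim_config(n_per_group = n_per_group, channels = chans,
                    rate = rate, duration_s = duration_s, seed = seed)
  nh <- group_kernels("NH"); ci <- group_kernels("CI")
  cohort <- simulate_cohort(cfg, nh, ci, trial_s = 60)
  lags <- lag_spec(rate = rate)
  groups <- vapply(cohort, `[[`, character(1), "group")
  cv_idx <- c(which(groups == "NH")[seq_len(ceiling(n_cv_subjects / 2))],
              which(groups == "CI")[seq_len(floor(n_cv_subjects / 2))])
  cvs <- lapply(cohort[cv_idx], function(s)
    cross_validate_lambda(s$epochs, lags = lags))
  lambda_star <- choose_group_lambda(cvs)
  diffs <- lapply(cohort, function(s) {
    te <- condition_trf(s$epochs, lambda_star, "E45", lags)
    tc <- condition_trf(s$epochs, lambda_star, "Control", lags)
    extract_n400(te, tc, roi)$waveform
  })
  lat_of <- function(idx) {
    w <- rowMeans(vapply(diffs[idx], `[[`,
                         numeric(length(lags$lags_ms)), "amplitude"))
    sel <- lags$lags_ms >= 200 & lags$lags_ms <= 1000
    lags$lags_ms[sel][which.min(w[sel])]
  }
  nh_lat <- lat_of(which(groups == "NH"))
  ci_lat <- lat_of(which(groups == "CI"))
  list(shift_est = ci_lat - nh_lat,
       shift_true = ci$surprisal$latency - nh$surprisal$latency,
       nh_latency = nh_lat, ci_latency = ci_lat, lambda = lambda_star)
}

#' Null calibration of the added-value test
#'
#' Simulates cohorts whose surprisal kernel (and incongruity response) is
#' exactly zero, so word surprisal carries no neural signal, and measures
#' how often the one-sided Wilcoxon signed-rank test on the per-subject
#' cross-validated accuracy difference (full minus acoustic model) rejects
#' at level `alpha`. Stories, regressors and therefore the design Grams
#' are fixed per subject; each repeat redraws only the 1/f + white noise,
#' which is what makes hundreds of repeats affordable.
#'
#' @param n_repeats number of null cohorts.
#' @param n_subjects subjects per cohort.
#' @param rate analysis sampling rate, Hz.
#' @param n_trials trials per subject.
#' @param trial_s trial length, seconds.
#' @param n_channels channels (montage subset).
#' @param snr_db SNR of the envelope/onset signal relative to noise.
#' @param lambdas regularization grid.
#' @param alpha test level tallied.
#' @param seed RNG seed.
#' @return list with `rejection_rate`, `p_values` (one per repeat), and
#'   the `delta_r` matrix (repeats x subjects).
#' @export
null_added_value_calibration <- function(n_repeats = 200, n_subjects = 20,
                                         rate = 32, n_trials = 4,
                                         trial_s = 30, n_channels = 8,
                                         snr_db = 0,
                                         lambdas = default_lambda_grid(),
                                         alpha = 0.05, seed = 1) {
  chans <- c("Fz", "FCz", "Cz", "CPz", "Pz", "C3", "C4", "POz",
             "P3", "P4", "F3", "F4")[seq_len(n_channels)]
  band <- c(1, min(20, 0.45 * rate))
  cfg <- sim_config(n_per_group = max(2L, ceiling(n_subjects / 2)),
                    channels = chans, rate = rate,
                    duration_s = n_trials * trial_s, snr_db = Inf,
                    seed = seed)
  lm <- train_ngram(tokenize_text(toy_corpus()), order = 5)
  lags <- lag_spec(rate = rate)
  kern0 <- ground_truth_kernels(n400_gain = 0, incongruity_gain = 0)

  subs <- lapply(seq_len(n_subjects), function(s) {
    set.seed(seed + 37L * s)
    jit <- stats::rnorm(1, 0, cfg$latency_jitter_sd)
    kern <- kern0
    kern$envelope$n1_latency <- kern$envelope$n1_latency + jit
    kern$envelope$p2_latency <- kern$envelope$p2_latency + jit
    build_null_subject(cfg, lm, kern, lags, trial_s, lambdas,
                       sub_seed = seed + 37L * s + 1L, band)
  })

  bf <- signal::butter(2, band / (rate / 2), type = "pass")
  n_smp <- round(trial_s * rate)
  scale_fac <- 10^(-snr_db / 20)
  set.seed(seed + 7919L)
  rep_seeds <- sample.int(2^30, n_repeats)
  delta <- matrix(NA_real_, n_repeats, n_subjects)
  p_values <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(rep_seeds[r])
    for (s in seq_len(n_subjects)) {
      sub <- subs[[s]]
      nch <- nrow(sub$trials[[1L]]$eeg)
      eeg_trials <- lapply(seq_along(sub$trials), function(i) {
        noise <- t(vapply(seq_len(nch), function(ch)
          as.numeric(signal::filtfilt(
            bf, pink_noise(n_smp, 1) + 0.5 * stats::rnorm(n_smp))),
          numeric(n_smp)))
        noise <- noise * (sub$rms_sig * scale_fac / sqrt(mean(noise^2)))
        sub$signal[, , i] + noise
      })
      delta[r, s] <- cached_delta_r(sub, eeg_trials, lags, lambdas)
    }
    p_values[r] <- wilcoxon_signed_rank(delta[r, ], "greater")$p
  }
  list(rejection_rate = mean(p_values < alpha), p_values = p_values,
       delta_r = delta)
}
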