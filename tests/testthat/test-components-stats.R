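# ROI waveforms, TRF component extraction, behavioral scoring, statistics

fake_trf <- function(amp_fun, labels = c("P3", "Pz", "P4"),
                     features = c("envelope", "word_surprisal"),
                     rate = 250) {
  lg <- lag_spec(-100, 1000, rate = rate)
  W <- array(0, c(length(features), length(lg$lags), length(labels)),
             dimnames = list(features, NULL, labels))
  for (f in seq_along(features)) for (ch in seq_along(labels))
    W[f, , ch] <- amp_fun(lg$lags_ms, features[f], labels[ch])
  structure(list(weights = W, intercept = numeric(length(labels)),
                 lags_ms = lg$lags_ms, lags = lg, lambda = 1,
                 features = features, labels = labels,
                 baseline_corrected = TRUE), class = "trf_model")
}

test_that("ROI waveforms average the selected channels", {
  m <- fake_trf(function(t, f, ch) switch(ch, P3 = sin(t / 100),
                                          Pz = -sin(t / 100),
                                          P4 = rep(2, length(t))))
  expect_equal(roi_waveform(m, "envelope", "P4")$amplitude,
               rep(2, length(m$lags_ms)))
  expect_equal(roi_waveform(m, "envelope", c("P3", "Pz"))$amplitude,
               rep(0, length(m$lags_ms)))
  w3 <- roi_waveform(m, "envelope", c("P3", "Pz", "P4"))
  expect_equal(w3$amplitude, (sin(m$lags_ms / 100) - sin(m$lags_ms / 100)
                              + 2) / 3)
  expect_error(roi_waveform(m, "envelope", character(0)), "ROI")
  expect_error(roi_waveform(m, "envelope", "Cz"), "Cz")
  expect_error(roi_waveform(m, "nope", "Pz"), "feature")
})

test_that("sensory peaks find constructed extrema and handle flats", {
  wf <- list(lags_ms = seq(-100, 1000, by = 4),
             amplitude = -2 * exp(-0.5 * ((seq(-100, 1000, by = 4) - 100) / 20)^2) +
               3 * exp(-0.5 * ((seq(-100, 1000, by = 4) - 200) / 20)^2))
  pk <- extract_sensory_peaks(wf)
  expect_lte(abs(pk$N1$latency - 100), 4)
  expect_lte(abs(pk$P2$latency - 200), 4)
  expect_equal(pk$n1p2, pk$P2$amplitude - pk$N1$amplitude)
  expect_gt(pk$n1p2, 4.5)

  flat <- list(lags_ms = wf$lags_ms, amplitude = rep(0, length(wf$lags_ms)))
  pkf <- extract_sensory_peaks(flat)
  expect_equal(pkf$N1$amplitude, 0)
  expect_equal(pkf$n1p2, 0)
  expect_equal(pkf$N1$latency, 52)     # first sample inside 50-150 ms
  expect_error(extract_sensory_peaks(list(lags_ms = 0:10, amplitude = 0:10)),
               "window")
})

test_that("peak latency is scale-invariant, amplitude scales linearly", {
  t <- seq(-100, 1000, by = 4)
  wf <- list(lags_ms = t, amplitude = -exp(-0.5 * ((t - 120) / 30)^2) +
               0.8 * exp(-0.5 * ((t - 210) / 30)^2))
  wf5 <- list(lags_ms = t, amplitude = 5 * wf$amplitude)
  p1 <- extract_sensory_peaks(wf); p5 <- extract_sensory_peaks(wf5)
  expect_equal(p5$N1$latency, p1$N1$latency)
  expect_equal(p5$P2$latency, p1$P2$latency)
  expect_equal(p5$n1p2, 5 * p1$n1p2)
})

test_that("the N400 difference component is recovered from two models", {
  g <- function(t, c, s) exp(-0.5 * ((t - c) / s)^2)
  base <- fake_trf(function(t, f, ch) 0.2 * g(t, 150, 40))
  e45 <- fake_trf(function(t, f, ch)
    0.2 * g(t, 150, 40) - if (f == "word_surprisal") g(t, 500, 40) else 0)
  roi <- c("P3", "Pz", "P4")
  n4 <- extract_n400(e45, base, roi)
  expect_lte(abs(n4$latency - 500), 4)
  # analytic mean of the Gaussian over latency +- 10 ms
  sel <- seq(-100, 1000, by = 4)
  win <- sel >= n4$latency - 10 & sel <= n4$latency + 10
  expect_equal(n4$amplitude, mean(-g(sel[win], 500, 40)), tolerance = 1e-12)
  analytic <- -integrate(function(x) g(x, 500, 40),
                         n4$latency - 10, n4$latency + 10)$value / 20
  expect_equal(n4$amplitude, analytic, tolerance = 0.02)

  same <- extract_n400(base, base, roi)
  expect_equal(same$amplitude, 0)
  # two equal minima: earlier one wins
  twin <- fake_trf(function(t, f, ch)
    if (f == "word_surprisal") -(g(t, 400, 30) + g(t, 700, 30)) else 0)
  n4t <- extract_n400(twin, base, roi)
  expect_lt(n4t$latency, 450)
  short <- fake_trf(function(t, f, ch) 0, rate = 250)
  short$lags_ms <- short$lags_ms[short$lags_ms < 500]
  short$weights <- short$weights[, seq_along(short$lags_ms), , drop = FALSE]
  expect_error(extract_n400(short, short, roi), "cover")
})

test_that("listening span scoring counts matches and judgments", {
  # full design: loads 2..6, three blocks each -> 60 words
  set.seed(31)
  words <- replicate(15, NULL)
  loads <- rep(2:6, each = 3)
  pool <- sprintf("word%02d", 1:60)
  k <- 0
  blocks <- lapply(seq_len(15), function(i) {
    pres <- pool[(k + 1):(k + loads[i])]
    k <<- k + loads[i]
    list(presented = pres,
         recalled = pres[seq_len(ceiling(loads[i] / 2))],
         judgments = rep(TRUE, loads[i]))
  })
  sc <- score_listening_span(blocks)
  expect_equal(sc$n_words, 60)
  expect_equal(sc$judgment_pct, 100)
  n_rec <- sum(ceiling(loads / 2))
  expect_equal(sc$recall_pct, 100 * n_rec / 60)

  half <- list(list(presented = pool[1:4], recalled = pool[1:2],
                    judgments = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(score_listening_span(half)$recall_pct, 50)
  expect_equal(score_listening_span(half)$judgment_pct, 50)
  none <- list(list(presented = pool[1:4], recalled = character(0),
                    judgments = rep(TRUE, 4)))
  expect_equal(score_listening_span(none)$recall_pct, 0)
  # duplicates credited once per presented instance; case-insensitive
  dup <- list(list(presented = c("Torch", "lamp"),
                   recalled = c("torch", "TORCH", "torch"),
                   judgments = TRUE))
  expect_equal(score_listening_span(dup)$recall_pct, 50)
})

test_that("SSQ domain means", {
  items <- data.frame(domain = c(rep("speech", 3), rep("spatial", 2),
                                 rep("quality", 2)),
                      rating = c(4, 4, 4, 8, 8, 8, 8))
  sc <- score_ssq(items)
  expect_equal(sc$speech, 4)
  expect_equal(sc$spatial, 8)
  expect_equal(sc$all, mean(items$rating))
  all10 <- score_ssq(data.frame(domain = c("speech", "spatial", "quality"),
                                rating = 10))
  expect_equal(unlist(all10), c(speech = 10, spatial = 10, quality = 10,
                                all = 10))
  hand <- score_ssq(data.frame(domain = rep("quality", 5),
                               rating = c(1, 4, 6, 7, 9)))
  expect_equal(hand$quality, 5.4)
  expect_error(score_ssq(data.frame(domain = "speech", rating = 11)), "0-10")
  expect_error(score_ssq(data.frame(domain = "smell", rating = 5)), "domain")
})

test_that("Welch t matches the textbook formula and conventions", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, 2 * pt(t_hand, df_hand))
  # pooled-SD Cohen's d
  expect_equal(res$d, (mean(a) - mean(b)) / 1)
  flipped <- welch_t(b, a)
  expect_equal(flipped$statistic, -res$statistic)
  expect_equal(flipped$p, res$p)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("Welch reduces to pooled t for equal n and variance", {
  set.seed(32)
  a <- rnorm(15); b <- a * 1 + 2   # identical variances exactly
  w <- welch_t(a, b)
  cl <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(cl$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(cl$parameter), tolerance = 1e-10)
})

test_that("Cohen's d confidence interval brackets d and covers truth", {
  set.seed(33)
  a <- rnorm(20, 1); b <- rnorm(20, 0)
  res <- welch_t(a, b)
  expect_lt(res$d_ci[1], res$d)
  expect_gt(res$d_ci[2], res$d)
})

test_that("Wilcoxon signed-rank follows the stated conventions", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6))$p, 1 / 64)
  sym <- wilcoxon_signed_rank(c(-3, 3.2, -1, 1.1, -2, 2.1, 4, -4.4))$p
  expect_gt(sym, 0.3); expect_lt(sym, 0.7)
  d <- c(1.5, -2.5, 3.5, 4.5, -0.5, 2, -1, 5)
  expect_equal(wilcoxon_signed_rank(d, "greater")$p,
               wilcoxon_signed_rank(-d, "less")$p)
  # zeros dropped
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5, 6))$n, 6)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("mixed ANOVA matches a brute-force sums-of-squares oracle", {
  # 4 subjects (2 per group), one within factor with 2 levels
  d <- expand.grid(subject = paste0("s", 1:4), model = c("ac", "full"))
  d$group <- ifelse(d$subject %in% c("s1", "s2"), "g1", "g2")
  set.seed(34)
  d$value <- c(1, 2, 4, 5, 1.5, 2.2, 4.8, 6.1)
  res <- mixed_anova(d, between = "group", within = "model")

  # oracle: explicit SS decomposition
  mu <- mean(d$value)
  subj_m <- tapply(d$value, d$subject, mean)
  grp_m <- tapply(d$value, d$group, mean)
  mod_m <- tapply(d$value, d$model, mean)
  cell_m <- tapply(d$value, list(d$group, d$model), mean)
  ss_group <- 4 * sum((grp_m - mu)^2)
  ss_subj_within <- 2 * sum((subj_m - grp_m[c("g1", "g1", "g2", "g2")])^2)
  ss_model <- 4 * sum((mod_m - mu)^2)
  ss_gm <- 2 * sum((cell_m - outer(grp_m - mu, mod_m - mu, `+`) - mu)^2)
  ss_tot <- sum((d$value - mu)^2)
  ss_err_within <- ss_tot - ss_group - ss_subj_within - ss_model - ss_gm
  f_group <- (ss_group / 1) / (ss_subj_within / 2)
  f_model <- (ss_model / 1) / (ss_err_within / 2)
  f_gm <- (ss_gm / 1) / (ss_err_within / 2)
  expect_equal(res$F[res$effect == "group"], f_group, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "model"], f_model, tolerance = 1e-10)
  expect_equal(res$F[res$effect == "group:model"], f_gm, tolerance = 1e-10)

  shifted <- d; shifted$value <- d$value + 100
  res2 <- mixed_anova(shifted, "group", "model")
  expect_equal(res2$F, res$F, tolerance = 1e-9)
  expect_error(mixed_anova(d[-1, ], "group", "model"), "balanced")
})

test_that("three-factor mixed ANOVA runs on a cohort-shaped design", {
  set.seed(35)
  d <- expand.grid(subject = paste0("s", 1:8),
                   model = c("acoustic", "full"),
                   condition = c("Control", "E45"))
  d$group <- ifelse(d$subject %in% paste0("s", 1:4), "CI", "NH")
  d$value <- rnorm(nrow(d)) + (d$model == "full") * 0.5
  res <- mixed_anova(d, "group", c("model", "condition"))
  expect_setequal(
    res$effect,
    c("group", "model", "group:model", "condition", "group:condition",
      "model:condition", "group:model:condition"))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("Spearman + FDR behave per definition", {
  set.seed(36)
  x <- rnorm(30)
  out <- spearman_fdr(list(mono = list(x = x, y = exp(x))))
  expect_equal(out$rho, 1)
  xi <- rnorm(100)
  out2 <- spearman_fdr(list(indep = list(x = xi, y = sample(xi))))
  expect_lt(abs(out2$rho), 0.25)
  expect_error(spearman_fdr(list(const = list(x = rep(1, 10),
                                              y = rnorm(10)))), "constant")
  expect_error(spearman_fdr(list(short = list(x = 1:4, y = 4:1))), "n < 5")
  # BH step-up by hand
  expect_equal(bh_adjust(c(.01, .02, .03, .04)), rep(.04, 4))
  p <- c(0.001, 0.01, 0.04, 0.2)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # missing values dropped pairwise
  xm <- c(x, NA); ym <- c(exp(x), 3)
  expect_equal(spearman_fdr(list(a = list(x = xm, y = ym)))$n, 30)
})

test_that("chi-square handles correction, proportional and extreme tables", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  expect_equal(chi_square_2x2(prop, continuity = FALSE)$statistic, 0)
  extreme <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2), continuity = FALSE)
  expect_equal(extreme$statistic, 20)
  expect_equal(extreme$df, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("minimum detectable effect behaves at the power limits", {
  d_mid <- min_detectable_effect(21, 21, 0.05, 0.8, "one.sided")
  d_low <- min_detectable_effect(21, 21, 0.05, 0.06, "one.sided")
  expect_lt(d_low, 0.1)
  expect_gt(d_mid, d_low)
  d_two <- min_detectable_effect(21, 21, 0.05, 0.8, "two.sided")
  expect_gt(d_two, d_mid)
  expect_error(min_detectable_effect(21, 21, 0.05, 0.04), "power")
})

test_that("returned effect size attains the requested power by simulation", {
  d <- min_detectable_effect(21, 21, 0.05, 0.8, "one.sided")
  set.seed(37)
  nrep <- 50000
  crit <- qt(0.95, 40)
  a <- matrix(rnorm(21 * nrep, mean = d), 21)
  b <- matrix(rnorm(21 * nrep), 21)
  tstat <- (colMeans(a) - colMeans(b)) /
    sqrt((apply(a, 2, var) + apply(b, 2, var)) / 21)
  # pooled df = 40 for equal n; empirical power at the analytic d
  expect_equal(mean(tstat > crit), 0.80, tolerance = 0.01)
})
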