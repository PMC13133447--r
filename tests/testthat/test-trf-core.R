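# lagged designs, Tikhonov solver, cross-validation, model comparison

test_that("lagged design shifts features with zero padding", {
  lg <- list(lags = c(0L, 1L), lags_ms = c(0, 100))
  class(lg) <- "lag_spec"
  D <- build_lagged_design(cbind(f1 = c(1, 2, 3)), lg, intercept = FALSE)
  expect_equal(unname(D), cbind(c(1, 2, 3), c(0, 1, 2)))
  lg$lags <- -1L; lg$lags_ms <- -100
  Dn <- build_lagged_design(cbind(f1 = c(1, 2, 3)), lg, intercept = FALSE)
  expect_equal(unname(drop(Dn)), c(2, 3, 0))
})

test_that("a unit impulse identifies the EEG segment as the kernel", {
  set.seed(5)
  lg <- lag_spec(-100, 1000, rate = 10)
  y <- rnorm(100)
  imp <- matrix(0, 100, 1); imp[40, 1] <- 1
  colnames(imp) <- "f"
  D <- build_lagged_design(imp, lg)
  fit <- fit_tikhonov(D, cbind(y), 0, lg)
  # kernel + intercept reproduces the segment y[40 + tau]
  expect_equal(unname(fit$weights[1, , 1] + fit$intercept),
               y[40 + lg$lags], tolerance = 1e-8)
})

test_that("lambda = 0 equals brute-force normal equations", {
  set.seed(6)
  lg <- lag_spec(-100, 1000, rate = 4)   # 5 lags
  reg <- matrix(rnorm(50 * 2), 50, 2,
                dimnames = list(NULL, c("a", "b")))
  y <- matrix(rnorm(50 * 3), 50, 3)
  D <- build_lagged_design(reg, lg)
  fit <- fit_tikhonov(D, y, 0, lg)
  w_oracle <- solve(t(D) %*% D, t(D) %*% y)
  expect_lt(max(abs(speechTRF:::trf_weight_matrix(fit) - w_oracle)), 1e-8)
  expect_error(fit_tikhonov(D, y, -1, lg), "lambda")
  expect_error(fit_tikhonov(D, y[-1, ], 0, lg), "rows")
})

test_that("weight norm is non-increasing in lambda", {
  set.seed(7)
  lg <- lag_spec(-100, 1000, rate = 10)
  reg <- matrix(rnorm(400), 400, 1, dimnames = list(NULL, "f"))
  y <- cbind(rnorm(400))
  D <- build_lagged_design(reg, lg)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1e4, 1e6), function(l)
    sqrt(sum(fit_tikhonov(D, y, l, lg)$weights^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  expect_lt(norms[length(norms)], 0.01 * norms[1])
})

test_that("second-difference penalty smooths the kernel", {
  set.seed(8)
  lg <- lag_spec(-100, 1000, rate = 25)
  reg <- matrix(rnorm(600), 600, 1, dimnames = list(NULL, "f"))
  y <- cbind(rnorm(600))
  D <- build_lagged_design(reg, lg)
  rough <- function(w) sum(diff(w, differences = 2)^2)
  w_id <- fit_tikhonov(D, y, 50, lg, penalty = "identity")$weights[1, , 1]
  w_sm <- fit_tikhonov(D, y, 50, lg, penalty = "derivative")$weights[1, , 1]
  expect_lt(rough(w_sm), rough(w_id))
})

test_that("sufficient statistics reproduce the explicit design exactly", {
  set.seed(9)
  for (n in c(64, 200, 3000)) {
    reg <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("envelope", "word_onset",
                                          "word_surprisal")))
    eeg <- matrix(rnorm(4 * n), 4, n)
    lg <- lag_spec(-100, 1000, rate = if (n > 500) 50 else 10)
    D <- build_lagged_design(reg, lg)
    ss <- speechTRF:::trial_suffstats(reg, eeg, lg)
    expect_lt(max(abs(crossprod(D) - ss$G)), 1e-8)
    expect_lt(max(abs(crossprod(D, t(eeg)) - ss$B)), 1e-8)
    bs <- speechTRF:::trial_bstats(reg, eeg, lg)
    expect_equal(bs$B, ss$B)
  }
})

test_that("noiseless forward simulation is inverted to machine precision", {
  set.seed(10)
  lg <- lag_spec(-100, 1000, rate = 50)
  n <- 1000
  reg <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  kerns <- list(dnorm(lg$lags_ms, 120, 40), -dnorm(lg$lags_ms, 400, 60))
  y <- forward_eeg(reg, kerns, lg)
  fit <- fit_tikhonov(build_lagged_design(reg, lg), cbind(y), 0, lg)
  est <- rbind(fit$weights[1, , 1], fit$weights[2, , 1])
  expect_lt(sqrt(mean((est - do.call(rbind, kerns))^2)), 1e-6)
})

test_that("cross-validation scores held-out trials only and breaks ties low", {
  set.seed(11)
  lg <- lag_spec(-100, 1000, rate = 20)
  trials <- lapply(1:4, function(i) {
    reg <- matrix(rnorm(300 * 2), 300, 2,
                  dimnames = list(NULL, c("envelope", "word_onset")))
    k <- list(dnorm(lg$lags_ms, 150, 50), 0.5 * dnorm(lg$lags_ms, 300, 80))
    eeg <- rbind(forward_eeg(reg, k, lg))
    list(eeg = eeg, reg = reg, condition = "Control")
  })
  ep <- structure(list(trials = trials, rate = 20, labels = "ch1"),
                  class = "epoched_data")
  cv <- cross_validate_lambda(ep, lambdas = c(2^-5, 1, 2^5), lags = lg)
  # noiseless forward data: near-perfect prediction, smallest lambda wins
  expect_gt(cv$accuracy, 0.99)
  expect_equal(cv$best_lambda, 2^-5)
  for (f in cv$folds) expect_false(f$test %in% f$train)
  expect_equal(sort(unique(vapply(cv$folds, `[[`, integer(1), "test"))), 1:4)
  # grid of one value
  cv1 <- cross_validate_lambda(ep, lambdas = 4, lags = lg)
  expect_equal(cv1$best_lambda, 4)
  expect_error(cross_validate_lambda(
    structure(list(trials = trials[1], rate = 20), class = "epoched_data"),
    lags = lg), "2 trials")
})

test_that("pure-noise EEG yields chance-level prediction accuracy", {
  set.seed(12)
  lg <- lag_spec(-100, 1000, rate = 16)
  trials <- lapply(1:5, function(i) list(
    eeg = matrix(rnorm(2 * 400), 2, 400),
    reg = matrix(rnorm(400 * 2), 400, 2,
                 dimnames = list(NULL, c("envelope", "word_onset"))),
    condition = "Control"))
  ep <- structure(list(trials = trials, rate = 16, labels = c("c1", "c2")),
                  class = "epoched_data")
  cv <- cross_validate_lambda(ep, lags = lg)
  expect_lt(abs(cv$accuracy), 0.15)
})

test_that("prediction scoring matches a hand-computed correlation", {
  # 3-sample oracle: r computed from the definition
  lg <- list(lags = 0L, lags_ms = 0)
  class(lg) <- "lag_spec"
  model <- speechTRF:::new_trf_model(
    W = rbind(0, 2), lags = lg, features = "f", labels = "ch1", lambda = 0)
  trial <- list(reg = cbind(f = c(1, 2, 4)), eeg = rbind(c(2, 3, 9)))
  sc <- score_prediction(model, trial)
  pred <- 2 * c(1, 2, 4); obs <- c(2, 3, 9)
  r_hand <- sum((pred - mean(pred)) * (obs - mean(obs))) /
    sqrt(sum((pred - mean(pred))^2) * sum((obs - mean(obs))^2))
  expect_equal(unname(sc$r), r_hand)
  # fitting a trial and scoring it, noiseless, lambda 0 -> r = 1
  set.seed(13)
  lg2 <- lag_spec(-100, 1000, rate = 10)
  reg <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "f"))
  y <- forward_eeg(reg, list(dnorm(lg2$lags_ms, 200, 80)), lg2)
  fit <- fit_tikhonov(build_lagged_design(reg, lg2), cbind(ch1 = y), 0, lg2)
  expect_equal(unname(score_prediction(fit, list(reg = reg,
                                                 eeg = rbind(y)))$r), 1,
               tolerance = 1e-9)
  # orthogonal random signals -> r near 0
  expect_lt(abs(score_prediction(fit, list(
    reg = reg, eeg = rbind(rnorm(200))))$mean_r), 0.3)
  expect_warning(
    score_prediction(fit, list(reg = cbind(f = numeric(200)),
                               eeg = rbind(rnorm(200)))), "zero-variance")
})

test_that("condition TRFs average epochs and baseline-correct", {
  set.seed(14)
  lg <- lag_spec(-100, 1000, rate = 20)
  reg <- matrix(rnorm(400), 400, 1, dimnames = list(NULL, "f"))
  y <- forward_eeg(reg, list(dnorm(lg$lags_ms, 200, 60) + 0.3), lg)
  tr <- list(eeg = rbind(y), reg = reg, condition = "A")
  ep <- structure(list(trials = list(tr, tr), rate = 20, labels = "ch1"),
                  class = "epoched_data")
  m2 <- condition_trf(ep, 0.01, lags = lg)
  m1 <- condition_trf(structure(list(trials = list(tr), rate = 20,
                                     labels = "ch1"),
                                class = "epoched_data"), 0.01, lags = lg)
  expect_equal(m2$weights, m1$weights, tolerance = 1e-10)
  bl <- m2$lags_ms >= -100 & m2$lags_ms <= -4
  expect_lt(max(abs(apply(m2$weights[, bl, , drop = FALSE], c(1, 3), mean))),
            1e-9)
  # mirrored responses cancel
  trn <- list(eeg = rbind(-y), reg = reg, condition = "A")
  epn <- structure(list(trials = list(tr, trn), rate = 20, labels = "ch1"),
                   class = "epoched_data")
  mn <- condition_trf(epn, 0.01, lags = lg)
  expect_lt(max(abs(mn$weights)), 1e-8)
  expect_error(condition_trf(ep, 0.01, condition = "missing", lags = lg),
               "no trials")
})

test_that("an all-zero surprisal channel adds no predictive value", {
  set.seed(15)
  lg <- lag_spec(-100, 1000, rate = 16)
  subj <- lapply(1:2, function(s) {
    trials <- lapply(1:3, function(i) {
      reg <- cbind(envelope = rnorm(320), word_onset = rnorm(320),
                   word_surprisal = 0)
      k <- list(dnorm(lg$lags_ms, 150, 50), 0.4 * dnorm(lg$lags_ms, 250, 70),
                numeric(length(lg$lags)))
      list(eeg = rbind(forward_eeg(reg, k, lg) + 0.5 * rnorm(320)),
           reg = reg, condition = "Control")
    })
    structure(list(trials = trials, rate = 16, labels = "ch1"),
              class = "epoched_data")
  })
  suppressWarnings({
    av <- added_value(subj, lambdas = c(0.1, 10), lags = lg)
  })
  expect_lt(max(abs(av$delta_r)), 1e-9)
})
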