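# Shared fixtures, built once per test run.

the_cat_corpus <- function() tokenize_text("the cat sat . the cat ran .")

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

toy_lm <- function(order = 5, smoothing = "add_k") {
  memo(paste0("lm_", order, "_", smoothing), function()
    train_ngram(tokenize_text(toy_corpus()), order = order,
                smoothing = smoothing))
}

# small annotated token table with contiguous words
tiny_tokens <- function() {
  token_table(c("the", "dog", "ran", "home"),
              onset = c(0.5, 0.8, 1.1, 1.5),
              offset = c(0.8, 1.1, 1.5, 1.9),
              surprisal = c(4, 2, 3, 1))
}

# white-noise regressor set for well-conditioned TRF problems
white_regressors <- function(n, rate, seed = 1) {
  set.seed(seed)
  regressor_set(rnorm(n), rnorm(n), rnorm(n), rate)
}

# forward-simulate EEG = sum_f conv(x_f, k_f) for given kernel rows
forward_eeg <- function(reg_mat, kernels_by_feature, lags) {
  n <- nrow(reg_mat)
  D <- build_lagged_design(reg_mat, lags)
  w <- c(0, as.numeric(t(do.call(rbind, kernels_by_feature))))
  drop(D %*% w)
}

expect_all_finite <- function(x) expect_true(all(is.finite(unlist(x))))
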