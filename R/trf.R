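#' Lag specification for TRF estimation
#'
#' Defines the window of stimulus-to-response time lags over which the
#' temporal response function is estimated, and its sampling rate.
#'
#' @param t_min,t_max lag window in ms (`t_min < 0 < t_max`; defaults
#'   -100 to 1000 ms).
#' @param rate sampling rate, Hz.
#' @return list with integer sample lags and the lag axis in ms.
#' @export
lag_spec <- function(t_min = -100, t_max = 1000, rate) {
  if (!(t_min < 0 && t_max > 0)) stop("require t_min < 0 < t_max", call. = FALSE)
  smp <- seq.int(round(t_min / 1000 * rate), round(t_max / 1000 * rate))
  structure(list(t_min = t_min, t_max = t_max, rate = rate,
                 lags = smp, lags_ms = smp / rate * 1000),
            class = "lag_spec")
}

default_lambda_grid <- function() 2 ^ seq(-5, 15)

#' Build the lagged (time-expanded) design matrix
#'
#' Column (f, tau) holds stimulus feature f delayed by tau samples
#' (out-of-range samples zero-padded); a leading intercept column is
#' included. Negative lags advance the feature (response preceding the
#' stimulus, used for the baseline part of the window).
#'
#' @param reg samples x features numeric matrix (or a [regressor_set()]).
#' @param lags a [lag_spec()].
#' @param intercept include the leading intercept column.
#' @return samples x (1 + features * n_lags) matrix.
#' @export
build_lagged_design <- function(reg, lags, intercept = TRUE) {
  if (inherits(reg, "regressor_set")) reg <- regressor_matrix(reg)
  reg <- as.matrix(reg)
  n <- nrow(reg)
  if (length(lags$lags) > n)
    stop("lag window longer than the trial", call. = FALSE)
  cols <- lapply(seq_len(ncol(reg)), function(f)
    vapply(lags$lags, function(tau) {
      out <- numeric(n)
      src <- seq_len(n) - tau
      ok <- src >= 1L & src <= n
      out[ok] <- reg[src[ok], f]
      out
    }, numeric(n)))
  D <- do.call(cbind, cols)
  fn <- colnames(reg) %||% paste0("f", seq_len(ncol(reg)))
  colnames(D) <- paste0(rep(fn, each = length(lags$lags)), "@",
                        rep(round(lags$lags_ms, 3), ncol(reg)))
  if (intercept) D <- cbind("(intercept)" = 1, D)
  D
}

# second-difference (smoothness) penalty block for one feature's lags
second_diff_penalty <- function(L) {
  if (L < 3L) return(diag(L))
  Dm <- diff(diag(L), differences = 2)
  crossprod(Dm)
}

penalty_matrix <- function(penalty, n_feat, n_lag) {
  blk <- switch(penalty,
                identity = diag(n_lag),
                derivative = second_diff_penalty(n_lag),
                stop("unknown penalty: ", penalty, call. = FALSE))
  M <- matrix(0, n_feat * n_lag, n_feat * n_lag)
  for (f in seq_len(n_feat)) {
    idx <- ((f - 1L) * n_lag + 1L):(f * n_lag)
    M[idx, idx] <- blk
  }
  M
}

#' Fit a Tikhonov-regularized TRF from an explicit design
#'
#' Solves `(D'D + lambda * M) w = D'y` per channel, where `M` is the
#' identity (classical ridge, default) or a per-feature second-difference
#' smoothness matrix; the intercept column is never penalized. This is the
#' reference solver; the cross-validation and per-condition fitting paths
#' compute the same solution from sufficient statistics without
#' materializing the design.
#'
#' @param design output of [build_lagged_design()] (intercept first column).
#' @param eeg samples x channels matrix (or an [eeg_recording()], which is
#'   transposed).
#' @param lambda regularization strength, `>= 0`.
#' @param lags the [lag_spec()] used for the design.
#' @param features feature names (defaults recovered from design columns).
#' @param penalty `"identity"` or `"derivative"`.
#' @return object of class `trf_model` with `weights`
#'   (features x lags x channels), `intercept` (per channel), `lags_ms`,
#'   `lambda`, `features`, `labels`.
#' @export
fit_tikhonov <- function(design, eeg, lambda, lags,
                         features = NULL, penalty = "identity") {
  if (inherits(eeg, "eeg_recording")) eeg <- t(eeg$data)
  eeg <- as.matrix(eeg)
  if (nrow(design) != nrow(eeg))
    stop("design rows must equal EEG samples", call. = FALSE)
  if (any(!is.finite(design)) || any(!is.finite(eeg)))
    stop("non-finite inputs", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  L <- length(lags$lags)
  n_feat <- (ncol(design) - 1L) / L
  if (n_feat != round(n_feat)) stop("design/lag mismatch", call. = FALSE)
  if (is.null(features)) {
    features <- unique(sub("@.*$", "", colnames(design)[-1L])) %||%
      paste0("f", seq_len(n_feat))
  }
  M <- rbind(0, cbind(0, penalty_matrix(penalty, n_feat, L)))
  A <- crossprod(design) + lambda * M
  W <- solve(A, crossprod(design, eeg))
  new_trf_model(W, lags, features,
                labels = colnames(eeg) %||% paste0("ch", seq_len(ncol(eeg))),
                lambda = lambda)
}

new_trf_model <- function(W, lags, features, labels, lambda,
                          baseline_corrected = FALSE) {
  L <- length(lags$lags)
  n_feat <- length(features)
  weights <- array(W[-1L, , drop = FALSE], dim = c(L, n_feat, ncol(W)))
  weights <- aperm(weights, c(2L, 1L, 3L))
  dimnames(weights) <- list(features, NULL, labels)
  structure(list(weights = weights, intercept = W[1L, ],
                 lags_ms = lags$lags_ms, lags = lags, lambda = lambda,
                 features = features, labels = labels,
                 baseline_corrected = baseline_corrected),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf(
    "<trf_model> %d features x %d lags (%g..%g ms) x %d channels, lambda = %g%s\n",
    dim(x$weights)[1], dim(x$weights)[2], min(x$lags_ms), max(x$lags_ms),
    dim(x$weights)[3], x$lambda,
    if (x$baseline_corrected) ", baseline-corrected" else ""))
  invisible(x)
}

# stacked weight matrix (intercept + features*lags) from a trf_model
trf_weight_matrix <- function(model) {
  W <- apply(model$weights, 3L, function(m) as.numeric(t(m)))
  rbind(model$intercept, W)
}

# ---------------------------------------------------------------------------
# Sufficient statistics of the lagged regression, computed in O(n * L) per
# feature pair through running cross-products instead of the explicit
# (n x F*L) design. Exactness against build_lagged_design is covered by a
# dedicated test.

trial_suffstats <- function(reg, eeg, lags) {
  reg <- as.matrix(reg)
  stopifnot(is.matrix(eeg))
  Y <- t(eeg)                      # samples x channels
  n <- nrow(reg)
  stopifnot(nrow(Y) == n)
  taus <- lags$lags
  L <- length(taus)
  F <- ncol(reg)
  p <- F * L + 1L
  tau_min <- min(taus); tau_max <- max(taus)

  L2 <- stats::nextn(2L * n, 2)
  pad <- function(M) rbind(M, matrix(0, L2 - n, ncol(M)))
  FX <- stats::mvfft(pad(reg))
  FY <- stats::mvfft(pad(Y))
  # full-overlap cross-correlation c_d = sum_u a[u] b[u+d], d = -(n-1)..(n-1)
  xcorr_full <- function(Fa, Fb) {
    cc <- Re(stats::mvfft(Conj(Fa) * Fb, inverse = TRUE)) / L2
    cc
  }
  at_lag <- function(cc, d) cc[ifelse(d >= 0L, d + 1L, L2 + d + 1L)]

  G <- matrix(0, p, p)
  G[1L, 1L] <- n
  # intercept x lagged-feature blocks: shifted column sums via prefix sums
  for (f in seq_len(F)) {
    cs <- c(0, cumsum(reg[, f]))
    lo <- pmax(1L, 1L - taus); hi <- pmin(n, n - taus)
    s <- ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0)
    G[1L, 1L + (f - 1L) * L + seq_len(L)] <- s
  }

  # feature-pair lag blocks: entry (tau1, tau2) = sum over the in-range
  # samples of x_f delayed tau1 times x_g delayed tau2. Equal to the full
  # cross-correlation at d = tau1 - tau2 minus head/tail terms that fall
  # outside the trial for the given (tau1, tau2); those corrections touch
  # at most max(|tau|) samples at each end.
  Kh <- max(0L, -tau_min); Kt <- max(0L, tau_max)
  small_n <- n < (Kh + Kt + 2L) * 2L
  for (f in seq_len(F)) for (g in f:F) {
    xf <- reg[, f]; xg <- reg[, g]
    blk <- matrix(0, L, L)
    cc_fg <- xcorr_full(FX[, f, drop = FALSE], FX[, g, drop = FALSE])[, 1L]
    for (d in (tau_min - tau_max):(tau_max - tau_min)) {
      umin <- max(1L, 1L - d); umax <- min(n, n - d)
      if (umax < umin) next
      t1 <- taus[taus >= tau_min + max(0L, d) & taus <= tau_max + min(0L, d)]
      if (!length(t1)) next
      lo <- pmax(umin, 1L - t1); hi <- pmin(umax, n - t1)
      if (small_n) {
        z <- xf[umin:umax] * xg[(umin + d):(umax + d)]
        cz <- c(0, cumsum(z))
        v <- ifelse(hi >= lo, cz[hi - umin + 2L] - cz[lo - umin + 1L], 0)
      } else {
        # full-overlap value corrected by short partial sums at each end
        nh <- min(Kh, umax - umin + 1L)
        zh <- xf[umin:(umin + nh - 1L)] * xg[(umin + d):(umin + d + nh - 1L)]
        czh <- c(0, cumsum(zh))
        nt <- min(Kt, umax - umin + 1L)
        zt <- xf[(umax - nt + 1L):umax] * xg[(umax - nt + 1L + d):(umax + d)]
        czt <- c(0, cumsum(rev(zt)))        # czt[k+1] = sum of last k terms
        head_trim <- lo - umin              # 0..Kh terms cut from the head
        tail_trim <- umax - hi              # 0..Kt terms cut from the tail
        v <- at_lag(cc_fg, d) - czh[head_trim + 1L] - czt[tail_trim + 1L]
        v[hi < lo] <- 0
      }
      i1 <- match(t1, taus); i2 <- match(t1 - d, taus)
      blk[cbind(i1, i2)] <- v
    }
    ri <- 1L + (f - 1L) * L + seq_len(L)
    ci <- 1L + (g - 1L) * L + seq_len(L)
    G[ri, ci] <- blk
    if (g > f) G[ci, ri] <- t(blk)
  }
  G[-1L, 1L] <- G[1L, -1L]

  B <- matrix(0, p, ncol(Y))
  B[1L, ] <- colSums(Y)
  idx <- ifelse(taus >= 0L, taus + 1L, L2 + taus + 1L)
  for (f in seq_len(F)) {
    cc <- xcorr_full(FX[, f, drop = FALSE][, rep(1L, ncol(Y)), drop = FALSE], FY)
    B[1L + (f - 1L) * L + seq_len(L), ] <- cc[idx, , drop = FALSE]
  }

  list(G = G, B = B, n = n,
       sy = colSums(Y), syy = colSums(Y^2))
}

sum_suffstats <- function(ss_list) {
  out <- ss_list[[1L]]
  for (s in ss_list[-1L]) {
    out$G <- out$G + s$G; out$B <- out$B + s$B
    out$n <- out$n + s$n; out$sy <- out$sy + s$sy; out$syy <- out$syy + s$syy
  }
  out
}

# EEG-dependent half of the sufficient statistics (B = X'y, y sums); the
# regressor Gram does not change when only the EEG is redrawn, which the
# calibration helpers exploit
trial_bstats <- function(reg, eeg, lags) {
  reg <- as.matrix(reg)
  Y <- t(eeg)
  n <- nrow(reg)
  taus <- lags$lags
  L <- length(taus)
  L2 <- stats::nextn(2L * n, 2)
  pad <- function(M) rbind(M, matrix(0, L2 - n, ncol(M)))
  FX <- stats::mvfft(pad(reg))
  FY <- stats::mvfft(pad(Y))
  B <- matrix(0, ncol(reg) * L + 1L, ncol(Y))
  B[1L, ] <- colSums(Y)
  idx <- ifelse(taus >= 0L, taus + 1L, L2 + taus + 1L)
  for (f in seq_len(ncol(reg))) {
    cc <- Re(stats::mvfft(Conj(FX[, f, drop = FALSE][, rep(1L, ncol(Y)),
                                                     drop = FALSE]) * FY,
                          inverse = TRUE)) / L2
    B[1L + (f - 1L) * L + seq_len(L), ] <- cc[idx, , drop = FALSE]
  }
  list(B = B, n = n, sy = colSums(Y), syy = colSums(Y^2))
}

# eigendecomposition of the intercept-centered Gram, reusable across
# lambdas and EEG redraws
center_gram_eigen <- function(G, n) {
  g0 <- G[1L, -1L]
  Gc <- G[-1L, -1L] - tcrossprod(g0) / n
  eg <- eigen(Gc, symmetric = TRUE)
  list(vectors = eg$vectors, values = pmax(eg$values, 0), g0 = g0, n = n)
}

# ridge solutions over a lambda grid from summed sufficient statistics,
# intercept eliminated by centering (rank-one Gram update), single
# eigendecomposition reused for every lambda
solve_ridge_grid <- function(ss, lambdas, penalty = "identity",
                             n_feat = NULL, n_lag = NULL, eig = NULL) {
  p <- nrow(ss$G %||% ss$B)
  g0 <- if (is.null(eig)) ss$G[1L, -1L] else eig$g0
  if (is.null(eig)) Gc <- ss$G[-1L, -1L] - tcrossprod(g0) / ss$n
  Bc <- ss$B[-1L, , drop = FALSE] - outer(g0, ss$B[1L, ]) / ss$n
  n_ch <- ncol(Bc)
  W <- array(0, dim = c(p, n_ch, length(lambdas)))
  if (penalty == "identity" && length(lambdas) == 1L && is.null(eig)) {
    # single lambda: a direct symmetric solve beats the eigen path
    A <- Gc
    diag(A) <- diag(A) + lambdas
    w1 <- solve(A, Bc)
    W[1L, , 1L] <- (ss$B[1L, ] - drop(crossprod(w1, g0))) / ss$n
    W[-1L, , 1L] <- w1
  } else if (penalty == "identity") {
    eg <- if (is.null(eig)) {
      e <- eigen(Gc, symmetric = TRUE)
      list(vectors = e$vectors, values = pmax(e$values, 0))
    } else eig
    alpha <- crossprod(eg$vectors, Bc)       # (p-1) x ch
    for (j in seq_along(lambdas)) {
      w1 <- eg$vectors %*% (alpha / (eg$values + lambdas[j]))
      w0 <- (ss$B[1L, ] - drop(crossprod(w1, g0))) / ss$n
      W[1L, , j] <- w0
      W[-1L, , j] <- w1
    }
  } else {
    M <- penalty_matrix(penalty, n_feat, n_lag)
    for (j in seq_along(lambdas)) {
      w1 <- solve(Gc + lambdas[j] * M, Bc)
      w0 <- (ss$B[1L, ] - drop(crossprod(w1, g0))) / ss$n
      W[1L, , j] <- w0
      W[-1L, , j] <- w1
    }
  }
  W
}

# Pearson r of predictions vs observations per channel, from test-trial
# sufficient statistics; W is p x ch (one lambda)
score_from_suffstats <- function(ss, W) {
  n <- ss$n
  syh <- drop(crossprod(W, ss$G[1L, ]))                       # sum(yhat)
  GW <- ss$G %*% W
  syhyh <- colSums(W * GW)                                    # sum(yhat^2)
  syyh <- colSums(W * ss$B)                                   # sum(y yhat)
  num <- n * syyh - ss$sy * syh
  den <- sqrt(pmax(n * ss$syy - ss$sy^2, 0) *
              pmax(n * syhyh - syh^2, 0))
  r <- ifelse(den > 0, num / den, 0)
  pmin(pmax(r, -1), 1)
}

#' Leave-one-out cross-validated selection of the regularization strength
#'
#' For each lambda on the grid and each held-out trial, fits the TRF on the
#' remaining trials, predicts the held-out EEG, and computes the Pearson
#' correlation between predicted and observed signal per channel, averaged
#' over channels and folds. The chosen lambda maximizes the mean prediction
#' accuracy; ties break toward the smallest lambda. The group-level variant
#' (averaging accuracy curves across participants before choosing, the
#' pipeline default) is available via [choose_group_lambda()].
#'
#' @param epochs an [epoch_trials()] result (or list of trials).
#' @param lambdas lambda grid (default `2^-5 .. 2^15`, 21 values).
#' @param lags a [lag_spec()] (default -100..1000 ms at the epoch rate).
#' @param features regressor channels to include (default all).
#' @param penalty see [fit_tikhonov()].
#' @return object of class `cv_result`: `lambdas`, `mean_r` (per lambda),
#'   `fold_r` (folds x lambdas), `best_lambda`, `accuracy` (mean r at the
#'   chosen lambda), and fold bookkeeping in `folds`.
#' @export
cross_validate_lambda <- function(epochs, lambdas = default_lambda_grid(),
                                  lags = NULL, features = NULL,
                                  penalty = "identity") {
  trials <- if (inherits(epochs, "epoched_data")) epochs$trials else epochs
  if (length(trials) < 2L)
    stop("cross-validation needs at least 2 trials", call. = FALSE)
  if (is.null(lags)) lags <- lag_spec(rate = epochs$rate)
  feats <- features %||% colnames(trials[[1L]]$reg)
  L <- length(lags$lags)

  ss <- lapply(trials, function(tr)
    trial_suffstats(tr$reg[, feats, drop = FALSE], tr$eeg, lags))
  tot <- sum_suffstats(ss)
  n_fold <- length(trials)
  fold_r <- matrix(NA_real_, n_fold, length(lambdas))
  folds <- vector("list", n_fold)
  for (i in seq_len(n_fold)) {
    train <- tot
    train$G <- tot$G - ss[[i]]$G; train$B <- tot$B - ss[[i]]$B
    train$n <- tot$n - ss[[i]]$n
    train$sy <- tot$sy - ss[[i]]$sy; train$syy <- tot$syy - ss[[i]]$syy
    W <- solve_ridge_grid(train, lambdas, penalty,
                          n_feat = length(feats), n_lag = L)
    for (j in seq_along(lambdas))
      fold_r[i, j] <- mean(score_from_suffstats(ss[[i]], W[, , j]))
    folds[[i]] <- list(test = i, train = setdiff(seq_len(n_fold), i))
  }
  mean_r <- colMeans(fold_r)
  best <- which(mean_r >= max(mean_r) - 1e-15)[1L]
  structure(list(lambdas = lambdas, mean_r = mean_r, fold_r = fold_r,
                 best_lambda = lambdas[best], accuracy = mean_r[best],
                 folds = folds, features = feats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d lambdas, best = %g (mean r = %.4f)\n",
              length(x$lambdas), x$best_lambda, x$accuracy))
  invisible(x)
}

#' Group-level lambda choice
#'
#' Averages cross-validation accuracy curves across participants (and
#' conditions) and returns the lambda maximizing the grand-average
#' prediction accuracy, ties toward the smallest lambda.
#'
#' @param cv_list list of [cross_validate_lambda()] results on a common
#'   lambda grid.
#' @export
choose_group_lambda <- function(cv_list) {
  grid <- cv_list[[1L]]$lambdas
  curves <- vapply(cv_list, function(cv) {
    stopifnot(identical(cv$lambdas, grid))
    cv$mean_r
  }, numeric(length(grid)))
  m <- rowMeans(curves)
  grid[which(m >= max(m) - 1e-15)[1L]]
}

#' Predict held-out EEG and score the match
#'
#' @param model a [fit_tikhonov()] result.
#' @param trial a single trial (list with `reg`, samples x features, and
#'   `eeg`, channels x samples).
#' @return list with per-channel Pearson `r`, `mean_r`, and the predicted
#'   samples x channels matrix.
#' @export
score_prediction <- function(model, trial) {
  D <- build_lagged_design(trial$reg[, model$features, drop = FALSE],
                           model$lags)
  pred <- D %*% trf_weight_matrix(model)
  obs <- t(trial$eeg)
  r <- vapply(seq_len(ncol(obs)), function(ch) {
    if (stats::sd(pred[, ch]) == 0 || stats::sd(obs[, ch]) == 0) {
      warning("zero-variance prediction; r set to 0")
      return(0)
    }
    stats::cor(pred[, ch], obs[, ch])
  }, numeric(1))
  list(r = stats::setNames(r, model$labels), mean_r = mean(r), prediction = pred)
}

#' Per-condition TRF: per-epoch fits averaged, baseline-corrected
#'
#' Fits one TRF per epoch at the supplied lambda, averages the weights
#' across epochs of the condition, and subtracts the mean over the baseline
#' lag window from every feature x channel kernel.
#'
#' @param epochs an [epoch_trials()] result (or trial list).
#' @param lambda regularization strength (typically the CV optimum).
#' @param condition restrict to trials with this condition label
#'   (default: all).
#' @param lags a [lag_spec()].
#' @param features regressor channels to include.
#' @param baseline_ms baseline window in ms, default `c(-100, -4)`.
#' @param penalty see [fit_tikhonov()].
#' @return a baseline-corrected `trf_model`.
#' @export
condition_trf <- function(epochs, lambda, condition = NULL, lags = NULL,
                          features = NULL, baseline_ms = c(-100, -4),
                          penalty = "identity") {
  trials <- if (inherits(epochs, "epoched_data")) epochs$trials else epochs
  if (!is.null(condition))
    trials <- Filter(function(tr) identical(tr$condition, condition), trials)
  if (!length(trials)) stop("no trials for condition", call. = FALSE)
  if (is.null(lags)) lags <- lag_spec(rate = epochs$rate)
  feats <- features %||% colnames(trials[[1L]]$reg)
  L <- length(lags$lags)
  Ws <- lapply(trials, function(tr) {
    ss <- trial_suffstats(tr$reg[, feats, drop = FALSE], tr$eeg, lags)
    w <- solve_ridge_grid(ss, lambda, penalty,
                          n_feat = length(feats), n_lag = L)
    matrix(w[, , 1L], nrow = dim(w)[1L])
  })
  W <- Reduce(`+`, Ws) / length(Ws)
  labels <- if (inherits(epochs, "epoched_data")) epochs$labels
            else paste0("ch", seq_len(nrow(trials[[1L]]$eeg)))
  model <- new_trf_model(W, lags, feats, labels, lambda)
  baseline_correct(model, baseline_ms)
}

#' Baseline-correct a TRF model
#'
#' Subtracts, per feature and channel, the mean kernel value over the
#' baseline lag window from the whole kernel.
#'
#' @param model a `trf_model`.
#' @param baseline_ms window in ms, default `c(-100, -4)`.
#' @export
baseline_correct <- function(model, baseline_ms = c(-100, -4)) {
  sel <- model$lags_ms >= baseline_ms[1L] & model$lags_ms <= baseline_ms[2L]
  if (!any(sel)) stop("baseline window outside lag axis", call. = FALSE)
  bl <- apply(model$weights[, sel, , drop = FALSE], c(1L, 3L), mean)
  model$weights <- sweep(model$weights, c(1L, 3L), bl, `-`)
  model$baseline_corrected <- TRUE
  model
}

# average trf_models (shared lag axis / features / channels)
average_trf <- function(models) {
  out <- models[[1L]]
  out$weights <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  out$intercept <- Reduce(`+`, lapply(models, `[[`, "intercept")) / length(models)
  out
}

#' Added predictive value of word surprisal
#'
#' Compares cross-validated prediction accuracy of the acoustic model
#' (envelope + word onset) against the full model (envelope + word onset +
#' word surprisal) for every participant, averaging across conditions, and
#' tests the per-participant accuracy difference with a one-sided Wilcoxon
#' signed-rank test (H1: median difference > 0). Cohen's d is reported as
#' mean/SD of the differences.
#'
#' @param subjects list of per-subject [epoch_trials()] results containing
#'   all three regressor channels.
#' @param lambdas lambda grid for cross-validation.
#' @param lags a [lag_spec()] (default -100..1000 ms at the data rate).
#' @param acoustic,full feature sets defining the two models.
#' @return list with `delta_r` per subject, accuracies per model, the
#'   Wilcoxon `test`, and `cohens_d`.
#' @export
added_value <- function(subjects, lambdas = default_lambda_grid(),
                        lags = NULL,
                        acoustic = c("envelope", "word_onset"),
                        full = c("envelope", "word_onset", "word_surprisal")) {
  acc <- vapply(subjects, function(ep) {
    cva <- cross_validate_lambda(ep, lambdas, lags, features = acoustic)
    cvf <- cross_validate_lambda(ep, lambdas, lags, features = full)
    c(acoustic = cva$accuracy, full = cvf$accuracy)
  }, numeric(2))
  delta <- acc["full", ] - acc["acoustic", ]
  if (length(delta) < 5L)
    warning("fewer than 5 participants; test underpowered")
  test <- wilcoxon_signed_rank(delta, alternative = "greater")
  d <- mean(delta) / stats::sd(delta)
  list(delta_r = delta, accuracy = t(acc), test = test, cohens_d = d)
}
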