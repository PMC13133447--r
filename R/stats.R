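# Group and correlation statistics used by the analysis: thin, contract-
# checked wrappers over the base R tests, plus effect sizes with the
# conventions fixed here (pooled-SD Cohen's d, noncentral-t confidence
# intervals, BH false discovery rate).

#' Welch's two-sample t-test with Cohen's d
#'
#' Welch statistic with Welch-Satterthwaite fractional degrees of freedom;
#' Cohen's d uses the pooled-SD standardizer with a noncentral-t 95%
#' confidence interval.
#'
#' @param a,b numeric samples (each `n >= 2`).
#' @param tails `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `statistic`, `df`, `p`, `d`, `d_ci`, group means.
#' @export
welch_t <- function(a, b, tails = "two.sided") {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples", call. = FALSE)
  ht <- stats::t.test(a, b, alternative = tails, var.equal = FALSE)
  d <- cohens_d_pooled(a, b)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = d$d, d_ci = d$ci,
       mean_a = mean(a), mean_b = mean(b))
}

cohens_d_pooled <- function(a, b, conf = 0.95) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  d <- (mean(a) - mean(b)) / sp
  # CI by inverting the noncentral t distribution of d * sqrt(n_eff)
  ne <- sqrt(na * nb / (na + nb))
  tval <- d * ne
  df <- na + nb - 2
  lo_p <- (1 - conf) / 2
  ncp_bound <- function(target_p) {
    # pt() warns about reduced tail precision for large ncp; harmless here
    f <- function(ncp) suppressWarnings(stats::pt(tval, df, ncp = ncp)) -
      target_p
    lim <- abs(tval) + 10 + 4 * sqrt(df)
    if (f(-lim) * f(lim) > 0) return(sign(tval) * lim)
    stats::uniroot(f, c(-lim, lim), tol = 1e-8)$root
  }
  ci <- c(ncp_bound(1 - lo_p), ncp_bound(lo_p)) / ne
  list(d = d, ci = sort(ci))
}

#' One-sided Wilcoxon signed-rank test on paired differences
#'
#' Zeros dropped by convention; exact p for `n <= 25`, normal approximation
#' with continuity correction above.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative `"greater"` (default), `"less"`, `"two.sided"`.
#' @return list with `statistic` (V), `p`, `n` (nonzero differences).
#' @export
wilcoxon_signed_rank <- function(diffs, alternative = "greater") {
  diffs <- diffs[is.finite(diffs)]
  nz <- diffs[diffs != 0]
  if (!length(nz)) stop("all differences are zero", call. = FALSE)
  n <- length(nz)
  ht <- suppressWarnings(
    stats::wilcox.test(nz, alternative = alternative,
                       exact = (n <= 25) && !anyDuplicated(abs(nz)),
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = n)
}

#' Mixed repeated-measures ANOVA
#'
#' Standard partitioned sums of squares for one between-subject factor and
#' up to two crossed within-subject factors: the between effect is tested
#' against the between-subject error, each within effect and its
#' interactions against the corresponding subject-by-factor error stratum
#' (via `aov` with an `Error(subject/...)` term). Requires a complete
#' balanced design.
#'
#' @param data data.frame with columns `value`, `subject`, plus the factor
#'   columns named in `between` and `within`.
#' @param between name of the between-subject factor.
#' @param within character vector of within-subject factor names.
#' @return data.frame with effect, F, df1, df2, p.
#' @export
mixed_anova <- function(data, between, within) {
  need <- c("value", "subject", between, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (v in c("subject", between, within)) data[[v]] <- factor(data[[v]])
  counts <- table(data[c("subject", within)])
  if (any(counts != 1L)) stop("design must be complete and balanced",
                              call. = FALSE)
  wterm <- paste(within, collapse = "*")
  fml <- stats::as.formula(sprintf(
    "value ~ %s * %s + Error(subject/(%s))", between, wterm, wterm))
  fit <- stats::aov(fml, data = data)
  out <- do.call(rbind, lapply(summary(fit), function(stratum) {
    tab <- stratum[[1L]]
    eff <- trimws(rownames(tab))
    keep <- eff != "Residuals"
    if (!any(keep)) return(NULL)
    data.frame(effect = eff[keep],
               F = tab$`F value`[keep],
               df1 = tab$Df[keep],
               df2 = tab$Df[!keep][1L],
               p = tab$`Pr(>F)`[keep])
  }))
  rownames(out) <- NULL
  out
}

#' Spearman correlations with FDR correction across a family
#'
#' Pairwise-complete Spearman rho with tie-aware p-values, and
#' Benjamini-Hochberg q-values across the submitted family of pairs.
#'
#' @param pairs named list; each element a list/data.frame with `x` and
#'   `y`.
#' @return data.frame with pair, n (pairwise complete), rho, p, q.
#' @export
spearman_fdr <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(i) {
    x <- pairs[[i]]$x; y <- pairs[[i]]$y
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 5L) stop("pair ", i, ": n < 5", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("pair ", i, ": constant variable, rho undefined", call. = FALSE)
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(pair = names(pairs)[i] %||% paste0("pair", i),
               n = length(x), rho = unname(ht$estimate), p = ht$p.value)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Chi-square test of independence on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative counts (all margins > 0).
#' @param continuity apply Yates continuity correction.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Minimum detectable effect size for a two-sample t-test
#'
#' The smallest Cohen's d at which an independent-samples t-test with the
#' given group sizes attains the requested power (sensitivity analysis),
#' found by noncentral-t root finding on the power function.
#'
#' @param n1,n2 group sizes.
#' @param alpha significance level.
#' @param power target power in `(alpha, 1)`.
#' @param tails `"one.sided"` or `"two.sided"`.
#' @return Cohen's d.
#' @export
min_detectable_effect <- function(n1, n2, alpha = 0.05, power = 0.80,
                                  tails = c("one.sided", "two.sided")) {
  tails <- match.arg(tails)
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  if (power <= alpha || power >= 1)
    stop("power must lie in (alpha, 1)", call. = FALSE)
  df <- n1 + n2 - 2
  ne <- sqrt(n1 * n2 / (n1 + n2))
  power_at <- function(d) {
    ncp <- d * ne
    if (tails == "one.sided") {
      crit <- stats::qt(1 - alpha, df)
      1 - stats::pt(crit, df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
    }
  }
  stats::uniroot(function(d) power_at(d) - power, c(1e-8, 20),
                 tol = 1e-10)$root
}

#' Benjamini-Hochberg q-values (step-up)
#'
#' Convenience wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p vector of p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
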