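# Statistical battery: bootstrap Pearson correlation, bootstrap one-way
# ANOVA, Levene's variance-equality test, Lilliefors-corrected
# Kolmogorov-Smirnov normality check, and a residualization utility for
# covariate adjustment. Resampling loops are seeded and reproducible
# bit-for-bit.

#' Pearson correlation with bootstrap confidence interval
#'
#' Point estimate and two-sided p from the exact r-to-t reference
#' distribution; 95% CI from `n_boot` case-resampled replicates
#' (percentile method).
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return list of class `boot_stat`: `estimate`, `ci_low`, `ci_high`,
#'   `p`, `n`, `n_boot`, `seed`, `statistic = "pearson_r"`.
#' @export
bootstrap_correlation <- function(x, y, n_boot = 1000L, seed = 1L,
                                  conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  p <- stats::cor.test(x, y)$p.value
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i])
  }, numeric(1))
  ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(estimate = r, ci_low = ci[1], ci_high = ci[2], p = p,
                 n = n, n_boot = n_boot, seed = seed,
                 statistic = "pearson_r"),
            class = "boot_stat")
}

#' @export
print.boot_stat <- function(x, ...) {
  cat(x$statistic, "=", format(x$estimate, digits = 4),
      sprintf("[%s, %s]", format(x$ci_low, digits = 4),
              format(x$ci_high, digits = 4)),
      "p =", format.pval(x$p, digits = 3),
      sprintf("(n = %d, n_boot = %d, seed = %d)\n", x$n, x$n_boot, x$seed))
  invisible(x)
}

# one-way ANOVA F via the standard linear-model machinery
.oneway_f <- function(values, groups) {
  fit <- stats::aov(values ~ groups)
  summary(fit)[[1]][["F value"]][1]
}

#' One-way ANOVA F statistic with bootstrap confidence interval
#'
#' Observed F from the standard one-way analysis of variance; CI by
#' resampling cases within each group (group sizes preserved). Optional
#' covariates are regressed out of the response first (residualization),
#' so e.g. network-size or demographic effects can be removed before
#' comparing networks.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2).
#' @param n_boot,seed,conf as in [bootstrap_correlation()].
#' @param covariates optional data.frame of covariates, one row per
#'   observation in `unlist(groups)` order.
#' @return list of class `boot_stat` with `estimate` (F), percentile CI,
#'   `p` from the F reference distribution, `df1`, `df2`.
#' @export
bootstrap_anova <- function(groups, n_boot = 1000L, seed = 1L, conf = 0.95,
                            covariates = NULL) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  v <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(v))) stop("non-finite values")
  if (!is.null(covariates)) v <- residualize(v, covariates)
  f_obs <- .oneway_f(v, g)
  df1 <- length(groups) - 1L
  df2 <- length(v) - length(groups)
  p <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  set.seed(seed)
  idx <- split(seq_along(v), g)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- unlist(lapply(idx, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]),
      use.names = FALSE)
    .oneway_f(v[i], g)
  }, numeric(1))
  ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(estimate = f_obs, ci_low = ci[1], ci_high = ci[2], p = p,
                 df1 = df1, df2 = df2, n = length(v), n_boot = n_boot,
                 seed = seed, statistic = "anova_F"),
            class = "boot_stat")
}

#' Residualize a response on covariates
#'
#' Returns the residuals of `values ~ covariates` (intercept included),
#' re-centered on the original mean. Constant covariates reduce to the
#' identity.
#'
#' @param values numeric vector.
#' @param covariates data.frame or matrix, one row per value.
#' @return numeric vector of adjusted values.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(col) length(unique(col)) > 1L,
                 logical(1))
  if (!any(keep)) return(values)
  fit <- stats::lm(values ~ ., data = covariates[, keep, drop = FALSE])
  stats::residuals(fit) + mean(values)
}

#' Levene's test for equality of variances
#'
#' Mean-centered variant (absolute deviations from the group means),
#' delegated to `car::leveneTest`.
#'
#' @param groups list of numeric vectors.
#' @return list with `statistic` (W), `p`, `df1`, `df2`.
#' @export
levene_test <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups with >= 2 values each")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  v <- unlist(groups, use.names = FALSE)
  dev <- abs(v - ave(v, g))
  if (all(dev == 0))  # every group internally constant: no dispersion at all
    return(list(statistic = 0, p = 1,
                df1 = length(groups) - 1L, df2 = length(v) - length(groups)))
  res <- car::leveneTest(v, g, center = mean)
  list(statistic = res[1, "F value"], p = res[1, "Pr(>F)"],
       df1 = res[1, "Df"], df2 = res[2, "Df"])
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test against a normal with the sample's mean and SD.
#' Because the parameters are estimated, the default uses the Lilliefors
#' correction (`nortest::lillie.test`); `correct = FALSE` gives the plain
#' KS p (anti-conservative).
#'
#' @param x numeric vector, n >= 5.
#' @param correct use the Lilliefors-corrected p (default TRUE).
#' @return list with `statistic` (D), `p`.
#' @export
ks_normality <- function(x, correct = TRUE) {
  x <- x[is.finite(x)]
  if (length(x) < 5L) stop("need n >= 5")
  if (stats::sd(x) == 0) stop("zero variance: normality test undefined")
  if (correct) {
    res <- nortest::lillie.test(x)
  } else {
    res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                           stats::sd(x)))
  }
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Pairwise t-tests with Bonferroni correction
#'
#' Post-hoc utility for group comparisons after a significant ANOVA.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `t`, `p_bonferroni`.
#' @export
pairwise_bonferroni <- function(groups) {
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  cmb <- utils::combn(length(groups), 2)
  m <- ncol(cmb)
  rows <- lapply(seq_len(m), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    tt <- stats::t.test(groups[[a]], groups[[b]])
    data.frame(group1 = nm[a], group2 = nm[b], t = unname(tt$statistic),
               p_bonferroni = min(1, tt$p.value * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
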