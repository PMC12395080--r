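#' Hedges' g standardized mean difference
#'
#' Bias-corrected SMD between the delirious and non-delirious arms of one
#' subgroup. With pooled SD
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)},
#' \eqn{d = (\bar x_{del} - \bar x_{ctrl})/s_p}, the small-sample correction
#' \eqn{J = 1 - 3/(4(n_1+n_2-2) - 1)} gives \eqn{g = J d} with sampling
#' variance \eqn{J^2 [(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))]}. The sign
#' convention is delirious minus non-delirious: features that are lower in
#' delirium give negative g.
#'
#' @param x_del numeric values from the delirious arm (n >= 2).
#' @param x_ctrl numeric values from the non-delirious arm (n >= 2).
#' @param conf_level confidence level for the Wald CI.
#' @return A list of class `hedges_g`: `g`, `var_g`, `ci_lo`, `ci_hi`, `d`,
#'   `J`, `n_del`, `n_ctrl`.
#' @export
#' @examples
#' hedges_g(c(0, 1), c(1, 2))$g  # -0.80812
hedges_g <- function(x_del, x_ctrl, conf_level = 0.95) {
  x_del <- as.numeric(x_del); x_ctrl <- as.numeric(x_ctrl)
  if (!all(is.finite(x_del)) || !all(is.finite(x_ctrl))) {
    stop("inputs must be finite", call. = FALSE)
  }
  n1 <- length(x_del); n2 <- length(x_ctrl)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  s2p <- ((n1 - 1) * stats::var(x_del) + (n2 - 1) * stats::var(x_ctrl)) /
    (n1 + n2 - 2)
  if (s2p <= 0) stop("zero pooled variance: effect size undefined", call. = FALSE)
  d <- (mean(x_del) - mean(x_ctrl)) / sqrt(s2p)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * d
  var_g <- J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(g = g, var_g = var_g,
                 ci_lo = g - z * sqrt(var_g), ci_hi = g + z * sqrt(var_g),
                 d = d, J = J, n_del = n1, n_ctrl = n2),
            class = "hedges_g")
}

#' @export
print.hedges_g <- function(x, ...) {
  cat(sprintf("Hedges' g = %.4f (95%% CI %.4f to %.4f), var = %.5f, n = %d/%d\n",
              x$g, x$ci_lo, x$ci_hi, x$var_g, x$n_del, x$n_ctrl))
  invisible(x)
}

#' Percentile bootstrap CI of the mean
#'
#' Nonparametric descriptive CI used instead of a normal-theory interval
#' because the feature distributions are not Gaussian. Resamples with
#' replacement, takes the mean of each resample, and reports the percentile
#' interval.
#'
#' @param x numeric values, n >= 2.
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed (required: results must be reproducible).
#' @return A list of class `bootstrap_summary`: `mean`, `ci_lo`, `ci_hi`,
#'   `n_boot`, `level`, `seed`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 1000, level = 0.95, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need n >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  means <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  nrow = n_boot)
    rowMeans(matrix(x[idx], nrow = n_boot))
  })
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(mean = mean(x), ci_lo = qs[1], ci_hi = qs[2],
                 n_boot = n_boot, level = level, seed = seed),
            class = "bootstrap_summary")
}

#' Cochran's Q heterogeneity test
#'
#' Fixed-effect inverse-variance weights \eqn{w_i = 1/v_i}; Q is the weighted
#' sum of squared deviations from the fixed-effect pooled estimate, referred
#' to a chi-square distribution with k - 1 df.
#'
#' @param g_i effect estimates (k >= 2).
#' @param var_i their sampling variances (> 0).
#' @return A list: `Q`, `df`, `p`.
#' @export
cochran_q <- function(g_i, var_i) {
  k <- length(g_i)
  if (k < 2) stop("need at least 2 effects", call. = FALSE)
  if (length(var_i) != k) stop("g_i and var_i must have equal length", call. = FALSE)
  if (any(var_i <= 0)) stop("all variances must be positive", call. = FALSE)
  w <- 1 / var_i
  g_fe <- sum(w * g_i) / sum(w)
  Q <- sum(w * (g_i - g_fe)^2)
  df <- k - 1
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared heterogeneity statistic
#'
#' Percentage of total variability attributable to between-study
#' heterogeneity rather than sampling error:
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param Q Cochran's Q (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return I-squared in percent, in [0, 100].
#' @export
i_squared <- function(Q, df) {
  if (Q < 0) stop("Q must be non-negative", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (Q == 0) return(0)
  max(0, (Q - df) / Q) * 100
}

# restricted log-likelihood of the random-effects model at tau2 (vectorized
# over tau2); used by the Fisher-scoring convergence check and exported for
# testing against a grid search.
reml_loglik <- function(tau2, g_i, var_i) {
  vapply(tau2, function(t) {
    w <- 1 / (var_i + t)
    mu <- sum(w * g_i) / sum(w)
    -0.5 * (sum(log(var_i + t)) + log(sum(w)) + sum(w * (g_i - mu)^2))
  }, numeric(1))
}

#' REML estimate of between-study variance
#'
#' Estimates tau^2 of the random-effects model
#' \eqn{g_i \sim N(\mu, v_i + \tau^2)} by restricted maximum likelihood,
#' using Fisher scoring with the estimate floored at 0, convergence
#' tolerance `tol` on the change in tau^2 and at most `max_iter` iterations.
#'
#' @param g_i effect estimates (k >= 2).
#' @param var_i sampling variances (> 0).
#' @param tol convergence tolerance on |delta tau^2| (default 1e-8).
#' @param max_iter maximum Fisher-scoring iterations (default 200).
#' @return The tau^2 estimate (>= 0).
#' @export
reml_tau2 <- function(g_i, var_i, tol = 1e-8, max_iter = 200) {
  k <- length(g_i)
  if (k < 2) stop("need at least 2 effects", call. = FALSE)
  if (any(var_i <= 0)) stop("all variances must be positive", call. = FALSE)
  # DerSimonian-Laird start, floored at 0
  q <- cochran_q(g_i, var_i)
  w <- 1 / var_i
  t2 <- max(0, (q$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  for (iter in seq_len(max_iter)) {
    w <- 1 / (var_i + t2)
    sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
    mu <- sum(w * g_i) / sw
    r2 <- (g_i - mu)^2
    score <- -0.5 * sw + 0.5 * sum(w^2 * r2) + 0.5 * sw2 / sw
    info <- 0.5 * sw2 - sw3 / sw + 0.5 * (sw2 / sw)^2
    if (info <= 0) info <- 0.5 * sw2  # fall back to ML information
    t2_new <- t2 + score / info
    if (t2_new < 0) t2_new <- 0
    if (abs(t2_new - t2) < tol) return(t2_new)
    if (t2 == 0 && t2_new == 0) return(0)
    t2 <- t2_new
  }
  stop(sprintf("REML did not converge after %d iterations (last tau2 = %g)",
               max_iter, t2), call. = FALSE)
}

#' Random-effects meta-analysis of subgroup effects
#'
#' The central pooling model: subgroup standardized mean differences are
#' combined with inverse-variance random-effects weights
#' \eqn{w_i^* = 1/(v_i + \tau^2)}, with tau^2 estimated by REML
#' ([reml_tau2()]). The pooled effect is \eqn{\sum w_i^* g_i / \sum w_i^*}
#' with standard error \eqn{1/\sqrt{\sum w_i^*}} and a Wald CI. Cochran's Q
#' (computed with fixed-effect weights, the standard definition) and
#' I-squared quantify heterogeneity.
#'
#' @param g_i effect estimates, one per subgroup (k >= 2).
#' @param var_i sampling variances (> 0).
#' @param labels optional subgroup labels.
#' @param conf_level confidence level (default 0.95).
#' @param tau2 optional fixed tau^2; if supplied, REML is skipped (tau2 = 0
#'   reproduces the fixed-effect inverse-variance result exactly).
#' @return An object of class `rema` with components `b` (pooled estimate),
#'   `se`, `ci_lo`, `ci_hi`, `zval`, `pval`, `tau2`, `Q`, `df`, `p_Q`, `I2`,
#'   `weights` (normalized, summing to 1), `g_i`, `var_i`, `labels`, `k`.
#' @export
#' @examples
#' fit <- rema(c(0.4, 0.6, 0.5), c(0.05, 0.04, 0.06))
#' coef(fit); confint(fit)
rema <- function(g_i, var_i, labels = NULL, conf_level = 0.95, tau2 = NULL) {
  k <- length(g_i)
  if (k < 2) stop("need at least 2 subgroups to pool", call. = FALSE)
  if (length(var_i) != k) stop("g_i and var_i must have equal length", call. = FALSE)
  if (any(!is.finite(g_i)) || any(!is.finite(var_i)) || any(var_i <= 0)) {
    stop("effects must be finite with positive variances", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("subgroup_", seq_len(k))
  t2 <- if (is.null(tau2)) reml_tau2(g_i, var_i) else {
    stopifnot(tau2 >= 0); tau2
  }
  w <- 1 / (var_i + t2)
  b <- sum(w * g_i) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  q <- cochran_q(g_i, var_i)
  structure(list(
    b = b, se = se, ci_lo = b - z * se, ci_hi = b + z * se,
    zval = b / se, pval = 2 * stats::pnorm(-abs(b / se)),
    tau2 = t2, Q = q$Q, df = q$df, p_Q = q$p, I2 = i_squared(q$Q, q$df),
    weights = w / sum(w), g_i = g_i, var_i = var_i, labels = labels,
    k = k, conf_level = conf_level
  ), class = "rema")
}

#' @export
print.rema <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis (REML), k = %d\n", x$k))
  cat(sprintf("  pooled SMD %.3f (%.0f%% CI %.3f to %.3f), z = %.2f, p = %.3g\n",
              x$b, 100 * x$conf_level, x$ci_lo, x$ci_hi, x$zval, x$pval))
  cat(sprintf("  tau^2 = %.4f; Q = %.2f (df %d, p = %.3g); I^2 = %.0f%%\n",
              x$tau2, x$Q, x$df, x$p_Q, x$I2))
  invisible(x)
}

#' @export
summary.rema <- function(object, ...) {
  tab <- data.frame(
    subgroup = object$labels, g = object$g_i, var_g = object$var_i,
    weight = object$weights, stringsAsFactors = FALSE
  )
  out <- list(fit = object, subgroups = tab)
  class(out) <- "summary.rema"
  out
}

#' @export
print.summary.rema <- function(x, ...) {
  print(x$fit)
  cat("\nSubgroups:\n")
  print(x$subgroups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.rema <- function(object, ...) c(pooled_g = object$b)

#' @export
confint.rema <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    return(c(object$b - z * object$se, object$b + z * object$se))
  }
  c(object$ci_lo, object$ci_hi)
}

#' @export
weights.rema <- function(object, ...) {
  stats::setNames(object$weights, object$labels)
}

#' Status-stratified heterogeneity of subgroup means
#'
#' Meta-analysis of the raw subgroup means of one status arm (delirious or
#' non-delirious only), with sampling variance sd_i^2 / n_i, to ask in which
#' arm the between-subgroup variability lives. Returns I-squared and the
#' Q-test p-value. Works on raw means (not SMDs): within one status there is
#' no group contrast to standardize.
#'
#' @param means subgroup means of one status arm (k >= 2).
#' @param sds subgroup standard deviations.
#' @param ns subgroup sample sizes (>= 2 each).
#' @return A list: `I2` (percent), `p` (Q-test), `Q`, `df`, `tau2`.
#' @export
status_heterogeneity <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2) stop("need at least 2 subgroups", call. = FALSE)
  if (length(sds) != k || length(ns) != k) stop("inputs must share length", call. = FALSE)
  if (any(ns < 2)) stop("each subgroup needs n >= 2", call. = FALSE)
  if (any(sds <= 0)) stop("standard deviations must be positive", call. = FALSE)
  var_i <- sds^2 / ns
  q <- cochran_q(means, var_i)
  list(I2 = i_squared(q$Q, q$df), p = q$p, Q = q$Q, df = q$df,
       tau2 = reml_tau2(means, var_i))
}

#' Age-adjusted delirium effect on a qEEG feature
#'
#' Ordinary least-squares regression of the feature on delirium status with
#' age as covariate: `feature ~ status + age`. Reports coefficients,
#' standard errors and two-sided t-test p-values (n - 3 df).
#'
#' @param feature_values numeric outcome (n >= 4).
#' @param delirium_status logical or 0/1 vector.
#' @param ages numeric ages in years.
#' @return A data frame with rows `(Intercept)`, `status`, `age` and columns
#'   `estimate`, `se`, `t`, `p`.
#' @export
age_adjusted_effect <- function(feature_values, delirium_status, ages) {
  y <- as.numeric(feature_values)
  status <- as.numeric(delirium_status)
  ages <- as.numeric(ages)
  n <- length(y)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (length(status) != n || length(ages) != n) stop("inputs must share length", call. = FALSE)
  if (length(unique(status)) < 2) stop("delirium status is constant: model is collinear", call. = FALSE)
  if (length(unique(ages)) < 2) stop("age is constant: model is collinear", call. = FALSE)
  fit <- stats::lm(y ~ status + ages)
  cf <- summary(fit)$coefficients
  data.frame(term = c("(Intercept)", "status", "age"),
             estimate = cf[, 1], se = cf[, 2], t = cf[, 3], p = cf[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}
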