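#' Statistical contrasts
#'
#' Nonparametric OFF/ON contrasts (Wilcoxon signed-rank and rank-sum) with
#' Bonferroni correction, paired Cohen's d, linear and linear mixed models
#' for PLV and sensation ratings, and normality/outlier diagnostics.
#'
#' @name stats_layer
NULL

new_test_result <- function(statistic, W, p_raw, n_comparisons, side,
                            method) {
  structure(list(
    statistic = statistic, W = W, p_raw = p_raw,
    p_corrected = min(1, p_raw * n_comparisons),
    n_comparisons = n_comparisons, side = side, method = method
  ), class = "entrain_test")
}

#' @export
print.entrain_test <- function(x, ...) {
  cat(sprintf("%s (%s): Z = %.3f, p = %.4g (Bonferroni x%d: p = %.4g)\n",
              x$method, x$side, x$statistic, x$p_raw, x$n_comparisons,
              x$p_corrected))
  invisible(x)
}

signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  # tie-corrected variance of the signed-rank statistic
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  list(V = V, z = (V - mu) / sqrt(sig2), n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are discarded (Wilcoxon's rule). The p-value is exact
#' for n <= 25 without ties and uses the normal approximation otherwise;
#' the Z statistic from the normal approximation is always reported for
#' comparability across sample sizes. One-sided tests take
#' `side = "greater"` to mean `x > y` (e.g. ON entrainment above OFF).
#'
#' @param x,y Paired samples.
#' @param side "greater", "less" or "two.sided".
#' @param n_comparisons Bonferroni correction factor (corrected p capped
#'   at 1).
#' @return An `entrain_test` with `statistic` (Z), `W` (signed-rank V),
#'   `p_raw`, `p_corrected`.
#' @export
wilcoxon_signed_rank <- function(x, y, side = c("greater", "less",
                                                "two.sided"),
                                 n_comparisons = 1) {
  side <- match.arg(side)
  stopifnot(length(x) == length(y))
  d <- x - y
  if (all(d == 0))
    stop("all paired differences are zero; test degenerate", call. = FALSE)
  if (length(d[d != 0]) < 5)
    warning("fewer than 5 non-zero differences", call. = FALSE)
  sr <- signed_rank_z(d)
  ex <- sr$n <= 25 && !any(duplicated(abs(d[d != 0])))
  p <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           alternative = side, exact = ex,
                                           correct = FALSE))$p.value
  new_test_result(sr$z, sr$V, p, n_comparisons, side,
                  "Wilcoxon signed rank")
}

#' Unpaired Wilcoxon rank-sum test
#'
#' @param x,y Independent samples.
#' @inheritParams wilcoxon_signed_rank
#' @return An `entrain_test` with `statistic` (Z), `W` (rank-sum W),
#'   `p_raw`, `p_corrected`.
#' @export
wilcoxon_rank_sum <- function(x, y, side = c("greater", "less",
                                             "two.sided"),
                              n_comparisons = 1) {
  side <- match.arg(side)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- table(r)
  sig2 <- n * m / 12 *
    (n + m + 1 - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
  z <- (W - mu) / sqrt(sig2)
  ex <- n + m <= 50 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = side,
                                           exact = ex,
                                           correct = FALSE))$p.value
  new_test_result(z, W, p, n_comparisons, side, "Wilcoxon rank sum")
}

#' Paired Cohen's d
#'
#' Difference in means divided by the standard deviation of the paired
#' differences. Values above 0.8 are conventionally a large effect.
#'
#' @param x,y Paired samples.
#' @return Effect size d.
#' @export
cohens_d_paired <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  s <- stats::sd(d)
  if (s == 0)
    stop("zero variance of paired differences; d undefined", call. = FALSE)
  mean(d) / s
}

#' Linear (mixed) model for PLV or sensation ratings
#'
#' Fits the repeated-measures designs' models: fixed effects (optionally with all
#' two-way interactions among the given terms) and, when
#' `random_intercept` is `TRUE`, a random intercept per `group` (REML via
#' `lme4::lmer`, Wald normal-approximation p-values for the fixed effects).
#' With `random_intercept = FALSE` an ordinary linear model is fitted.
#'
#' Covered designs include `plv_dif ~ amplitude` (fixed only),
#' `plv_dif ~ amplitude * configuration` (fixed only),
#' `plv ~ amplitude * anesthesia + (1 | subject)` and
#' `plv ~ amplitude + (1 | subject)`.
#'
#' @param data Tidy data frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect column names.
#' @param interaction Include all interactions among `fixed`
#'   (`*` expansion)?
#' @param random_intercept Add `(1 | group)`?
#' @param group Grouping column for the random intercept.
#' @return A `plv_model_fit`: `coefficients` data frame (term, estimate,
#'   se, z, p), `random_variance` (subject-intercept variance or `NA`),
#'   `formula`, and the underlying `fit`.
#' @export
fit_plv_model <- function(data, response = "plv", fixed = "amplitude",
                          interaction = FALSE, random_intercept = FALSE,
                          group = "subject") {
  stopifnot(response %in% names(data), all(fixed %in% names(data)))
  rhs <- paste(fixed, collapse = if (interaction) " * " else " + ")
  if (random_intercept) {
    stopifnot(group %in% names(data))
    f <- stats::as.formula(
      paste(response, "~", rhs, "+ (1 |", group, ")"))
    fit <- lme4::lmer(f, data = data, REML = TRUE)
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    rv <- vc$vcov[vc$grp == group][1]
  } else {
    f <- stats::as.formula(paste(response, "~", rhs))
    fit <- stats::lm(f, data = data)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient design; aliased terms: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "), call. = FALSE)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    rv <- NA_real_
  }
  z <- est / se
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), z = unname(z),
                              p = unname(2 * stats::pnorm(-abs(z))),
                              row.names = NULL),
    random_variance = rv, formula = deparse(f), fit = fit
  ), class = "plv_model_fit")
}

#' @export
print.plv_model_fit <- function(x, ...) {
  cat("<plv_model_fit>", x$formula, "\n")
  print(x$coefficients, digits = 4)
  if (!is.na(x$random_variance))
    cat(sprintf("random-intercept variance: %.4g\n", x$random_variance))
  invisible(x)
}

#' Normality and outlier diagnostics
#'
#' One-sample Kolmogorov-Smirnov test of the standardized sample against
#' the standard normal, and a two-sided Grubbs test for a single outlier
#' (largest absolute deviation from the mean, referred to its
#' t-distribution bound).
#'
#' @param x Numeric sample (n >= 5 for KS, n >= 3 for Grubbs).
#' @param alpha Significance level for the outlier flag.
#' @return List with `ks_p`, `grubbs_statistic`, `grubbs_p`,
#'   `outlier` (flag), `outlier_index`, `degenerate` (constant sample).
#' @export
diagnostics <- function(x, alpha = 0.05) {
  n <- length(x)
  if (stats::sd(x) == 0)
    return(list(ks_p = NA_real_, grubbs_statistic = NA_real_,
                grubbs_p = NA_real_, outlier = FALSE,
                outlier_index = NA_integer_, degenerate = TRUE))
  ks_p <- if (n >= 5)
    suppressWarnings(stats::ks.test((x - mean(x)) / stats::sd(x),
                                    "pnorm"))$p.value
  else NA_real_
  if (n >= 3) {
    dev <- abs(x - mean(x))
    G <- max(dev) / stats::sd(x)
    # invert G -> t and bound the p-value (standard Grubbs relation)
    denom <- (n - 1)^2 / n - G^2
    if (denom <= 0) {
      g_p <- 0
    } else {
      t_stat <- sqrt((n - 2) * G^2 / denom)
      g_p <- min(1, 2 * n * stats::pt(t_stat, n - 2, lower.tail = FALSE))
    }
    out_idx <- which.max(dev)
  } else {
    G <- NA_real_; g_p <- NA_real_; out_idx <- NA_integer_
  }
  list(ks_p = ks_p, grubbs_statistic = G, grubbs_p = g_p,
       outlier = isTRUE(g_p < alpha), outlier_index = out_idx,
       degenerate = FALSE)
}
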