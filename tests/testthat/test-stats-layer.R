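test_that("signed-rank test gives the exact p for uniform positive shifts", {
  # 12 uniformly positive paired differences: one-sided exact p = 2^-12
  y <- (1:12) * 1.0
  x <- y + (1:12) / 10  # distinct positive differences
  res <- wilcoxon_signed_rank(x, y, "greater")
  expect_equal(res$p_raw, 2^-12)
  expect_lt(res$statistic * -1, 0)  # Z positive for x > y
  expect_error(wilcoxon_signed_rank(y, y), "zero")
})

test_that("Bonferroni correction multiplies and caps at 1", {
  x <- c(2, 3, 1, 5, 4, 6, 8, 7, 9, 11, 10, 12) + 0.25
  y <- as.numeric(1:12)
  r3 <- wilcoxon_signed_rank(x, y, "greater", n_comparisons = 3)
  expect_equal(r3$p_corrected, min(1, 3 * r3$p_raw))
  r_many <- wilcoxon_signed_rank(x, y, "two.sided", n_comparisons = 1e6)
  expect_equal(r_many$p_corrected, 1)
})

test_that("rank-sum test gives the exact p for separated groups", {
  # complete separation, n = m = 6: two-sided exact p = 2 / choose(12, 6)
  res <- wilcoxon_rank_sum(7:12 + 0.1, 1:6 + 0.1, "two.sided")
  expect_equal(res$p_raw, 2 / choose(12, 6))
  # identical groups: p near 1
  set.seed(2)
  z <- rnorm(8)
  expect_gt(wilcoxon_rank_sum(z, z, "two.sided")$p_raw, 0.9)
})

test_that("both Wilcoxon tests hold their type-I error near alpha", {
  set.seed(99)
  n_rep <- 2000
  rej_sr <- mean(vapply(1:n_rep, function(i) {
    d <- rnorm(12)
    wilcoxon_signed_rank(d, numeric(12), "two.sided")$p_raw < 0.05
  }, logical(1)))
  rej_rs <- mean(vapply(1:n_rep, function(i) {
    wilcoxon_rank_sum(rnorm(10), rnorm(10), "two.sided")$p_raw < 0.05
  }, logical(1)))
  expect_gt(rej_sr, 0.025); expect_lt(rej_sr, 0.075)
  expect_gt(rej_rs, 0.025); expect_lt(rej_rs, 0.075)
})

test_that("paired Cohen's d is the mean difference over the difference SD", {
  set.seed(12)
  y <- rnorm(30)
  d <- rnorm(30, 1, 1)
  expect_equal(cohens_d_paired(y + d, y), mean(d) / sd(d))
  expect_error(cohens_d_paired(c(3, 4, 5), c(1, 2, 3)), "zero variance")
  # a 1-SD shift gives d near 1 on average
  ds <- vapply(1:500, function(i) {
    a <- rnorm(12); cohens_d_paired(a + rnorm(12, 1, 1), a)
  }, numeric(1))
  expect_equal(mean(ds), 1, tolerance = 0.1)
})

test_that("mixed model recovers amplitude effects and subject variance", {
  set.seed(7)
  sim_study <- function() {
    subj <- rep(1:12, each = 9)
    amp <- rep(rep(0:2, each = 3), times = 12)
    b_subj <- rnorm(12, 0, 0.02)
    data.frame(subject = subj, amplitude = amp,
               plv = 0.10 + 0.05 * amp + b_subj[subj] + rnorm(108, 0, 0.03))
  }
  fits <- replicate(60, {
    f <- fit_plv_model(sim_study(), "plv", "amplitude",
                       random_intercept = TRUE, group = "subject")
    co <- f$coefficients[f$coefficients$term == "amplitude", ]
    c(covered = abs(co$estimate - 0.05) <= 1.96 * co$se,
      rv = f$random_variance)
  })
  expect_gte(mean(fits["covered", ]), 0.9)
  expect_lt(abs(mean(fits["rv", ]) - 0.02^2), 0.5 * 0.02^2)
})

test_that("zero random-effect variance reproduces the OLS fixed effects", {
  set.seed(3)
  d <- data.frame(subject = rep(1:10, each = 6),
                  amplitude = rep(0:2, 20))
  d$plv <- 0.2 + 0.04 * d$amplitude + rnorm(60, 0, 0.05)
  fm <- fit_plv_model(d, "plv", "amplitude", random_intercept = TRUE,
                      group = "subject")
  fo <- fit_plv_model(d, "plv", "amplitude", random_intercept = FALSE)
  expect_equal(fm$coefficients$estimate, fo$coefficients$estimate,
               tolerance = 0.02)
})

test_that("interaction designs expand and rank deficiency is diagnosed", {
  set.seed(4)
  d <- expand.grid(subject = 1:8, amplitude = 0:2,
                   configuration = c("fore", "hind"))
  d$plv_dif <- 0.05 * d$amplitude +
    0.03 * (d$configuration == "fore") * d$amplitude + rnorm(nrow(d), 0, 0.02)
  f <- fit_plv_model(d, "plv_dif", c("amplitude", "configuration"),
                     interaction = TRUE)
  expect_true(any(grepl(":", f$coefficients$term)))
  d$dup <- d$amplitude  # aliased predictor
  expect_error(fit_plv_model(d, "plv_dif", c("amplitude", "dup")),
               "rank-deficient")
})

test_that("model p-values are uniform under the null", {
  set.seed(15)
  ps <- vapply(1:80, function(i) {
    d <- data.frame(subject = rep(1:12, each = 6),
                    amplitude = rep(0:2, 24),
                    plv = rnorm(72, 0.2, 0.05))
    f <- fit_plv_model(d, "plv", "amplitude", random_intercept = TRUE,
                       group = "subject")
    f$coefficients$p[f$coefficients$term == "amplitude"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("diagnostics flag outliers and degenerate samples", {
  set.seed(8)
  x <- rnorm(100)
  d <- diagnostics(x)
  expect_gt(d$ks_p, 0.01)
  expect_false(d$outlier)
  xo <- c(rnorm(30), 10)
  do <- diagnostics(xo)
  expect_true(do$outlier)
  expect_equal(do$outlier_index, 31)
  expect_true(diagnostics(rep(1, 10))$degenerate)
  # normal samples pass the KS check in most seeds
  passes <- vapply(1:50, function(s) {
    set.seed(s); diagnostics(rnorm(100))$ks_p > 0.05
  }, logical(1))
  expect_gte(mean(passes), 0.9)
})
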