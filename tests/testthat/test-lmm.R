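balanced_data <- function(n_subj, factors, seed, subj_sd = 1, noise = 1,
                          effects = NULL) {
  set.seed(seed)
  d <- do.call(tidyr::expand_grid,
               c(list(subject = sprintf("S%03d", seq_len(n_subj))), factors))
  d$y <- rnorm(nrow(d), sd = noise) +
    rep(rnorm(n_subj, sd = subj_sd), each = nrow(d) / n_subj)
  if (!is.null(effects)) d$y <- d$y + effects(d)
  d
}

test_that("balanced within-subject designs get the exact residual df", {
  d <- balanced_data(30, list(category = c("neg", "neu"),
                              stimulation = c("tavns", "sham")), seed = 1)
  fit <- fit_lmm_ri(d, y ~ category * stimulation)
  td <- tidy(fit)
  within <- td$term != "(Intercept)"
  # N - n_subjects - (rank - 1) = 120 - 30 - 3 = 87
  expect_equal(td$df[within], rep(87, 3), tolerance = 1e-6)
  expect_equal(td$df[!within], 29, tolerance = 1e-6)

  d3 <- balanced_data(30, list(a = c("1", "2"), b = c("1", "2"),
                               c = c("1", "2")), seed = 2)
  fit3 <- fit_lmm_ri(d3, y ~ a * b * c)
  td3 <- tidy(fit3)
  expect_equal(td3$df[td3$term != "(Intercept)"], rep(203, 7),
               tolerance = 1e-6)
})

test_that("estimates, df and likelihoods agree with the reference fitter", {
  skip_if_not_installed("lmerTest")
  for (seed in c(3, 4)) {
    d <- balanced_data(12, list(a = c("x", "y"), b = c("u", "v")), seed = seed,
                       effects = function(d) 0.5 * (d$a == "x"))
    # make one dataset unbalanced by dropping rows (post-exclusion shape)
    if (seed == 4) d <- d[-c(2, 7, 8, 21), ]
    fit <- fit_lmm_ri(d, y ~ a * b)
    dd <- within(as.data.frame(d), { a <- factor(a); b <- factor(b) })
    ref <- lmerTest::lmer(
      y ~ a * b + (1 | subject), data = dd, REML = TRUE,
      contrasts = list(a = "contr.sum", b = "contr.sum")
    )
    rs <- coef(summary(ref))
    td <- tidy(fit)
    expect_equal(td$estimate, unname(rs[, "Estimate"]), tolerance = 1e-6)
    expect_equal(td$std.error, unname(rs[, "Std. Error"]), tolerance = 1e-6)
    expect_equal(td$df, unname(rs[, "df"]), tolerance = 1e-3)
    expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(ref))$vcov
    expect_equal(c(fit$sigma2_subject, fit$sigma2_resid), vc, tolerance = 1e-5)
  }
})

test_that("at the zero-variance boundary the fit collapses to least squares", {
  # find a replicate whose REML subject variance lands on the boundary
  fit <- NULL; d <- NULL
  for (seed in 1:20) {
    d <- balanced_data(40, list(a = c("x", "y"), b = c("u", "v")), seed = seed,
                       subj_sd = 0)
    fit <- fit_lmm_ri(d, y ~ a * b)
    if (fit$sigma2_subject == 0) break
  }
  expect_equal(fit$sigma2_subject, 0)
  dd <- within(as.data.frame(d), { a <- factor(a); b <- factor(b) })
  ols <- lm(y ~ a * b, data = dd,
            contrasts = list(a = "contr.sum", b = "contr.sum"))
  expect_equal(tidy(fit)$estimate, unname(coef(ols)), tolerance = 1e-8)
  # Satterthwaite still partitions df by stratum, as the reference fitter
  # does: within effects get N - n_subj - (rank - 1), the intercept n_subj - 1
  td <- tidy(fit)
  expect_equal(td$df[td$term != "(Intercept)"], rep(160 - 40 - 3, 3),
               tolerance = 1e-3)
  expect_equal(td$df[td$term == "(Intercept)"], 39, tolerance = 1e-3)
})

test_that("REML variance components are translation invariant", {
  d <- balanced_data(15, list(a = c("x", "y")), seed = 6)
  f1 <- fit_lmm_ri(d, y ~ a)
  d$y <- d$y + 1000
  f2 <- fit_lmm_ri(d, y ~ a)
  expect_equal(f1$sigma2_subject, f2$sigma2_subject, tolerance = 1e-6)
  expect_equal(f1$sigma2_resid, f2$sigma2_resid, tolerance = 1e-6)
  expect_equal(tidy(f1)$estimate[-1], tidy(f2)$estimate[-1], tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- balanced_data(8, list(a = c("x", "y")), seed = 7)
  d$z <- d$a # aliased column
  expect_error(fit_lmm_ri(d, y ~ a + z), "singular")
  d1 <- d[-1, ] # leaves one subject with a single observation
  expect_error(fit_lmm_ri(d1, y ~ a), "observations per subject")
})

test_that("BIC Bayes factors behave as evidence measures", {
  d <- balanced_data(12, list(a = c("x", "y")), seed = 8)
  f_alt <- fit_lmm_ri(d, y ~ a, reml = FALSE)
  expect_equal(bf10_bic(f_alt, f_alt)$bf10, 1)
  # strong effect (standardized paired difference 0.9) wins in >= 90%
  wins <- 0
  for (r in 1:20) {
    ds <- balanced_data(30, list(a = c("x", "y")), seed = 100 + r,
                        subj_sd = 0.5, noise = 1,
                        effects = function(d) 0.9 * sqrt(2) * (d$a == "x"))
    bf <- bf10_bic(fit_lmm_ri(ds, y ~ a), fit_lmm_ri(ds, y ~ 1))
    wins <- wins + (bf$bf10 > 3)
  }
  expect_gte(wins, 18)
  # absent effect: evidence leans to the null in most replicates
  nulls <- 0
  for (r in 1:20) {
    ds <- balanced_data(30, list(a = c("x", "y")), seed = 200 + r)
    bf <- bf10_bic(fit_lmm_ri(ds, y ~ a), fit_lmm_ri(ds, y ~ 1))
    nulls <- nulls + (bf$bf10 < 1)
  }
  expect_gt(nulls, 10)
})

test_that("Bayes-factor comparisons demand identical data and nesting", {
  d <- balanced_data(10, list(a = c("x", "y"), b = c("u", "v")), seed = 9)
  f_ab <- fit_lmm_ri(d, y ~ a * b)
  f_a <- fit_lmm_ri(d, y ~ a)
  expect_s3_class(bf10_bic(f_ab, f_a), "tbl_df")
  d2 <- d; d2$y <- d2$y + rnorm(nrow(d2))
  expect_error(bf10_bic(f_ab, fit_lmm_ri(d2, y ~ a)), "identical data")
  f_b <- fit_lmm_ri(d, y ~ b)
  expect_error(bf10_bic(f_a, f_b), "not nested")
})
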