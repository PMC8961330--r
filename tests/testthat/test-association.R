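test_that("wave averaging uses available waves and propagates all-missing", {
  expect_equal(aggregate_repeated_measures(c(10, 20, NA)), 15)
  expect_equal(aggregate_repeated_measures(7), 7)
  expect_true(is.na(aggregate_repeated_measures(c(NA, NA))))
  m <- rbind(c(1, 2, 3), c(NA, 4, NA), c(NA, NA, NA))
  expect_equal(aggregate_repeated_measures(m), c(2, 4, NA))
})

test_that("adjusted fit recovers exact and null associations", {
  set.seed(31)
  n <- 10000
  d <- data.frame(age = rnorm(n, 50, 10),
                  female = rbinom(n, 1, 0.6),
                  education_years = rnorm(n, 13, 3),
                  x = rnorm(n))
  d$y_null <- rnorm(n)
  d$y_exact <- d$x
  null_fit <- fit_adjusted(d, "y_null", "x")
  expect_lt(abs(null_fit$beta), 0.03)
  exact <- fit_adjusted(d, "y_exact", "x")
  expect_equal(exact$beta, 1, tolerance = 1e-10)
  expect_equal(exact$b, 1, tolerance = 1e-10)
  expect_lt(exact$p_raw, 1e-100)
  expect_true(exact$ci_low <= exact$b && exact$b <= exact$ci_high)
  expect_equal(exact$n_used, n)
})

test_that("without covariates the fit matches the textbook closed form", {
  set.seed(32)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  fit <- fit_adjusted(data.frame(x = x, y = y), "y", "x",
                      covariates = character(0))
  expect_equal(fit$b, cov(x, y) / var(x), tolerance = 1e-12)
  expect_equal(fit$beta, cor(x, y), tolerance = 1e-12)
})

test_that("simulation oracle: mean standardized estimate matches the truth", {
  set.seed(33)
  betas <- replicate(100, {
    n <- 5000
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, 0, sqrt(1 - 0.25))
    fit_adjusted(data.frame(x = x, y = y), "y", "x",
                 covariates = character(0))$beta
  })
  expect_lt(abs(mean(betas) - 0.5), 2 * sd(betas) / sqrt(100))
})

test_that("degenerate fits fail loudly", {
  d <- data.frame(y = rnorm(20), x = 1,
                  age = rnorm(20), female = rbinom(20, 1, 0.5),
                  education_years = rnorm(20))
  expect_error(fit_adjusted(d, "y", "x"), "constant")
  expect_error(fit_adjusted(d[1:5, ], "y", "x"), "complete cases")
  expect_error(fit_adjusted(d, "y", "missing_col"), "not found")
})

test_that("residualizing FLS on FH removes exactly the group means", {
  expect_equal(residualize(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               c(-0.5, 0.5, -0.5, 0.5), tolerance = 1e-12)
  # constant within group -> perfect fit, all-zero residuals
  expect_equal(residualize(c(2, 2, 5, 5), c(0, 0, 1, 1)), rep(0, 4),
               tolerance = 1e-12)
  set.seed(41)
  fls <- rnorm(500); fh <- rbinom(500, 1, 0.6)
  r <- residualize(fls, fh)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_lt(abs(cor(r, fh)), 1e-10)
  expect_error(residualize(fls, rep(1, 500)), "single level")
})

test_that("point-biserial equals Pearson under 0/1 coding", {
  expect_equal(point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4)), 2 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(point_biserial(c(0, 1, 0, 1), c(3, 3, 3.5, 3.5)),
               0, tolerance = 1e-12)
  expect_equal(point_biserial(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  set.seed(42)
  for (i in 1:25) {
    b <- rbinom(40, 1, 0.5); x <- rnorm(40)
    if (length(unique(b)) < 2) next
    expect_equal(point_biserial(b, x), pearson_cor(b, x),
                 tolerance = 1e-12)
  }
  expect_error(point_biserial(rep(0, 10), rnorm(10)), "degenerate")
  expect_error(point_biserial(c(0, 2, 1), 1:3), "0/1")
})

test_that("Pearson correlation behaves at its boundaries", {
  x <- rnorm(100)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  set.seed(43)
  expect_lt(abs(pearson_cor(rnorm(10000), rnorm(10000))), 0.03)
  expect_error(pearson_cor(rep(1, 10), rnorm(10)), "constant")
})

test_that("pooled t test uses N - 2 degrees of freedom", {
  expect_equal(pooled_t_test(c(1, 2), c(1, 2))$t, 0)
  tt <- pooled_t_test(rnorm(700), rnorm(725))
  expect_equal(tt$df, 1423)
  deg <- pooled_t_test(c(0, 0, 0), c(1, 1, 1))
  expect_true(deg$degenerate)
  expect_true(is.infinite(deg$t))
  expect_error(pooled_t_test(1, c(1, 2)), "n >= 2")
  # sign convention: first group minus second
  expect_lt(pooled_t_test(c(0, 1, 0, 1), c(5, 6, 5, 6))$t, 0)
})

test_that("2x2 chi-square without continuity correction matches knowns", {
  res <- chi_square_2x2(matrix(c(191, 57, 949, 476), 2, byrow = TRUE))
  expect_equal(round(res$chi2, 2), 10.56)
  expect_equal(res$df, 1)
  expect_equal(round(res$p, 3), 0.001)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_equal(chi_square_2x2(matrix(c(20, 10, 10, 20), 2))$chi2,
               20 / 3, tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_2x2(matrix(1, 3, 3)), "2x2")
})

test_that("BH step-up rejects per the sorted threshold rule", {
  res <- bh_fdr(c(0.001, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(res$reject)) # thresholds 0.0125/0.025/0.0375/0.05
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  expect_true(bh_fdr(0.04)$reject) # m = 1 reduces to p <= q
  expect_equal(res$p_raw, c(0.001, 0.02, 0.03, 0.04)) # raw p preserved
  expect_true(all(diff(sort(res$p_adjusted)) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with brute force and is monotone in q", {
  set.seed(55)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(bh_fdr(p, q)$reject, bh_brute_force(p, q))
    q2 <- q + 0.1
    expect_true(all(bh_fdr(p, q2)$reject >= bh_fdr(p, q)$reject))
  }
})

test_that("the full pipeline produces three adjusted models per outcome", {
  co <- generate_cohort(cohort_config(n_participants = 800, seed = 60))
  outs <- default_outcome_specs()$name
  an <- run_full_analysis(co$participants, outs)
  expect_equal(nrow(an$results), 3 * length(outs))
  expect_setequal(unique(an$results$exposure), c("fls", "fh", "fls_resid"))
  expect_true(all(an$results$ci_low <= an$results$b &
                    an$results$b <= an$results$ci_high))
  expect_true(all(an$results$p_raw >= 0 & an$results$p_raw <= 1))
  expect_true(all(an$results$n_used <= 800))
  # correlation summary direction: FH+ group has the higher mean FLS
  expect_lt(an$correlations$t_fls_by_fh$t, 0)
  expect_gt(an$correlations$r_fh_fls, 0.3)
  expect_equal(an$correlations$t_fls_by_fh$df, 798)
  # global family is at least as conservative per test as per-exposure m
  an_g <- run_full_analysis(co$participants, outs, bh_family = "global")
  expect_equal(nrow(an_g$results), nrow(an$results))
})

test_that("residualized-FLS coefficients ignore constant shifts of FLS", {
  co <- generate_cohort(cohort_config(n_participants = 600, seed = 61))
  outs <- c("rumination", "childhood_trauma")
  a1 <- run_full_analysis(co$participants, outs)
  shifted <- co$participants
  shifted$fls <- shifted$fls + 5
  a2 <- run_full_analysis(shifted, outs)
  i <- a1$results$exposure == "fls_resid"
  expect_equal(a1$results$beta[i], a2$results$beta[i], tolerance = 1e-10)
  expect_equal(a1$results$b[i], a2$results$b[i], tolerance = 1e-10)
})

test_that("partial standardization leaves binary exposures on the 0/1 scale", {
  co <- generate_cohort(cohort_config(n_participants = 600, seed = 62))
  full <- fit_adjusted(co$participants, "rumination", "fh")
  part <- fit_adjusted(co$participants, "rumination", "fh",
                       full_standardization = FALSE)
  expect_equal(full$b, part$b) # raw scale untouched
  expect_false(isTRUE(all.equal(full$beta, part$beta)))
  sd_fh <- sd(co$participants$fh)
  sd_y <- sd(co$participants$rumination)
  expect_equal(part$beta, part$b / sd_y, tolerance = 1e-10)
  expect_equal(full$beta, part$b * sd_fh / sd_y, tolerance = 1e-10)
})
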