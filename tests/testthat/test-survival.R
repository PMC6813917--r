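test_that("Kaplan-Meier equals the empirical survival under zero censoring", {
  set.seed(6)
  for (rep in 1:5) {
    t <- round(rexp(30, 0.2) + 0.01, 3)
    km <- km_logrank(t, rep(1, 30))
    for (i in seq_len(nrow(km$curves)))
      expect_equal(km$curves$surv[i], empirical_surv(t, km$curves$time[i]),
                   tolerance = 1e-12)
  }
})

test_that("the hand-computed four-subject product-limit example matches", {
  expect_message(km <- km_logrank(c(1, 2, 3, 4), c(1, 1, 0, 1)), "single group")
  expect_equal(km$curves$surv, c(0.75, 0.5, 0.5, 0))
  expect_equal(km$curves$n_risk, c(4, 3, 2, 1))
  expect_null(km$logrank)
})

test_that("log-rank is exactly null on identical groups and valid otherwise", {
  t <- c(1, 2, 3, 4, 5); e <- c(1, 0, 1, 1, 1)
  km <- km_logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(km$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(km$logrank$p, 1, tolerance = 1e-12)
  expect_equal(km$logrank$df, 1L)
  expect_error(km_logrank(c(-1, 2), c(1, 1)), "positive")
  expect_error(km_logrank(c(1, 2), c(0, 0)), "event")
})

test_that("Cox coefficients match brute-force partial-likelihood maximization", {
  fixtures <- list(
    list(t = c(1, 2, 3, 4, 5, 6), e = c(1, 0, 1, 1, 0, 1),
         x = c(1, 1, 0, 1, 0, 0)),
    list(t = c(2.3, 1.1, 4.5, 3.3, 5.9), e = c(1, 1, 1, 0, 1),
         x = c(0, 1, 1, 0, 0)),
    list(t = c(0.5, 1.5, 2.5, 3.5), e = c(1, 1, 1, 1),
         x = c(0.2, 0.8, 0.1, 0.9)),
    list(t = c(1, 3, 2, 6, 5, 4), e = c(0, 1, 1, 0, 1, 1),
         x = c(0.1, 0.9, 0.4, 0.2, 0.7, 0.3)))
  for (fx in fixtures) {
    rec <- data.frame(time = fx$t, event = fx$e, fib_frac = fx$x / 10)
    fit <- cox_fit(rec, class_covariates = "fib_frac")
    oracle <- cox_brute_force(fx$t, fx$e, fx$x)
    expect_lt(abs(fit$table$coef[1] - oracle), 1e-4)
    expect_equal(fit$table$hazard_ratio[1], exp(fit$table$coef[1]))
    expect_true(fit$table$ci95_low[1] <= fit$table$hazard_ratio[1])
    expect_true(fit$table$ci95_high[1] >= fit$table$hazard_ratio[1])
  }
})

test_that("a null covariate shows no effect at n = 500", {
  d <- sim_null_cox(500, seed = 41)
  f <- cox_fit(d, class_covariates = "fib_frac")
  expect_lt(abs(f$table$coef[1]) / f$table$se[1], 3)
})

test_that("Cox guards: separation, no events, constants, Gleason reference", {
  sep <- data.frame(time = c(1, 2, 3, 4, 5), event = c(1, 1, 1, 0, 0),
                    fib_frac = c(0.1, 0.1, 0.1, 0, 0))
  expect_error(suppressWarnings(cox_fit(sep, class_covariates = "fib_frac")),
               "separation|monotone")
  none <- data.frame(time = 1:4, event = rep(0, 4), fib_frac = runif(4))
  expect_error(cox_fit(none, class_covariates = "fib_frac"), "event")
  d <- sim_null_cox(60, seed = 42)
  d$gleason_group <- sample(c("lt7", "eq7", "gt7"), 60, replace = TRUE)
  d$age <- rnorm(60, 65, 5)
  f <- cox_fit(d, class_covariates = "fib_frac",
               adjust = c("gleason_group", "age"))
  # reference level gt7 absent from the coefficient table
  expect_true(all(c("gleason_grouplt7", "gleason_groupeq7") %in% f$table$term))
  expect_false("gleason_groupgt7" %in% f$table$term)
  d$const <- 1
  expect_warning(cox_fit(d, class_covariates = "fib_frac", adjust = "const"),
                 "constant")
  # class covariate must be a fraction
  d$bad <- runif(60, 5, 10)
  expect_error(cox_fit(d, class_covariates = "bad"), "fraction")
})

test_that("complete-case filtering is applied and reported", {
  d <- sim_null_cox(50, seed = 43)
  d$age <- rnorm(50); d$age[1:5] <- NA
  f <- cox_fit(d, class_covariates = "fib_frac", adjust = "age")
  expect_equal(f$n_excluded, 5L)
  expect_equal(f$n, 45L)
})

test_that("Schoenfeld test requires events and reports per-covariate p", {
  d <- sim_null_cox(100, seed = 44)
  f <- cox_fit(d, class_covariates = "fib_frac")
  z <- schoenfeld_test(f)
  expect_equal(z$term, "fib_frac_x10")
  expect_true(is.finite(z$p))
  few <- data.frame(time = c(1, 2, 3), event = c(1, 0, 0),
                    fib_frac = c(0.05, 0, 0.1))
  f2 <- cox_fit(few, class_covariates = "fib_frac")
  expect_error(schoenfeld_test(f2), "insufficient events")
})

test_that("BH step-up matches the worked example and the exhaustive oracle", {
  bh <- bh_adjust(c(0.01, 0.02, 0.03, 0.5), q = 0.2)
  expect_equal(bh$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh$n_rejected, 3L)
  expect_equal(bh_adjust(rep(1, 5), q = 0.2)$n_rejected, 0L)
  expect_true(bh_adjust(0.19, q = 0.2)$reject)
  expect_false(bh_adjust(0.21, q = 0.2)$reject)
  set.seed(7)
  for (rep in 1:100) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    q <- runif(1, 0.05, 0.4)
    bh <- bh_adjust(p, q)
    expect_identical(bh$reject, bh_oracle(p, q))
    # agreement with the adjusted-p route
    expect_identical(bh$reject, unname(bh$adjusted <= q))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(0.5, q = 1.5), "q must")
})

test_that("BH rejection sets are monotone in the FDR level", {
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(10)
    r1 <- bh_adjust(p, q = 0.1)$reject
    r2 <- bh_adjust(p, q = 0.25)$reject
    expect_true(all(r2[r1]))
  }
})

test_that("group comparisons delegate to the standard tests", {
  # chi-square without continuity correction matches the textbook formula
  v <- rep(c("x", "y"), c(30, 30))
  g <- c(rep(c("a", "b"), c(20, 10)), rep(c("a", "b"), c(10, 20)))
  res <- compare_groups(v, g, test = "chi_square")
  expect_equal(res$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-12)
  # perfectly correlated data
  x <- 1:20
  expect_equal(compare_groups(x, test = "pearson", y = 2 * x + 3)$statistic, 1)
  # Mann-Whitney two-group guard and Kruskal-Wallis + Dunn
  expect_error(compare_groups(rnorm(9), rep(c("a", "b", "c"), 3),
                              test = "mann_whitney"), "2 groups")
  set.seed(10)
  vals <- c(rnorm(20), rnorm(20) + 3, rnorm(20))
  grp <- rep(c("a", "b", "c"), each = 20)
  kw <- compare_groups(vals, grp, test = "kruskal_wallis_dunn")
  expect_lt(kw$p, 0.05)
  expect_s3_class(kw$pairwise, "data.frame")
  expect_equal(nrow(kw$pairwise), 3L)
  # the b-vs-others contrasts dominate
  pw <- kw$pairwise
  expect_lt(pw$p_adj[pw$group1 == "a" & pw$group2 == "b"], 0.05)
})

test_that("Mann-Whitney p-values are calibrated under the null", {
  set.seed(12)
  rej <- 0
  for (rep in 1:200) {
    v <- rnorm(60)
    g <- rep(c("a", "b"), 30)
    rej <- rej + (compare_groups(v, g, test = "mann_whitney")$p < 0.05)
  }
  expect_gte(rej / 200, 0.02)
  expect_lte(rej / 200, 0.08)
})
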