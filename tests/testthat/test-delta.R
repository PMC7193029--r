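test_that("generalized variances match hand arithmetic", {
  # W1* = (1, -1, 0), W2* = (1, 1, 0), one stratum:
  # det(Sigma) = 2*2 - 0 = 4; centered: 2 * (2 - 4/3) - 0 = 4/3
  pr <- pseudo_r2(c(1, -1, 0), c(1, 1, 0))
  expect_equal(pr$det_null, 4)
  expect_equal(pr$det_alt, 4 / 3)
  expect_equal(pr$delta, (4 - 4 / 3) / 4)
  expect_false(pr$clipped)
  expect_equal(pr$K, 3)

  # stratum means already zero: centering is a no-op, Delta = 0
  pr0 <- pseudo_r2(c(1, -1, 2, -2), c(1, 1, -1, -1))
  expect_equal(pr0$det_alt, pr0$det_null)
  expect_equal(pr0$delta, 0)

  # a singleton stratum contributes nothing to the centered sums
  pr1 <- pseudo_r2(c(1, -1, 0, 5), c(1, 1, 0, -3),
                   stratum = c(1, 1, 1, 2))
  expect_equal(pr1$det_alt, 4 / 3 + 0)   # only stratum 1 contributes... to a11/a22 parts
  expect_equal(pr1$k_by_stratum[["2"]], 1L)
})

test_that("degenerate generalized variances are refused", {
  expect_error(pseudo_r2(c(1, -1, 0), c(0, 0, 0)), "not positive")
  expect_error(pseudo_r2(c(1, -1, 2), 2 * c(1, -1, 2)), "not positive")
  expect_error(pseudo_r2(c(1, -1), c(1, 1)), "at least 3")
})

test_that("Delta stays in [0, 1] and the clipping rule is consistent", {
  # det(Sigma*) <= det(Sigma) holds exactly (subtracting a PSD mean matrix),
  # so clipping can only ever absorb floating-point noise; check the rule
  # and the range over random configurations
  for (s in 1:100) {
    set.seed(s)
    w1 <- rnorm(6); w2 <- rnorm(6)
    pr <- try(pseudo_r2(w1, w2, stratum = c(1, 1, 1, 2, 2, 2)),
              silent = TRUE)
    if (inherits(pr, "try-error")) next
    expect_gte(pr$delta, 0)
    expect_lte(pr$delta, 1)
    expect_lte(pr$det_alt, pr$det_null + 1e-12 * pr$det_null)
    expect_equal(pr$clipped, pr$delta_raw < 0 || pr$delta_raw > 1)
    expect_equal(pr$delta, min(max(pr$delta_raw, 0), 1))
  }
})

test_that("vectorized pipeline equals the literal double-loop transcription", {
  for (s in 1:20) {
    n <- sample(6:12, 1)
    co <- rand_cohort(n, seed = 600 + s, p_event = 0.8,
                      ties = s %% 3 == 0, n_strata = 1 + s %% 2)
    ok <- all(tapply(co$event, co$stratum, sum) >= 1) && sum(co$event) >= 3
    if (!ok) next
    fit <- survdelta:::.delta_fit(co$time, co$event, co$z,
                                  stratum = co$stratum)
    expect_equal(fit$delta, brute_delta(co$time, co$event, co$z, co$stratum),
                 tolerance = 1e-12)
  }
})

test_that("Delta is invariant to affine transformations of the marker", {
  co <- simulate_cohort(400, tail_defect = 0.5, beta = log(2), seed = 20)
  f0 <- survdelta:::.delta_fit(co$followup_age, co$event, co$marker)
  f1 <- survdelta:::.delta_fit(co$followup_age, co$event, 2 * co$marker + 5)
  f2 <- survdelta:::.delta_fit(co$followup_age, co$event, -0.3 * co$marker)
  expect_lt(abs(f0$delta - f1$delta), 1e-8)
  expect_lt(abs(f0$delta - f2$delta), 1e-8)
})

test_that("the formula interface reproduces the internal pipeline and handles strata", {
  co <- simulate_cohort(300, tail_defect = 0.5, alpha = log(1.5),
                        n_strata = 2, seed = 21)
  fit <- delta_r2(survival::Surv(followup_age, event) ~ marker +
                    strata(stratum), data = co)
  ref <- survdelta:::.delta_fit(co$followup_age, co$event, co$marker,
                                stratum = co$stratum)
  expect_equal(fit$delta, ref$delta)
  expect_equal(sort(as.integer(fit$k_by_stratum)),
               sort(as.integer(ref$k_by_stratum)))

  # counting-process response with zero entry ages equals the right-censored fit
  fit2 <- delta_r2(survival::Surv(entry_age, followup_age, event) ~ marker +
                     strata(stratum), data = co, delayed_entry = FALSE)
  expect_equal(fit2$delta, fit$delta)

  expect_error(delta_r2(survival::Surv(followup_age, event) ~ marker +
                          entry_age, data = co), "exactly one marker")
})

test_that("fit objects print, summarise, and expose residuals and a plot", {
  co <- simulate_cohort(300, tail_defect = 0.7, beta = log(2.5), seed = 22)
  fit <- delta_r2(survival::Surv(followup_age, event) ~ marker, data = co)
  expect_output(print(fit), "pseudo-R2")
  expect_output(print(summary(fit)), "Per-stratum")
  r <- residuals(fit)
  expect_equal(dim(r), c(300L, 2L))
  rs <- residuals(fit, event_only = TRUE)
  expect_equal(nrow(rs), fit$K)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
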