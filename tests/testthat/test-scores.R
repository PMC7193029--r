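# A stratum_null object with prescribed values, for direct weight checks.
fake_null <- function(surv_left, cumhaz0, theta_hat) {
  structure(list(table = data.frame(time = seq_along(surv_left),
                                    n_event = 1,
                                    n_risk = length(surv_left):1,
                                    surv_left = surv_left,
                                    cumhaz0 = cumhaz0),
                 theta_hat = theta_hat,
                 tail_defect_hat = exp(-theta_hat)),
            class = "stratum_null")
}

test_that("weights match their closed forms, including the w2 sign change", {
  # first event age: S = 1, Lambda0 = 0 forces w2 = 1
  w <- score_weights(fake_null(1, 0, 0.3567))
  expect_equal(w$w2, 1)
  expect_equal(w$w1, exp(-0.3567) * 0.3567)

  # defect 0.7, S = 1: w1 = 0.7 * theta
  th <- -log(0.7)
  w <- score_weights(fake_null(1, 0, th))
  expect_equal(w$w1, 0.7 * th, tolerance = 1e-12)

  # defect 0.7, Lambda0 = 2, S = 0.7406: w2 is negative
  w <- score_weights(fake_null(0.7406, 2, th))
  expect_equal(w$w2, (0.7 * (1 - exp(-2) - 2) + exp(-2)) / 0.7406)
  expect_lt(w$w2, -0.89 + 0.001)
  expect_gt(w$w1, 0)

  expect_error(score_weights(fake_null(0, 1, th)), "undefined")
})

test_that("raw scores reduce to the weighted risk-set-mean bracket", {
  # two subjects z = {1, 0}, event for subject 1 at the earliest age:
  # w2(a1) = 1 so U2 = 1 * (1 - 1/2) = 0.5
  st <- score_table(time = c(1, 2), event = c(1, 0), marker = c(1, 0))
  expect_equal(st$U2[1], 0.5)
  expect_equal(st$U1[1], st$w1[1] * 0.5)
  expect_equal(st$U1[2], 0)   # censored subjects carry no raw score
  expect_equal(st$U2[2], 0)

  # all markers equal: centering kills every score and every shift
  st <- score_table(time = 1:5, event = c(1, 1, 0, 1, 0),
                    marker = rep(2.5, 5))
  expect_lt(max(abs(st[, c("U1", "U2", "W1", "W2")])), 1e-12)

  # single subject: self-only risk set
  st <- score_table(time = 3, event = 1, marker = 1.7)
  expect_equal(st$U1, 0)
  expect_equal(st$W1, 0)
})

test_that("the three algebraic forms of the raw scores agree to 1e-10", {
  for (s in 1:100) {
    co <- rand_cohort(50, seed = 100 + s, ties = s %% 4 == 0)
    if (sum(co$event) < 2) next
    a <- score_table(co$time, co$event, co$z, form = "reduced")
    b <- score_table(co$time, co$event, co$z, form = "weighted")
    d <- score_table(co$time, co$event, co$z, form = "separability")
    expect_lt(max(abs(a$U1 - b$U1), abs(a$U2 - b$U2)), 1e-10)
    expect_lt(max(abs(a$U1 - d$U1), abs(a$U2 - d$U2)), 1e-10)
  }
})

test_that("shifts vanish for subjects censored before the first event age", {
  st <- score_table(time = c(0.5, 1, 2), event = c(0, 1, 1),
                    marker = c(3, 1, -1))
  expect_equal(st$shift1[1], 0)
  expect_equal(st$shift2[1], 0)
  expect_equal(st$W1[1], 0)
})

test_that("with unit weights the shifted scores are the Cox score residuals at beta = 0", {
  for (s in 1:20) {
    co <- rand_cohort(sample(20:80, 1), seed = 200 + s, ties = s %% 3 == 0)
    if (sum(co$event) < 3) next
    est <- null_estimates(co$time, co$event)
    sc <- survdelta:::.score_stratum(co$time, co$event, co$z, est = est,
                                     weights = list(w1 = 1, w2 = 1))
    fit <- survival::coxph(survival::Surv(time, event) ~ z, data = co,
                           init = 0, ties = "breslow",
                           control = survival::coxph.control(iter.max = 0))
    ref <- as.vector(residuals(fit, type = "score"))
    expect_lt(max(abs(sc$W1 - ref)), 1e-8)
    expect_lt(max(abs(sc$W2 - ref)), 1e-8)
  }
})

test_that("scores are translation-invariant and scale linearly in the marker", {
  co <- rand_cohort(60, seed = 301)
  a <- score_table(co$time, co$event, co$z)
  b <- score_table(co$time, co$event, co$z + 100)
  expect_equal(a$U1, b$U1, tolerance = 1e-9)
  expect_equal(a$W2, b$W2, tolerance = 1e-9)
  d <- score_table(co$time, co$event, 3 * co$z)
  expect_equal(3 * a$U1, d$U1, tolerance = 1e-10)
  expect_equal(3 * a$W1, d$W1, tolerance = 1e-10)
  expect_equal(3 * a$W2, d$W2, tolerance = 1e-10)
})

test_that("shifted scores at event times have mean zero under the null", {
  reps <- 500
  m1 <- m2 <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- simulate_cohort(200, tail_defect = 0.5, seed = 5000 + r)
    st <- score_table(co$followup_age, co$event, co$marker)
    ev <- st[st$event == 1, ]
    m1[r] <- mean(ev$W1)
    m2[r] <- mean(ev$W2)
  }
  expect_lt(abs(mean(m1)), 3 * sd(m1) / sqrt(reps))
  expect_lt(abs(mean(m2)), 3 * sd(m2) / sqrt(reps))
})

test_that("event restriction keeps one row per event and demands at least 3", {
  co <- rand_cohort(40, seed = 400, n_strata = 4)
  st <- score_table(co$time, co$event, co$z, stratum = co$stratum)
  ev <- event_scores(st)
  expect_equal(nrow(ev), sum(co$event))
  expect_equal(sum(attr(ev, "k_by_stratum")), attr(st, "K"))

  # an all-censored stratum contributes no rows but raises no error
  co2 <- data.frame(time = c(1, 2, 3, 4, 1.5, 2.5),
                    event = c(1, 1, 1, 1, 0, 0),
                    z = c(0.3, -1, 2, 0.5, 1, -2),
                    stratum = c(1, 1, 1, 1, 2, 2))
  st2 <- score_table(co2$time, co2$event, co2$z, stratum = co2$stratum)
  ev2 <- event_scores(st2)
  expect_equal(nrow(ev2), 4)
  expect_false("2" %in% ev2$stratum)

  st3 <- score_table(c(1, 2, 3), c(1, 1, 0), c(0.3, -1, 2))
  expect_error(event_scores(st3), "at least 3")
})
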