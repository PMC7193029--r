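#' Simulate a cohort from the two-component mixture survival model
#'
#' Generates subject records from a two-part ("cure") survival model in which
#' a subject with marker value \eqn{z} is non-susceptible to the event with
#' probability \eqn{\exp(-\theta e^{\alpha z})} and, when susceptible, fails
#' with conditional cumulative hazard \eqn{\Lambda_0(t) e^{\beta z}}.  Two
#' conditional families are available:
#'
#' * `"exponential"`: the two-part model with \eqn{\Lambda_0(t) = t}, i.e.
#'   unit-exponential baseline event times among susceptible subjects.
#' * `"gompertz"`: an improper Gompertz law with overall survival
#'   \eqn{S(s \mid z) = \exp\{-\theta e^{\alpha z} (1 - e^{-s e^{\beta z}})\}},
#'   used to probe robustness to misspecification of the working model.
#'
#' The marker is drawn from a standard normal distribution or from a Student
#' t distribution with 10 degrees of freedom.  When `censor_fraction > 0`,
#' censoring times are drawn independently as Uniform(0, u), with the bound
#' `u` calibrated (see [censoring_bound()]) so that the expected fraction of
#' *susceptible* subjects censored before their event equals
#' `censor_fraction`; the non-susceptible fraction is not counted as
#' censoring in that calibration.  Non-susceptible subjects are recorded as
#' censored at `u`, or, in uncensored designs, at an administrative horizon
#' equal to 1.01 times the largest susceptible event time.
#'
#' All draws come from R's default Mersenne-Twister generator; when `seed`
#' is supplied the generator state is set locally and restored on exit, and
#' the cohort is fully reproducible.
#'
#' @param n Number of subjects (>= 2).
#' @param tail_defect Baseline probability \eqn{\exp(-\theta)} of being
#'   non-susceptible, in (0, 1).
#' @param alpha Log hazard ratio of the marker on the propensity of being
#'   susceptible (propensity effect).
#' @param beta Log hazard ratio of the marker on the event dynamic among
#'   susceptible subjects (dynamic effect).
#' @param covariate Marker law: `"normal"` (standard normal) or `"student"`
#'   (t with 10 df).
#' @param family Conditional survival family, `"exponential"` or
#'   `"gompertz"` (see Details).
#' @param censor_fraction Target fraction in [0, 1) of censored observations
#'   among susceptible subjects.
#' @param n_strata 1 or 2; with 2, a Bernoulli(0.5) stratum label is drawn
#'   and the same model parameters apply in both strata.
#' @param censor_bound Optional precomputed Uniform censoring bound `u`;
#'   computed via [censoring_bound()] when `NULL` and `censor_fraction > 0`.
#' @param horizon Optional administrative horizon for uncensored designs;
#'   defaults to 1.01 times the largest susceptible event time.
#' @param seed Optional integer seed.
#'
#' @return A `data.frame` with one row per subject and columns `entry_age`
#'   (0 in simulated designs), `followup_age`, `event` (0/1), `marker` and
#'   `stratum`.
#'
#' @examples
#' co <- simulate_cohort(500, tail_defect = 0.7, alpha = 0, beta = log(2.5),
#'                       seed = 1)
#' mean(co$event)  # close to 1 - 0.7
#' @seealso [censoring_bound()], [delta_r2()]
#' @export
simulate_cohort <- function(n, tail_defect, alpha = 0, beta = 0,
                            covariate = c("normal", "student"),
                            family = c("exponential", "gompertz"),
                            censor_fraction = 0, n_strata = 1,
                            censor_bound = NULL, horizon = NULL,
                            seed = NULL) {
  covariate <- match.arg(covariate)
  family <- match.arg(family)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single integer >= 2")
  if (!is.numeric(tail_defect) || tail_defect <= 0 || tail_defect >= 1)
    stop("'tail_defect' must lie strictly between 0 and 1")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("'censor_fraction' must lie in [0, 1)")
  if (!n_strata %in% c(1, 2))
    stop("'n_strata' must be 1 or 2")

  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }

  n <- as.integer(n)
  theta <- -log(tail_defect)
  z <- .draw_marker(n, covariate)
  theta_z <- theta * exp(alpha * z)
  p_ns <- exp(-theta_z)
  susceptible <- runif(n) > p_ns

  time <- rep(Inf, n)
  if (any(susceptible)) {
    u01 <- runif(sum(susceptible))
    time[susceptible] <- .conditional_event_time(
      u01, z[susceptible], theta_z[susceptible], beta, family)
  }

  if (censor_fraction > 0) {
    if (is.null(censor_bound))
      censor_bound <- censoring_bound(tail_defect, alpha = alpha, beta = beta,
                                      covariate = covariate, family = family,
                                      censor_fraction = censor_fraction)
    cc <- runif(n, 0, censor_bound)
    followup <- ifelse(susceptible, pmin(time, cc), censor_bound)
    event <- as.integer(susceptible & time <= cc)
  } else {
    if (is.null(horizon))
      horizon <- if (any(susceptible)) 1.01 * max(time[susceptible]) else 1
    followup <- ifelse(susceptible, time, horizon)
    event <- as.integer(susceptible)
  }

  stratum <- if (n_strata == 2L) rbinom(n, 1L, 0.5) + 1L else rep(1L, n)
  data.frame(entry_age = 0, followup_age = followup, event = event,
             marker = z, stratum = stratum)
}

#' Uniform censoring bound attaining a target censoring fraction
#'
#' Finds the upper bound `u` of a Uniform(0, u) censoring law such that the
#' expected fraction of susceptible subjects censored before their event
#' equals `censor_fraction`.  Following the convention of the simulation
#' design, the censoring percentage refers to censored observations among
#' susceptible subjects only, excluding the non-susceptible fraction.
#'
#' The censoring probability \eqn{P(C < T)} with \eqn{C \sim U(0, u)} equals
#' \eqn{E[\min(T/u, 1)]} over the susceptible conditional event-time law,
#' marginalised over the marker.  The expectation is estimated once by Monte
#' Carlo (importance weights proportional to the susceptibility probability)
#' and the monotone-decreasing root in `u` is found by bisection/uniroot on
#' that fixed sample, so the result is deterministic given `n_mc` and `seed`.
#'
#' @inheritParams simulate_cohort
#' @param n_mc Monte-Carlo sample size for the censoring-probability
#'   estimate (default 1e5; the resulting bound is accurate to well within
#'   0.005 on the censoring-fraction scale).
#' @param seed Optional integer seed for the Monte-Carlo sample; when `NULL`
#'   draws come from (and advance) the current generator state.
#' @return The positive bound `u`.
#' @examples
#' censoring_bound(0.7, censor_fraction = 0.2, n_mc = 2e4, seed = 1)
#' @export
censoring_bound <- function(tail_defect, alpha = 0, beta = 0,
                            covariate = c("normal", "student"),
                            family = c("exponential", "gompertz"),
                            censor_fraction, n_mc = 1e5, seed = NULL) {
  covariate <- match.arg(covariate)
  family <- match.arg(family)
  if (missing(censor_fraction) || censor_fraction <= 0)
    stop("'censor_fraction' must be > 0; no bound is defined at 0")
  if (censor_fraction >= 1)
    stop("'censor_fraction' must be < 1")
  if (tail_defect <= 0 || tail_defect >= 1)
    stop("'tail_defect' must lie strictly between 0 and 1")

  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }

  theta <- -log(tail_defect)
  z <- .draw_marker(n_mc, covariate)
  theta_z <- theta * exp(alpha * z)
  w <- -expm1(-theta_z)                     # susceptibility probability
  tt <- .conditional_event_time(runif(n_mc), z, theta_z, beta, family)
  sw <- sum(w)

  p_cens <- function(u) sum(w * pmin(tt / u, 1)) / sw
  lo <- 1e-8
  hi <- max(tt) + 1
  while (p_cens(hi) > censor_fraction) hi <- hi * 2
  uniroot(function(u) p_cens(u) - censor_fraction, c(lo, hi),
          tol = 1e-8)$root
}

# Event time of a susceptible subject given a Uniform(0,1) draw.
# exponential: cumulative hazard t * exp(beta z).
# gompertz: inverse CDF of the normalised conditional law hidden inside the
# improper survival exp(-theta_z (1 - exp(-s e^{beta z}))).
.conditional_event_time <- function(u01, z, theta_z, beta, family) {
  ebz <- exp(beta * z)
  if (family == "exponential") {
    -log(u01) / ebz
  } else {
    p <- exp(-theta_z)
    v <- p + (1 - p) * u01       # overall survival level at the drawn time
    inner <- -log(v) / theta_z   # = 1 - exp(-T e^{beta z}), in (0, 1)
    -log1p(-inner) / ebz
  }
}

.draw_marker <- function(n, covariate) {
  if (covariate == "normal") rnorm(n) else rt(n, df = 10)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Read or write a cohort table
#'
#' Cohorts are exchanged as delimited text with header columns `entry_age`,
#' `followup_age`, `event`, `marker`, `stratum` (the format written by
#' [simulate_cohort()]).
#'
#' @param path File path.
#' @param data Cohort `data.frame`.
#' @return `read_cohort()` returns the validated `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path)
  need <- c("entry_age", "followup_age", "event", "marker", "stratum")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file is missing columns: ", paste(miss, collapse = ", "))
  if (!all(d$event %in% c(0, 1))) stop("'event' must be 0/1")
  if (any(d$followup_age < d$entry_age))
    stop("'followup_age' must be >= 'entry_age'")
  d
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}
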