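#' Score-component weights at the event ages of a stratum
#'
#' Evaluates the two weight functions of the null score components at each
#' distinct event age \eqn{a_i}, using the left-continuous null estimates:
#' \deqn{w_1(a) = e^{-\hat\theta}\,\hat\theta \, / \, \hat S(a-)}
#' \deqn{w_2(a) = [e^{-\hat\theta}(1 - e^{-\hat\Lambda_0(a-)} -
#'   \hat\Lambda_0(a-)) + e^{-\hat\Lambda_0(a-)}] \, / \, \hat S(a-)}
#' \eqn{w_1} weights the propensity component and is always positive;
#' \eqn{w_2} weights the dynamic component and turns negative once the
#' baseline cumulative hazard is large with a substantial tail defect — the
#' formula is applied literally, with no flooring, since the pseudo-R2 uses
#' squared and cross terms only.
#'
#' @param est A `"stratum_null"` object from [null_estimates()].
#' @return A `data.frame` with columns `time`, `w1`, `w2`.
#' @examples
#' est <- null_estimates(c(1, 2, 3), c(1, 0, 1))
#' score_weights(est)   # w2 = 1 at the first event age
#' @export
score_weights <- function(est) {
  stopifnot(inherits(est, "stratum_null"))
  s <- est$table$surv_left
  if (any(s <= 0))
    stop("left-continuous survival is 0 at an event age; weights undefined")
  l0 <- est$table$cumhaz0
  p <- exp(-est$theta_hat)
  data.frame(time = est$table$time,
             w1 = p * est$theta_hat / s,
             w2 = (p * (1 - exp(-l0) - l0) + exp(-l0)) / s)
}

#' Score components, Lin-Wei shifts and shifted scores for a cohort
#'
#' Builds the full per-subject score table of the mixture-model score
#' statistic under the null hypothesis of no marker effect.  For each event
#' at age \eqn{a_i} in stratum \eqn{j}, the raw score components are
#' \deqn{U_{kij} = \delta_i \, w_k(a_i)\{z_i - \bar z(a_i)\}, \quad k = 1, 2,}
#' where \eqn{\bar z(a_i)} is the marker mean over the risk set at
#' \eqn{a_i} (the weight is constant within a risk set at a fixed age, so
#' the weighted risk-set mean reduces to the plain mean; both the literal
#' weighted form and the separability factorisation over the risk set
#' excluding the failing subject are available via `form` and agree to
#' machine precision).  Censored subjects have \eqn{U = 0}.
#'
#' Every subject also receives the martingale-compensator shift of each
#' component,
#' \deqn{\tilde U_{kij} = \sum_{a_l \le X_{ij}} w_k(a_l)\,\frac{d_l}{r_l}
#'   \{z_i - \bar z(a_l)\},}
#' the weighted average of the score evaluated at event ages up to the
#' subject's follow-up age (with \eqn{d_l} events and \eqn{r_l} subjects at
#' risk at \eqn{a_l}).  The shifted (robust, Lin-Wei) scores
#' \eqn{W_{kij} = U_{kij} - \tilde U_{kij}} are independent and identically
#' distributed with mean zero under the null, which is what the
#' generalized-variance pseudo-R2 requires.  With both weights forced to 1
#' the \eqn{W} reduce to the classical Cox score residuals at \eqn{\beta=0}.
#'
#' @param time,event,marker Follow-up age, 0/1 event indicator and marker
#'   value per subject.
#' @param stratum Optional stratum labels; a single stratum when `NULL`.
#' @param entry Optional entry ages (used with `delayed_entry`).
#' @inheritParams null_estimates
#' @param form How to evaluate the raw scores: `"reduced"` (risk-set-mean
#'   form, default), `"weighted"` (literal weighted sums) or
#'   `"separability"` (factorised over the risk set excluding the failing
#'   subject).  All three are algebraically identical.
#'
#' @return A `data.frame` of class `"score_table"` with one row per subject
#'   in input order: `stratum`, `time`, `event`, `marker`, `w1`, `w2`
#'   (weights at the subject's own event age, `NA` for censored subjects),
#'   `U1`, `U2`, `shift1`, `shift2`, `W1`, `W2`.  Attributes:
#'   `null_estimates` (named list of [null_estimates()] objects),
#'   `K` (total events) and `neg_w2_fraction` (diagnostic: fraction of
#'   event ages with negative \eqn{w_2}).
#'
#' @examples
#' co <- simulate_cohort(200, tail_defect = 0.5, seed = 1)
#' st <- score_table(co$followup_age, co$event, co$marker)
#' colMeans(st[st$event == 1, c("W1", "W2")])
#' @export
score_table <- function(time, event, marker, stratum = NULL, entry = NULL,
                        delayed_entry = FALSE,
                        theta_convention = c("plateau", "printed"),
                        form = c("reduced", "weighted", "separability")) {
  theta_convention <- match.arg(theta_convention)
  form <- match.arg(form)
  n <- length(time)
  stopifnot(length(event) == n, length(marker) == n)
  if (is.null(stratum)) stratum <- rep(.DEFAULT_STRATUM, n)
  if (is.null(entry)) entry <- rep(0, n)
  stratum <- as.character(stratum)

  out <- data.frame(stratum = stratum, time = time, event = event,
                    marker = marker, w1 = NA_real_, w2 = NA_real_,
                    U1 = 0, U2 = 0, shift1 = 0, shift2 = 0, W1 = 0, W2 = 0)
  ests <- list()
  n_neg <- 0L
  n_et <- 0L
  for (j in unique(stratum)) {
    idx <- which(stratum == j)
    if (sum(event[idx]) == 0) next   # event-free stratum: all scores stay 0
    est <- null_estimates(time[idx], event[idx], entry = entry[idx],
                          delayed_entry = delayed_entry,
                          theta_convention = theta_convention,
                          stratum_label = j)
    sc <- .score_stratum(time[idx], event[idx], marker[idx],
                         entry = entry[idx], delayed_entry = delayed_entry,
                         est = est, form = form)
    out[idx, c("w1", "w2", "U1", "U2", "shift1", "shift2", "W1", "W2")] <- sc
    ests[[j]] <- est
    w <- score_weights(est)
    n_neg <- n_neg + sum(w$w2 < 0)
    n_et <- n_et + nrow(w)
  }
  structure(out, null_estimates = ests, K = sum(out$event),
            neg_w2_fraction = if (n_et > 0) n_neg / n_et else NA_real_,
            class = c("score_table", "data.frame"))
}

# Scores for one stratum.  'weights' overrides the model weights at the
# distinct event ages (a list with elements w1, w2), used to check the
# weight-1 reduction to classical Cox score residuals.
.score_stratum <- function(time, event, marker, entry = NULL,
                           delayed_entry = FALSE, est, form = "reduced",
                           weights = NULL) {
  rs <- .risk_stats(time, event, marker = marker, entry = entry,
                    delayed_entry = delayed_entry)
  et <- rs$event_time
  d <- rs$n_event
  r <- rs$n_risk
  zbar <- rs$marker_sum / r
  if (is.null(weights)) {
    w <- score_weights(est)
    w1 <- w$w1
    w2 <- w$w2
  } else {
    w1 <- rep_len(weights$w1, length(et))
    w2 <- rep_len(weights$w2, length(et))
  }

  n <- length(time)
  ev <- event == 1
  ai <- match(time, et)              # event-age index (NA for other ages)

  U1 <- U2 <- numeric(n)
  if (form == "reduced") {
    U1[ev] <- w1[ai[ev]] * (marker[ev] - zbar[ai[ev]])
    U2[ev] <- w2[ai[ev]] * (marker[ev] - zbar[ai[ev]])
  } else if (form == "weighted") {
    # literal weighted risk-set mean: sum Y w z / sum Y w with w constant
    # within the risk set at a fixed age
    for (k in which(ev)) {
      l <- ai[k]
      zb <- (w1[l] * rs$marker_sum[l]) / (w1[l] * r[l])
      U1[k] <- w1[l] * (marker[k] - zb)
      zb2 <- (w2[l] * rs$marker_sum[l]) / (w2[l] * r[l])
      U2[k] <- w2[l] * (marker[k] - zb2)
    }
  } else {                            # separability factorisation
    for (k in which(ev)) {
      l <- ai[k]
      if (r[l] <= 1) next             # self-only risk set: score is 0
      fac <- (r[l] - 1) / r[l]        # sum over R* / sum over R (w cancels)
      zstar <- (rs$marker_sum[l] - marker[k]) / (r[l] - 1)
      U1[k] <- w1[l] * fac * (marker[k] - zstar)
      U2[k] <- w2[l] * fac * (marker[k] - zstar)
    }
  }

  # martingale shifts: cumulative sums over event ages a_l <= X_i
  # (and a_l > entry_i under delayed entry)
  inc <- d / r
  c1a <- cumsum(w1 * inc);  c1b <- cumsum(w1 * inc * zbar)
  c2a <- cumsum(w2 * inc);  c2b <- cumsum(w2 * inc * zbar)
  hi <- findInterval(time, et)        # #{a_l <= X_i}
  lo <- if (delayed_entry) findInterval(entry, et) else integer(n)
  gat <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1L)], 0)
  shift1 <- marker * (gat(c1a, hi) - gat(c1a, lo)) -
    (gat(c1b, hi) - gat(c1b, lo))
  shift2 <- marker * (gat(c2a, hi) - gat(c2a, lo)) -
    (gat(c2b, hi) - gat(c2b, lo))

  data.frame(w1 = ifelse(ev, w1[ai], NA_real_),
             w2 = ifelse(ev, w2[ai], NA_real_),
             U1 = U1, U2 = U2, shift1 = shift1, shift2 = shift2,
             W1 = U1 - shift1, W2 = U2 - shift2)
}

#' Event-time-restricted shifted scores
#'
#' Restricts a [score_table()] to the rows of subjects that experienced the
#' event: the shifted scores at event times, \eqn{W^*_{1ij}} and
#' \eqn{W^*_{2ij}}, are the separability measures that enter the
#' generalized-variance pseudo-R2.
#'
#' @param st A `"score_table"`.
#' @return A `data.frame` with columns `stratum`, `time`, `marker`, `W1`,
#'   `W2`, one row per event, plus attributes `K` (total events) and
#'   `k_by_stratum`.
#' @export
event_scores <- function(st) {
  stopifnot(inherits(st, "score_table"))
  ev <- st[st$event == 1, c("stratum", "time", "marker", "W1", "W2")]
  K <- nrow(ev)
  if (K < 3)
    stop("only ", K, " event(s): at least 3 are required for the ",
         "generalized variance")
  kj <- table(factor(ev$stratum, levels = unique(ev$stratum)))
  structure(ev, K = K, k_by_stratum = c(kj))
}
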