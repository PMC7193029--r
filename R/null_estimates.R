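#' Per-stratum nuisance estimates under the null hypothesis
#'
#' Computes, for one stratum, every nuisance quantity of the two-component
#' mixture model evaluated under the null hypothesis of no marker effect:
#' the left-continuous Fleming-Harrington marginal survival
#' \eqn{\hat S(a_i-)} (exponential of minus the Nelson-Aalen cumulative
#' hazard), the tail-defect parameter \eqn{\hat\theta}, and the baseline
#' conditional cumulative hazard \eqn{\hat\Lambda_0(a_i-)} obtained by
#' inverting the mixture survival
#' \deqn{S(a) = e^{-\theta} + (1 - e^{-\theta}) e^{-\Lambda_0(a)}}
#' at the estimates, all tabulated at the distinct event ages of the
#' stratum.
#'
#' Ties are handled Breslow-style: all events at the same age share one
#' risk set.  The risk indicator is \eqn{Y_i(s) = 1(X_i \ge s)}; setting
#' `delayed_entry = TRUE` switches to \eqn{1(A_{0i} < s \le X_i)} for real
#' age-scale cohorts with staggered entry (off in all simulated designs,
#' where entry age is 0).
#'
#' Two conventions for \eqn{\hat\theta} are provided.  The default
#' `"plateau"` sets \eqn{\hat\theta = -\log \hat S(t_{max}+)}, so that
#' \eqn{e^{-\hat\theta}} equals the estimated survival plateau after the
#' last observed failure time — the estimated non-susceptible fraction that
#' the mixture model identifies as the tail defect.  The `"printed"`
#' variant \eqn{-\log(1 - \hat S(t_{max}+))} is retained for audit only;
#' it is inconsistent with the mixture parameterisation.
#'
#' @param time Follow-up ages \eqn{X_i}.
#' @param event 0/1 event indicators.
#' @param entry Entry ages (only used when `delayed_entry = TRUE`).
#' @param delayed_entry Use left-truncated risk sets.
#' @param theta_convention `"plateau"` (default) or `"printed"`; see
#'   Details.
#' @param stratum_label Label used in error messages and printing.
#'
#' @return An object of class `"stratum_null"`: a list with elements
#'   `table` (data.frame with columns `time`, `n_event`, `n_risk`,
#'   `surv_left`, `cumhaz0`), `theta_hat`, `tail_defect_hat`,
#'   `surv_plateau`, `k` (number of event contributions), `n`,
#'   `n_clipped` (event ages where the cumulative-hazard inversion was
#'   capped), `theta_convention` and `stratum_label`.
#'
#' @examples
#' est <- null_estimates(c(1, 2, 3), c(1, 0, 1))
#' est$table$surv_left   # 1 at age 1, exp(-1/3) at age 3
#' @export
null_estimates <- function(time, event, entry = NULL, delayed_entry = FALSE,
                           theta_convention = c("plateau", "printed"),
                           stratum_label = .DEFAULT_STRATUM) {
  theta_convention <- match.arg(theta_convention)
  n <- length(time)
  stopifnot(length(event) == n, all(event %in% c(0, 1)))
  if (delayed_entry && is.null(entry))
    stop("'entry' is required when delayed_entry = TRUE")
  if (sum(event) == 0)
    stop("no events in stratum '", stratum_label,
         "': null estimates are undefined")

  rs <- .risk_stats(time, event, marker = NULL, entry = entry,
                    delayed_entry = delayed_entry)
  et <- rs$event_time
  d <- rs$n_event
  r <- rs$n_risk
  if (any(r <= 0))
    stop("empty risk set at an event age in stratum '", stratum_label, "'")

  na_inc <- d / r
  na_right <- cumsum(na_inc)                 # Nelson-Aalen at et (right-cont.)
  surv_left <- exp(-c(0, na_right[-length(na_right)]))
  surv_plateau <- exp(-na_right[length(na_right)])

  theta_hat <- switch(theta_convention,
                      plateau = -log(surv_plateau),
                      printed = -log(1 - surv_plateau))
  if (!is.finite(theta_hat))
    warning("estimated survival reaches 0 at the last failure time; ",
            "theta_hat is infinite in stratum '", stratum_label, "'")

  ch <- .invert_cumhaz(surv_left, theta_hat)

  structure(list(
    table = data.frame(time = et, n_event = d, n_risk = r,
                       surv_left = surv_left, cumhaz0 = ch$cumhaz),
    theta_hat = theta_hat,
    tail_defect_hat = exp(-theta_hat),
    surv_plateau = surv_plateau,
    k = sum(d),
    n = n,
    n_clipped = ch$n_clipped,
    theta_convention = theta_convention,
    stratum_label = stratum_label
  ), class = "stratum_null")
}

# Invert the two-component mixture survival at the null estimates:
# Lambda0(a-) = -log[(S(a-) - e^-theta) / (1 - e^-theta)], left-continuous.
# Ages where S(a-) <= e^-theta are capped at the largest preceding finite
# value (count returned); monotonicity is enforced.
.invert_cumhaz <- function(surv_left, theta_hat) {
  p <- exp(-theta_hat)
  if (theta_hat <= 0 || p >= 1)
    stop("degenerate mixture: theta_hat must be > 0 to invert the ",
         "baseline cumulative hazard")
  ratio <- (surv_left - p) / (1 - p)
  bad <- ratio <= 0
  ch <- rep(NA_real_, length(ratio))
  ch[!bad] <- -log(ratio[!bad])
  if (any(bad)) {
    # carry the largest preceding finite value forward (0 if none)
    last <- 0
    for (i in seq_along(ch)) {
      if (is.na(ch[i])) ch[i] <- last else last <- ch[i]
    }
  }
  list(cumhaz = cummax(ch), n_clipped = sum(bad))
}

#' @export
print.stratum_null <- function(x, ...) {
  cat("Null-hypothesis estimates, stratum", x$stratum_label, "\n")
  cat(sprintf("  n = %d subjects, k = %d event contributions at %d ages\n",
              x$n, x$k, nrow(x$table)))
  cat(sprintf("  theta_hat = %.4f (tail defect %.4f, convention '%s')\n",
              x$theta_hat, x$tail_defect_hat, x$theta_convention))
  if (x$n_clipped > 0)
    cat(sprintf("  cumulative-hazard inversion capped at %d event age(s)\n",
                x$n_clipped))
  invisible(x)
}

# Risk-set statistics at the distinct event ages: multiplicity d, risk
# count r = sum Y_i(a), and (optionally) the risk-set sum of the marker.
# Y_i(a) = 1(X_i >= a), or 1(entry_i < a <= X_i) under delayed entry.
.risk_stats <- function(time, event, marker = NULL, entry = NULL,
                        delayed_entry = FALSE) {
  et <- sort(unique(time[event == 1]))
  ox <- order(time)
  xs <- time[ox]
  n <- length(time)
  below <- findInterval(et, xs, left.open = TRUE)   # #{X < a}
  n_risk <- n - below
  zsum <- NULL
  if (!is.null(marker)) {
    sufz <- rev(cumsum(rev(marker[ox])))            # sum z over X >= a
    zsum <- ifelse(below < n, sufz[below + 1L], 0)
  }
  if (delayed_entry) {
    oe <- order(entry)
    es <- entry[oe]
    in_before <- findInterval(et, es, left.open = TRUE)  # #{entry < a}
    not_in <- n - in_before                              # #{entry >= a}
    n_risk <- n_risk - not_in
    if (!is.null(marker)) {
      sufe <- rev(cumsum(rev(marker[oe])))
      zsum <- zsum - ifelse(in_before < n, sufe[in_before + 1L], 0)
    }
  }
  d <- as.integer(table(factor(time[event == 1], levels = et)))
  list(event_time = et, n_event = d, n_risk = n_risk, marker_sum = zsum)
}
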