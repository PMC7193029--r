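#' Generalized-variance pseudo-R2 from event-restricted shifted scores
#'
#' Low-level assembly of the pseudo-R2 from the shifted score vectors at
#' event times.  Under the null hypothesis the shifted scores have mean
#' zero, so the variance-covariance matrix of the 2-vector
#' \eqn{(W^*_1, W^*_2)} is estimated by uncentered cross-products pooled
#' over strata; under the alternative each stratum's cross-products are
#' centered by its own stratum mean.  With the common \eqn{1/(K-1)} factor
#' omitted (it cancels in the ratio),
#' \deqn{\Delta = \frac{\det(\Sigma) - \det(\Sigma^*)}{\det(\Sigma)},}
#' clipped to [0, 1] against finite-sample Monte-Carlo noise (the `clipped`
#' flag records when the raw ratio fell outside the range).
#'
#' @param W1,W2 Shifted score components at event times.
#' @param stratum Stratum labels (recycled to a single stratum when
#'   `NULL`).
#' @return A list with `det_null`, `det_alt`, `delta`, `delta_raw`, `K`,
#'   `k_by_stratum` and `clipped`.
#' @examples
#' pseudo_r2(c(1, -1, 0.5), c(1, 1, -0.5))
#' @export
pseudo_r2 <- function(W1, W2, stratum = NULL) {
  K <- length(W1)
  stopifnot(length(W2) == K)
  if (K < 3)
    stop("at least 3 event contributions are required; got ", K)
  if (is.null(stratum)) stratum <- rep(.DEFAULT_STRATUM, K)
  stratum <- as.character(stratum)

  s11 <- sum(W1^2); s22 <- sum(W2^2); s12 <- sum(W1 * W2)
  det_null <- s11 * s22 - s12^2

  a11 <- a22 <- a12 <- 0
  kj <- integer(0)
  for (j in unique(stratum)) {
    i <- stratum == j
    k <- sum(i)
    kj[j] <- k
    a11 <- a11 + sum(W1[i]^2) - sum(W1[i])^2 / k
    a22 <- a22 + sum(W2[i]^2) - sum(W2[i])^2 / k
    a12 <- a12 + sum(W1[i] * W2[i]) - sum(W1[i]) * sum(W2[i]) / k
  }
  det_alt <- a11 * a22 - a12^2

  if (det_null <= 0)
    stop("det(Sigma) under the null is not positive (degenerate or ",
         "collinear shifted scores); Delta is undefined")

  raw <- (det_null - det_alt) / det_null
  delta <- min(max(raw, 0), 1)
  list(det_null = det_null, det_alt = det_alt, delta = delta,
       delta_raw = raw, K = K, k_by_stratum = kj,
       clipped = raw < 0 || raw > 1)
}

#' Pseudo-R2 of a marker for time-to-event outcomes under a mixture cure
#' model
#'
#' Fits the score-statistic pseudo-R2 \eqn{\Delta} quantifying how much of
#' the separability of subject outcomes — both the propensity of being
#' susceptible to the event within the projection interval and the dynamic
#' of the event among susceptible subjects — is explained by a scalar
#' marker such as a polygenic risk score.  The criterion needs no
#' maximisation under the alternative: all nuisance quantities are
#' estimated under the null hypothesis of no marker effect
#' (see [null_estimates()]), the two score components and their Lin-Wei
#' shifts are evaluated (see [score_table()]), and \eqn{\Delta} is the
#' relative drop in the generalized variance of the event-restricted
#' shifted-score vector when centering under the alternative
#' (see [pseudo_r2()]).
#'
#' @param formula A formula with a [survival::Surv()] response and a single
#'   marker term, optionally plus a [survival::strata()] term, e.g.
#'   `Surv(followup_age, event) ~ marker + strata(entry_group)`.  A
#'   counting-process response `Surv(entry, time, event)` turns on delayed
#'   entry unless `delayed_entry = FALSE` is given explicitly.
#' @param data A `data.frame` containing the variables.
#' @param subset,na.action As in standard modelling functions.
#' @param delayed_entry Use left-truncated risk sets
#'   \eqn{1(A_0 < s \le X)} instead of \eqn{1(X \ge s)}.  Defaults to
#'   `TRUE` for counting-process responses, `FALSE` otherwise.
#' @inheritParams null_estimates
#'
#' @return An object of class `"delta_r2"` with components `delta`,
#'   `det_null`, `det_alt`, `clipped`, `K`, `k_by_stratum`, `n`,
#'   `theta_hat` and `tail_defect_hat` (named per stratum), `scores` (the
#'   full [score_table()]), `null_estimates`, `neg_w2_fraction`, `call`.
#'   Methods: `print`, `summary`, `residuals` (shifted scores), `plot`.
#'
#' @examples
#' co <- simulate_cohort(500, tail_defect = 0.7, beta = log(2.5), seed = 7)
#' fit <- delta_r2(survival::Surv(followup_age, event) ~ marker, data = co)
#' fit
#' summary(fit)
#' @export
delta_r2 <- function(formula, data, subset, na.action,
                     delayed_entry = NULL,
                     theta_convention = c("plateau", "printed")) {
  theta_convention <- match.arg(theta_convention)
  cl <- match.call()
  mf <- match.call(expand.dots = FALSE)
  m <- match(c("formula", "data", "subset", "na.action"), names(mf), 0L)
  mf <- mf[c(1L, m)]
  mf[[1L]] <- quote(stats::model.frame)
  tt <- if (missing(data)) terms(formula, specials = "strata")
        else terms(formula, specials = "strata", data = data)
  mf$formula <- tt
  mf <- eval(mf, parent.frame())

  y <- model.response(mf)
  if (!survival::is.Surv(y))
    stop("the response must be a survival::Surv() object")
  ytype <- attr(y, "type")
  if (ytype == "right") {
    entry <- rep(0, nrow(y))
    time <- y[, 1]
    event <- y[, 2]
    if (is.null(delayed_entry)) delayed_entry <- FALSE
  } else if (ytype == "counting") {
    entry <- y[, 1]
    time <- y[, 2]
    event <- y[, 3]
    if (is.null(delayed_entry)) delayed_entry <- TRUE
  } else {
    stop("unsupported Surv type '", ytype, "'")
  }

  specials <- attr(tt, "specials")$strata
  if (length(specials)) {
    stemp <- survival::untangle.specials(tt, "strata", 1)
    stratum <- if (length(stemp$vars) == 1L) mf[[stemp$vars]]
               else survival::strata(mf[, stemp$vars], shortlabel = TRUE)
    covars <- attr(tt, "term.labels")[-stemp$terms]
  } else {
    stratum <- NULL
    covars <- attr(tt, "term.labels")
  }
  if (length(covars) != 1L)
    stop("exactly one marker term is required; got ",
         length(covars))
  marker <- mf[[covars]]
  if (!is.numeric(marker))
    stop("the marker must be numeric")

  fit <- .delta_fit(time = time, event = event, marker = marker,
                    stratum = stratum, entry = entry,
                    delayed_entry = delayed_entry,
                    theta_convention = theta_convention)
  fit$call <- cl
  fit
}

# Workhorse behind delta_r2(); also called directly by the study harness.
.delta_fit <- function(time, event, marker, stratum = NULL, entry = NULL,
                       delayed_entry = FALSE,
                       theta_convention = "plateau") {
  st <- score_table(time, event, marker, stratum = stratum, entry = entry,
                    delayed_entry = delayed_entry,
                    theta_convention = theta_convention)
  ev <- event_scores(st)
  pr <- pseudo_r2(ev$W1, ev$W2, ev$stratum)
  ests <- attr(st, "null_estimates")
  structure(list(
    delta = pr$delta, delta_raw = pr$delta_raw,
    det_null = pr$det_null, det_alt = pr$det_alt, clipped = pr$clipped,
    K = pr$K, k_by_stratum = pr$k_by_stratum,
    n = length(time), n_event = sum(event),
    theta_hat = vapply(ests, `[[`, 0, "theta_hat"),
    tail_defect_hat = vapply(ests, `[[`, 0, "tail_defect_hat"),
    scores = st, null_estimates = ests,
    neg_w2_fraction = attr(st, "neg_w2_fraction"),
    delayed_entry = delayed_entry, theta_convention = theta_convention,
    call = NULL
  ), class = "delta_r2")
}

#' @export
print.delta_r2 <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n")
    print(x$call)
    cat("\n")
  }
  cat(sprintf("Mixture-model pseudo-R2: Delta = %.*f%s\n", digits, x$delta,
              if (x$clipped) " (clipped to [0, 1])" else ""))
  cat(sprintf("  n = %d subjects, K = %d events in %d stratum/strata\n",
              x$n, x$K, length(x$k_by_stratum)))
  cat(sprintf("  det(Sigma) = %.*g, det(Sigma*) = %.*g\n",
              digits, x$det_null, digits, x$det_alt))
  invisible(x)
}

#' @export
summary.delta_r2 <- function(object, ...) {
  strata_tab <- data.frame(
    stratum = names(object$k_by_stratum),
    k = as.integer(object$k_by_stratum),
    theta_hat = object$theta_hat[names(object$k_by_stratum)],
    tail_defect_hat = object$tail_defect_hat[names(object$k_by_stratum)],
    row.names = NULL)
  structure(list(fit = object, strata = strata_tab), class = "summary.delta_r2")
}

#' @export
print.summary.delta_r2 <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-stratum null estimates:\n")
  print(x$strata, digits = digits, row.names = FALSE)
  cat(sprintf("\nNegative w2 at %.1f%% of event ages\n",
              100 * x$fit$neg_w2_fraction))
  if (x$fit$theta_convention != "plateau")
    cat("theta convention:", x$fit$theta_convention, "\n")
  invisible(x)
}

#' Shifted-score residuals of a Delta pseudo-R2 fit
#'
#' @param object A `"delta_r2"` fit.
#' @param event_only Return only the event-restricted rows (the
#'   \eqn{W^*} used by the criterion).
#' @param ... Unused.
#' @return A two-column matrix of shifted scores (`W1`, `W2`), with the
#'   stratum labels as row names.
#' @export
residuals.delta_r2 <- function(object, event_only = FALSE, ...) {
  st <- object$scores
  if (event_only) st <- st[st$event == 1, ]
  m <- as.matrix(st[, c("W1", "W2")])
  rownames(m) <- st$stratum
  m
}

#' @export
plot.delta_r2 <- function(x, ...) {
  ev <- x$scores[x$scores$event == 1, ]
  js <- unique(ev$stratum)
  cols <- seq_along(js)
  plot(ev$W1, ev$W2, col = cols[match(ev$stratum, js)],
       xlab = "W1* (propensity component)",
       ylab = "W2* (dynamic component)",
       main = sprintf("Shifted scores at event times (Delta = %.3f)",
                      x$delta), ...)
  abline(h = 0, v = 0, lty = 3)
  if (length(js) > 1)
    legend("topright", legend = paste("stratum", js), col = cols, pch = 1,
           bty = "n")
  invisible(x)
}
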