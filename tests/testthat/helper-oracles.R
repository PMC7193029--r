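# Independent oracles used across the suite.  Everything here is written as
# literal loops over the defining sums, deliberately avoiding the vectorized
# code paths of the package.

# Small random right-censored cohort; occasional ties via rounding.
rand_cohort <- function(n, seed, p_event = 0.6, ties = FALSE, n_strata = 1) {
  set.seed(seed)
  time <- rexp(n)
  if (ties) time <- round(time, 1) + 0.05
  data.frame(
    time = time,
    event = rbinom(n, 1, p_event),
    z = rnorm(n),
    stratum = sample(seq_len(n_strata), n, replace = TRUE))
}

# Literal Nelson-Aalen / Fleming-Harrington null estimates for one stratum.
brute_null <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s_left <- numeric(length(et))
  cum <- 0
  for (m in seq_along(et)) {
    s_left[m] <- exp(-cum)
    d <- sum(time == et[m] & event == 1)
    r <- sum(time >= et[m])
    cum <- cum + d / r
  }
  plateau <- exp(-cum)
  theta <- -log(plateau)
  l0 <- -log((s_left - plateau) / (1 - plateau))
  list(et = et, s_left = s_left, theta = theta, plateau = plateau, l0 = l0)
}

# Literal double-loop transcription of the whole Delta pipeline: weights,
# weighted score brackets, martingale shifts, event restriction, pooled and
# within-stratum-centered generalized variances.
brute_delta <- function(time, event, z, stratum = rep(1, length(time))) {
  W1s <- W2s <- numeric(0)
  js <- character(0)
  for (j in unique(stratum)) {
    sel <- stratum == j
    tt <- time[sel]; dd <- event[sel]; zz <- z[sel]
    nb <- brute_null(tt, dd)
    p <- nb$plateau
    w1 <- p * nb$theta / nb$s_left
    w2 <- (p * (1 - exp(-nb$l0) - nb$l0) + exp(-nb$l0)) / nb$s_left
    for (k in seq_along(tt)) {
      u1 <- u2 <- 0
      if (dd[k] == 1) {
        m <- which(nb$et == tt[k])
        risk <- which(tt >= tt[k])
        u1 <- w1[m] * (zz[k] - sum(w1[m] * zz[risk]) / sum(rep(w1[m], length(risk))))
        u2 <- w2[m] * (zz[k] - sum(w2[m] * zz[risk]) / sum(rep(w2[m], length(risk))))
      }
      sh1 <- sh2 <- 0
      for (m in seq_along(nb$et)) {
        if (nb$et[m] <= tt[k]) {
          risk <- which(tt >= nb$et[m])
          dl <- sum(tt == nb$et[m] & dd == 1)
          zb <- mean(zz[risk])
          sh1 <- sh1 + w1[m] * dl / length(risk) * (zz[k] - zb)
          sh2 <- sh2 + w2[m] * dl / length(risk) * (zz[k] - zb)
        }
      }
      if (dd[k] == 1) {
        W1s <- c(W1s, u1 - sh1)
        W2s <- c(W2s, u2 - sh2)
        js <- c(js, as.character(j))
      }
    }
  }
  det_null <- sum(W1s^2) * sum(W2s^2) - sum(W1s * W2s)^2
  a11 <- a22 <- a12 <- 0
  for (j in unique(js)) {
    sel <- js == j
    kj <- sum(sel)
    a11 <- a11 + sum(W1s[sel]^2) - sum(W1s[sel])^2 / kj
    a22 <- a22 + sum(W2s[sel]^2) - sum(W2s[sel])^2 / kj
    a12 <- a12 + sum(W1s[sel] * W2s[sel]) -
      sum(W1s[sel]) * sum(W2s[sel]) / kj
  }
  det_alt <- a11 * a22 - a12^2
  min(max((det_null - det_alt) / det_null, 0), 1)
}

# Replication mean of Delta on simulated cohorts (one call per cell).
mc_delta_mean <- function(reps, n, tail, ea = 1, eb = 1, seed = 1, ...) {
  r <- run_study(hr_propensity = ea, hr_dynamic = eb, tail_defect = tail,
                 n = n, reps = reps, seed = seed, ...)
  r$mean[r$index == "delta"]
}
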