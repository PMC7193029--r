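#' Monte-Carlo simulation study of the pseudo-R2 indices
#'
#' Runs the factorial simulation study: for every combination of the
#' supplied hazard-ratio, tail-defect and design values, simulates `reps`
#' cohorts, computes the Delta pseudo-R2 (and, on request, the
#' partial-likelihood comparator indices) on each, and reports the
#' replication mean and standard deviation per cell.
#'
#' Per-cell seeds are derived reproducibly from the master `seed` (one
#' `sample.int()` draw per cell after seeding the generator), and the
#' replication seed is the cell seed plus the replication index, so the
#' whole study is byte-identical for a fixed `seed`.  Replications on which
#' the criterion is degenerate (fewer than 3 events, zero plateau, or a
#' non-positive null generalized variance) are dropped and counted; a cell
#' with more than 5% degenerate replications is flagged.
#'
#' @param hr_propensity,hr_dynamic Hazard-ratio grids \eqn{e^\alpha},
#'   \eqn{e^\beta} (each > 0).
#' @param tail_defect Baseline non-susceptible probabilities, each in
#'   (0, 1).
#' @param n Cohort sizes.
#' @param censor_fraction Target censoring fractions among susceptible
#'   subjects (0 disables censoring).
#' @param covariate,family,n_strata Passed to [simulate_cohort()] (scalar
#'   or vectors to include in the grid).
#' @param reps Replications per cell.
#' @param seed Master seed.
#' @param indices Character subset of `c("delta", "N", "XO", "OXS")`.
#' @param verbose Print per-cell progress.
#'
#' @return A long-format `data.frame` of class `"delta_study"`: one row per
#'   cell and index, with the cell parameters, `index`, `mean`, `sd`,
#'   `reps_used`, `reps_failed` and `flagged`.
#'
#' @examples
#' res <- run_study(hr_dynamic = c(1, 2.5), tail_defect = 0.7, n = 200,
#'                  reps = 20, seed = 1)
#' render_study_table(res)
#' @seealso [render_study_table()]
#' @export
run_study <- function(hr_propensity = 1, hr_dynamic = 1, tail_defect = 0.3,
                      n = 500, censor_fraction = 0,
                      covariate = "normal", family = "exponential",
                      n_strata = 1, reps = 300, seed = 1,
                      indices = "delta", verbose = FALSE) {
  stopifnot(reps >= 1, all(hr_propensity > 0), all(hr_dynamic > 0))
  indices <- match.arg(indices, c("delta", "N", "XO", "OXS"),
                       several.ok = TRUE)
  cells <- expand.grid(hr_propensity = hr_propensity,
                       hr_dynamic = hr_dynamic,
                       tail_defect = tail_defect, n = n,
                       censor_fraction = censor_fraction,
                       covariate = covariate, family = family,
                       n_strata = n_strata,
                       stringsAsFactors = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  cell_seed <- sample.int(.Machine$integer.max - reps - 1L, nrow(cells))

  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    u <- if (cell$censor_fraction > 0)
      censoring_bound(cell$tail_defect, alpha = log(cell$hr_propensity),
                      beta = log(cell$hr_dynamic),
                      covariate = cell$covariate, family = cell$family,
                      censor_fraction = cell$censor_fraction,
                      seed = cell_seed[ci])
    else NULL

    vals <- matrix(NA_real_, reps, length(indices),
                   dimnames = list(NULL, indices))
    failed <- 0L
    for (r in seq_len(reps)) {
      co <- simulate_cohort(cell$n, cell$tail_defect,
                            alpha = log(cell$hr_propensity),
                            beta = log(cell$hr_dynamic),
                            covariate = cell$covariate,
                            family = cell$family,
                            censor_fraction = cell$censor_fraction,
                            n_strata = cell$n_strata,
                            censor_bound = u,
                            seed = cell_seed[ci] + r)
      row <- tryCatch({
        v <- c()
        if ("delta" %in% indices) {
          fit <- .delta_fit(co$followup_age, co$event, co$marker,
                            stratum = co$stratum)
          v <- c(delta = fit$delta)
        }
        if (any(c("N", "XO", "OXS") %in% indices)) {
          pf <- fit_ph(co$followup_age, co$event, co$marker,
                       stratum = co$stratum)
          v <- c(v, ph_indices(pf)[setdiff(indices, "delta")])
        }
        v
      }, error = function(e) NULL)
      if (is.null(row) || anyNA(row)) failed <- failed + 1L
      else vals[r, names(row)] <- row
    }

    reps_used <- colSums(!is.na(vals))
    out[[ci]] <- data.frame(
      cell[rep(1, length(indices)), , drop = FALSE],
      index = indices,
      mean = colMeans(vals, na.rm = TRUE),
      sd = apply(vals, 2, function(x)
        if (sum(!is.na(x)) > 1) sd(x, na.rm = TRUE) else NA_real_),
      reps_used = as.integer(reps_used),
      reps_failed = failed,
      flagged = failed > 0.05 * reps,
      row.names = NULL)
    if (verbose)
      message(sprintf(
        "cell %d/%d (ea=%g, eb=%g, tail=%g, n=%d): %s%s", ci, nrow(cells),
        cell$hr_propensity, cell$hr_dynamic, cell$tail_defect, cell$n,
        paste(sprintf("%s=%.3f", indices, out[[ci]]$mean), collapse = ", "),
        if (failed > 0) sprintf(" [%d failed]", failed) else ""))
  }
  structure(do.call(rbind, out), class = c("delta_study", "data.frame"))
}

#' Format a simulation-study result in the comparison-table layout
#'
#' Lays the long-format result of [run_study()] out as panels, one per
#' tail-defect value, with one column per (propensity HR, dynamic HR)
#' combination and a Mean and SD row per index, formatted to two decimals.
#'
#' @param results A `"delta_study"` data frame.
#' @param digits Decimal places (default 2).
#' @param file Optional path; when given, the long-format table is written
#'   there as CSV and the text rendering is returned invisibly.
#' @return Character vector of formatted lines (invisibly when printed or
#'   written).
#' @export
render_study_table <- function(results, digits = 2, file = NULL) {
  stopifnot(is.data.frame(results))
  if (!is.null(file)) write.csv(results, file, row.names = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  lines <- character(0)
  if (nrow(results) == 0) {
    lines <- "index  statistic  (no cells)"
  } else {
    for (td in unique(results$tail_defect)) {
      panel <- results[results$tail_defect == td, ]
      combos <- unique(panel[, c("hr_propensity", "hr_dynamic")])
      hdr <- sprintf("%-6s %-5s %s", "index", "", paste(
        sprintf("ea=%g,eb=%g", combos$hr_propensity, combos$hr_dynamic),
        collapse = "  "))
      lines <- c(lines, sprintf("-- tail defect %g --", td), hdr)
      wid <- nchar(sprintf("ea=%g,eb=%g", combos$hr_propensity,
                           combos$hr_dynamic))
      pad <- function(v) mapply(function(x, w)
        formatC(x, width = w, flag = "-"), v, wid)
      for (ix in unique(panel$index)) {
        sub <- panel[panel$index == ix, ]
        key <- paste(sub$hr_propensity, sub$hr_dynamic)
        ord <- match(paste(combos$hr_propensity, combos$hr_dynamic), key)
        mrow <- pad(fmt(sub$mean[ord]))
        srow <- pad(fmt(sub$sd[ord]))
        lines <- c(lines,
                   sprintf("%-6s %-5s %s", ix, "Mean",
                           paste(mrow, collapse = "  ")),
                   sprintf("%-6s %-5s %s", "", "SD",
                           paste(srow, collapse = "  ")))
      }
    }
  }
  if (is.null(file)) {
    cat(lines, sep = "\n")
    invisible(lines)
  } else invisible(lines)
}
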