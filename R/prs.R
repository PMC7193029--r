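#' Compute a weighted allele-dosage polygenic risk score
#'
#' Builds the classical polygenic risk score: for subject \eqn{i},
#' \deqn{PRS_i = \sum_k d_{ik} \, \log OR_k,}
#' the sum of effect-allele dosages \eqn{d_{ik} \in [0, 2]} weighted by the
#' published log odds-ratios.  Dosages are assumed pre-oriented to the
#' effect allele; no strand or allele flipping is attempted (genotype QC
#' and imputation are upstream of this function).
#'
#' @param dosages Numeric matrix or data frame of expected effect-allele
#'   dosages, subjects in rows, variants in columns, with variant ids as
#'   column names (hard calls or imputed expectations, each in [0, 2];
#'   missing values must be `NA`, never silently 0).
#' @param weights Data frame with columns `variant_id`, `effect_allele`,
#'   `log_or` (see [read_weight_table()]).
#' @param missing_policy What to do when a weight variant is absent from
#'   the dosage matrix or a dosage is `NA`: `"error"` (default),
#'   `"mean_impute"` (replace `NA` dosages by the variant's observed mean;
#'   absent variants are still an error), or `"skip"` (drop absent
#'   variants from the score, with no renormalization of the remaining
#'   weights; `NA` dosages are still an error).
#' @return A named numeric vector of scores, one per subject (row) of
#'   `dosages`.
#' @examples
#' d <- matrix(c(0, 1, 2, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
#' w <- data.frame(variant_id = c("rs1", "rs2"), effect_allele = c("A", "G"),
#'                 log_or = c(log(1.5), log(0.8)))
#' compute_prs(d, w)
#' @export
compute_prs <- function(dosages, weights,
                        missing_policy = c("error", "mean_impute", "skip")) {
  missing_policy <- match.arg(missing_policy)
  dosages <- as.matrix(dosages)
  if (!is.numeric(dosages)) stop("'dosages' must be numeric")
  need <- c("variant_id", "log_or")
  if (!all(need %in% names(weights)))
    stop("'weights' must have columns 'variant_id' and 'log_or'")
  if (anyDuplicated(weights$variant_id))
    stop("duplicated variant ids in the weight table")
  if (!all(is.finite(weights$log_or)))
    stop("non-finite log odds-ratio in the weight table")

  present <- weights$variant_id %in% colnames(dosages)
  if (!all(present)) {
    if (missing_policy == "skip") {
      weights <- weights[present, , drop = FALSE]
    } else {
      stop("weight variant(s) absent from the dosage matrix: ",
           paste(weights$variant_id[!present], collapse = ", "))
    }
  }
  if (nrow(weights) == 0)
    return(structure(rep(0, nrow(dosages)), names = rownames(dosages)))

  d <- dosages[, weights$variant_id, drop = FALSE]
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]")
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      for (k in seq_len(ncol(d))) {
        nas <- is.na(d[, k])
        if (any(nas)) d[nas, k] <- mean(d[, k], na.rm = TRUE)
      }
      if (anyNA(d)) stop("a variant has no observed dosages to impute from")
    } else {
      stop("missing dosages present; set missing_policy = 'mean_impute' ",
           "to mean-impute them")
    }
  }
  drop(d %*% weights$log_or)
}

#' Read polygenic-score inputs from delimited text
#'
#' `read_weight_table()` reads a 3-column tab-separated table
#' (`variant_id`, `effect_allele`, `log_or`).  `read_dosage_matrix()` reads
#' a CSV whose first column holds subject ids and whose remaining columns,
#' headed by variant ids, hold effect-allele dosages.
#'
#' @param path File path.
#' @return A data frame (weights) or numeric matrix with subject row names
#'   (dosages).
#' @export
read_weight_table <- function(path) {
  w <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "log_or")
  if (!all(need %in% names(w)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  w
}

#' @rdname read_weight_table
#' @export
read_dosage_matrix <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}
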