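#' Frequency of tumors misjudged into normal
#'
#' Of the tumors of a cancer type that were ever misclassified, the
#' percentage whose misclassification was into the normal class, reported
#' to two decimals (37/37 gives 100.00; 57/59 gives 96.61).
#'
#' @param n_to_normal Tumors misjudged into normal.
#' @param n_error Tumors with at least one error identification.
#' @return Percentage rounded to 2 decimals; `NA` when `n_error` is 0.
#' @export
misjudged_to_normal_freq <- function(n_to_normal, n_error) {
  stopifnot(n_to_normal >= 0, n_error >= 0, n_to_normal <= n_error)
  ifelse(n_error == 0, NA_real_, round(100 * n_to_normal / n_error, 2L))
}

#' Survival-association ratio between misjudged and correct tumors
#'
#' Ratio of the proportion of "dead but survived >= 2 years" patients among
#' tumors misjudged into normal to the same proportion among correctly
#' identified tumors: (a / n_to_normal) / (b / n_correct). A value above 1
#' means the misjudged group was enriched for long-surviving patients.
#' Although often labeled an odds ratio in this context, the quantity is
#' algebraically a risk ratio; this function computes exactly that.
#'
#' @param a Dead-but->=2-year survivors among tumors misjudged into normal.
#' @param n_to_normal Tumors misjudged into normal.
#' @param b Dead-but->=2-year survivors among correctly identified tumors.
#' @param n_correct Correctly identified tumors.
#' @return The ratio; 0 when `a` = 0 and `b` > 0; `NA` when either
#'   denominator is 0, or when `b` = 0 with `a` > 0.
#' @export
survival_ratio <- function(a, n_to_normal, b, n_correct) {
  stopifnot(a >= 0, b >= 0, a <= n_to_normal, b <= n_correct)
  if (n_to_normal == 0 || n_correct == 0) return(NA_real_)
  if (b == 0) return(if (a == 0) 0 else NA_real_)
  if (a == 0) return(0)
  (a / n_to_normal) / (b / n_correct)
}

#' Misjudgment/survival association table
#'
#' Summarizes, per cancer type, the association between tumors being
#' misjudged into the normal class and patient survival: among the unique
#' tumors ever misclassified across all experiments of the prediction log,
#' how many went to normal, and whether the "dead but lived >= 2 years"
#' (>= 730 days) fraction differs between misjudged-into-normal and
#' correctly identified tumors.
#'
#' @param log Prediction log (`experiment_id`, `sample_id`, `truth`,
#'   `predicted`, `role`); truth classes other than `"normal"` are cancer
#'   types.
#' @param clinical Data frame with `sample_id`, `vital_status`
#'   (`"dead"`/`"alive"`), `survival_days`. Samples without clinical data
#'   propagate NA.
#' @param per_experiment Count sample-experiment events instead of unique
#'   samples (default `FALSE`: each sample counted once overall).
#' @param min_days Survival threshold in days for "lived >= 2 years"
#'   (default 730).
#' @return Data frame with one row per cancer: `cancer`, `freq_pct`,
#'   `n_error`, `n_to_normal`, `n_correct`, `dead_ge2y_misjudged`,
#'   `dead_ge2y_correct`, `ratio`, `note`; sorted by `freq_pct` descending.
#' @export
build_survival_table <- function(log, clinical, per_experiment = FALSE,
                                 min_days = 730) {
  rec <- log[log$role == "validation" & log$truth != "normal", ]
  if (nrow(rec) == 0L) stop("log has no validation tumor records")
  has_clin <- !is.null(clinical) && nrow(clinical) > 0L
  dead2y <- function(ids) {
    if (!has_clin) return(NA_integer_)
    cl <- clinical[match(ids, clinical$sample_id), ]
    if (all(is.na(cl$sample_id))) return(NA_integer_)
    sum(cl$vital_status == "dead" & cl$survival_days >= min_days, na.rm = TRUE)
  }

  rows <- lapply(sort(unique(rec$truth)), function(cx) {
    r <- rec[rec$truth == cx, ]
    if (per_experiment) {
      err_ids <- paste(r$experiment_id, r$sample_id)[r$predicted != r$truth]
      nrm_ids <- paste(r$experiment_id, r$sample_id)[r$predicted == "normal"]
      n_error <- length(unique(err_ids))
      n_to_normal <- length(unique(nrm_ids))
      to_normal_samples <- unique(r$sample_id[r$predicted == "normal"])
      correct_samples <- setdiff(unique(r$sample_id),
                                 unique(r$sample_id[r$predicted != r$truth]))
    } else {
      to_normal_samples <- unique(r$sample_id[r$predicted == "normal"])
      error_samples <- unique(r$sample_id[r$predicted != r$truth])
      correct_samples <- setdiff(unique(r$sample_id), error_samples)
      n_error <- length(error_samples)
      n_to_normal <- length(to_normal_samples)
    }
    n_correct <- length(correct_samples)
    a <- dead2y(to_normal_samples)
    b <- dead2y(correct_samples)
    note <- ""
    if (is.na(a) || is.na(b)) {
      ratio <- NA_real_
      note <- "no_clinical_data"
    } else if (n_to_normal > 0 && a == 0) {
      ratio <- survival_ratio(a, n_to_normal, b, n_correct)
      note <- "no_death_misjudged"
    } else if (n_to_normal == 0 || n_correct == 0) {
      ratio <- NA_real_
    } else {
      ratio <- survival_ratio(a, n_to_normal, b, n_correct)
    }
    data.frame(cancer = cx,
               freq_pct = misjudged_to_normal_freq(n_to_normal, n_error),
               n_error = n_error, n_to_normal = n_to_normal,
               n_correct = n_correct,
               dead_ge2y_misjudged = a, dead_ge2y_correct = b,
               ratio = ratio, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$freq_pct), , drop = FALSE]
}
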