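#' Draw a stratified training/validation split
#'
#' Per cancer type, the training set takes a subset of the normals (by
#' default a random half, rounded up) plus exactly `tumor_per_normal` times
#' that many randomly drawn tumors; everything else goes to validation. With
#' 57 training normals for a cancer and the default 3:1 ratio, 171 of its
#' tumors are drawn. Deterministic given `seed`.
#'
#' @param metadata Data frame with `sample_id`, `cancer`, `status`
#'   (`"tumor"`/`"normal"`); every cancer needs at least one normal and
#'   enough tumors for the ratio.
#' @param tumor_per_normal Training tumors drawn per training normal
#'   (default 3).
#' @param normal_fraction Fraction of each cancer's normals placed in
#'   training, rounded up (default 0.5).
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `validation`
#'   partitioning `metadata$sample_id`.
#' @export
make_split <- function(metadata, tumor_per_normal = 3L, normal_fraction = 0.5,
                       seed = 1L) {
  stopifnot(all(c("sample_id", "cancer", "status") %in% names(metadata)))
  with_seed(seed, {
    train <- character(0)
    for (cx in sort(unique(metadata$cancer))) {
      normals <- metadata$sample_id[metadata$cancer == cx &
                                      metadata$status == "normal"]
      tumors <- metadata$sample_id[metadata$cancer == cx &
                                     metadata$status == "tumor"]
      if (length(normals) < 1L)
        stop("cancer '", cx, "' has no normal samples")
      n_norm <- ceiling(length(normals) * normal_fraction)
      n_tum <- tumor_per_normal * n_norm
      if (length(tumors) < n_tum)
        stop("cancer '", cx, "' has only ", length(tumors),
             " tumors; the split needs ", n_tum)
      train <- c(train,
                 sample(normals, n_norm),
                 sample(tumors, n_tum))
    }
    list(train = train,
         validation = setdiff(as.character(metadata$sample_id), train))
  })
}

#' Classification accuracy from confusion counts
#'
#' (TP + TN) / (TP + TN + FP + FN) on the binary normal-vs-tumor view.
#'
#' @param counts A `confusion_counts` object from [confusion_matrix()], or a
#'   list/vector with elements `TP`, `TN`, `FP`, `FN`.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples: all confusion counts are zero")
  (tp + tn) / total
}

#' Multi-class and binary confusion counts for one experiment
#'
#' Tallies truth x predicted over the validation records of one experiment
#' in a prediction log. The binary view collapses every cancer class to
#' `"tumor"`, with `"normal"` as the negative class (TP = tumor called
#' tumor, TN = normal called normal).
#'
#' @param log Prediction log: data frame with `experiment_id`, `sample_id`,
#'   `truth`, `predicted`, `role` (`"train"`/`"validation"`).
#' @param experiment_id Which experiment to tally.
#' @return An object of class `confusion_counts`: list with `matrix`
#'   (class x class counts, truth in rows), `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(log, experiment_id) {
  rec <- log[log$experiment_id == experiment_id & log$role == "validation", ]
  if (nrow(rec) == 0L) stop("no validation records for experiment '",
                            experiment_id, "'")
  classes <- sort(unique(c(rec$truth, rec$predicted)))
  m <- table(factor(rec$truth, levels = classes),
             factor(rec$predicted, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("truth", "predicted")
  truth_tumor <- rec$truth != "normal"
  pred_tumor <- rec$predicted != "normal"
  structure(list(matrix = m,
                 TP = sum(truth_tumor & pred_tumor),
                 TN = sum(!truth_tumor & !pred_tumor),
                 FP = sum(!truth_tumor & pred_tumor),
                 FN = sum(truth_tumor & !pred_tumor)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion_counts (binary: TP", x$TP, "TN", x$TN, "FP", x$FP,
      "FN", x$FN, ")\n")
  print(x$matrix)
  invisible(x)
}

#' Per-sample error-identification frequency
#'
#' Across the repeated experiments of a prediction log, counts how often
#' each sample was drawn into a validation set and how often it was then
#' misclassified; the frequency is the percentage of misjudged appearances
#' (a sample always misjudged in 40 appearances scores 100).
#'
#' @param log Prediction log (see [confusion_matrix()]).
#' @param sample_id Optional single sample; default reports all samples.
#' @return Data frame `sample_id`, `truth`, `times_selected`,
#'   `times_misjudged`, `pct`. Samples never selected for validation get
#'   `NA` counts.
#' @export
error_frequency <- function(log, sample_id = NULL) {
  rec <- log[log$role == "validation", ]
  ids <- if (is.null(sample_id)) sort(unique(log$sample_id)) else sample_id
  out <- lapply(ids, function(id) {
    r <- rec[rec$sample_id == id, ]
    if (nrow(r) == 0L)
      return(data.frame(sample_id = id, truth = NA_character_,
                        times_selected = NA_integer_,
                        times_misjudged = NA_integer_, pct = NA_real_))
    mis <- sum(r$predicted != r$truth)
    data.frame(sample_id = id, truth = r$truth[1L],
               times_selected = nrow(r), times_misjudged = mis,
               pct = 100 * mis / nrow(r))
  })
  do.call(rbind, out)
}

#' Mean expression correlation between a sample and a class
#'
#' Averages the Pearson correlation between one sample's (DEG-restricted)
#' expression vector and every member of a class. When the sample itself
#' belongs to the class it is excluded from the average. Zero-variance
#' pairs yield NA and are dropped with a warning.
#'
#' @param profile Named numeric vector (genes) for the query sample.
#' @param class_profiles Genes x samples matrix of the class members (same
#'   genes as `profile`, or a shared subset of >= 2 genes).
#' @param self Optional column name in `class_profiles` identifying the
#'   query sample itself, excluded from the mean.
#' @return Mean Pearson r (scalar; NA if no valid pair).
#' @export
class_similarity <- function(profile, class_profiles, self = NULL) {
  class_profiles <- as.matrix(class_profiles)
  genes <- intersect(names(profile), rownames(class_profiles))
  if (length(genes) < 2L) stop("need at least 2 shared genes")
  if (!is.null(self)) {
    keep <- colnames(class_profiles) != self
    class_profiles <- class_profiles[, keep, drop = FALSE]
  }
  if (ncol(class_profiles) == 0L) stop("class is empty")
  x <- profile[genes]
  rs <- apply(class_profiles[genes, , drop = FALSE], 2L, function(yv) {
    if (stats::sd(x) == 0 || stats::sd(yv) == 0) return(NA_real_)
    stats::cor(x, yv)
  })
  if (anyNA(rs)) {
    warning(sum(is.na(rs)), " zero-variance pair(s) excluded")
    rs <- rs[!is.na(rs)]
  }
  if (length(rs) == 0L) return(NA_real_)
  mean(rs)
}

#' Repeated random-split experiments
#'
#' Runs [make_split()], [cnn_train()] and [predict.cnn_model()] `repeats`
#' times, accumulating a prediction log over the validation samples of each
#' experiment. Seeds for each experiment are derived from `seed`, so any
#' single experiment is reproducible in isolation.
#'
#' @param images A labeled `network_image_set` for the whole cohort.
#' @param metadata Cohort metadata (`sample_id`, `cancer`, `status`).
#' @param spec A [cnn_spec()] matching the image size.
#' @param config A [train_config()]; its `seed` field is overridden per
#'   experiment.
#' @param repeats Number of repeated experiments (the study design uses 50).
#' @param seed Root seed.
#' @param tumor_per_normal,normal_fraction Passed to [make_split()].
#' @return A prediction-log data frame (`experiment_id`, `sample_id`,
#'   `truth`, `predicted`, `role`).
#' @export
run_repeats <- function(images, metadata, spec, config, repeats = 50L,
                        seed = 1L, tumor_per_normal = 3L,
                        normal_fraction = 0.5) {
  logs <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    exp_seed <- derive_seed(seed, paste0("repeat", i))
    split <- make_split(metadata, tumor_per_normal = tumor_per_normal,
                        normal_fraction = normal_fraction, seed = exp_seed)
    cfg <- config
    cfg$seed <- exp_seed
    model <- build_model(spec, seed = exp_seed)
    model <- cnn_train(model, images[split$train], cfg)
    pred <- predict(model, images[split$validation])
    truth <- images$label[match(split$validation, images$sample_id)]
    logs[[i]] <- data.frame(experiment_id = i, sample_id = split$validation,
                            truth = truth, predicted = unname(pred$label),
                            role = "validation", stringsAsFactors = FALSE)
  }
  do.call(rbind, logs)
}
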