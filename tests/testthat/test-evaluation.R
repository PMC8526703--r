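brca_like_metadata <- function() {
  # mirrors the breast-cancer arm of the study design: 113 normals, 1095 tumors
  data.frame(
    sample_id = c(sprintf("BRCA_N%04d", 1:113), sprintf("BRCA_T%04d", 1:1095)),
    cancer = "BRCA",
    status = c(rep("normal", 113L), rep("tumor", 1095L)),
    stringsAsFactors = FALSE)
}

test_that("the 3:1 split rule picks 171 tumors for 57 training normals", {
  meta <- brca_like_metadata()
  sp <- make_split(meta, seed = 1L)
  train_norm <- sum(grepl("_N", sp$train))
  train_tum <- sum(grepl("_T", sp$train))
  expect_equal(train_norm, 57L)          # half of 113, rounded up
  expect_equal(train_tum, 3L * 57L)      # = 171
})

test_that("split is a partition and is deterministic in the seed", {
  meta <- data.frame(
    sample_id = c(sprintf("n%02d", 1:4), sprintf("t%02d", 1:20)),
    cancer = "CA",
    status = c(rep("normal", 4L), rep("tumor", 20L)))
  s1 <- make_split(meta, seed = 5L)
  s2 <- make_split(meta, seed = 5L)
  s3 <- make_split(meta, seed = 6L)
  expect_identical(s1, s2)
  expect_false(identical(s1$train, s3$train))
  expect_length(intersect(s1$train, s1$validation), 0L)
  expect_setequal(c(s1$train, s1$validation), meta$sample_id)
  expect_equal(sum(grepl("^t", s1$train)), 6L)  # 2 normals -> 6 tumors
})

test_that("split errors name the offending cancer", {
  meta <- data.frame(sample_id = c("n1", "t1", "t2"), cancer = "XX",
                     status = c("normal", "tumor", "tumor"))
  expect_error(make_split(meta, seed = 1L), "XX")
  meta2 <- data.frame(sample_id = c("t1", "t2", "t3"), cancer = "YY",
                      status = "tumor")
  expect_error(make_split(meta2, seed = 1L), "YY")
})

test_that("accuracy is (TP+TN)/total with guarded degenerate input", {
  expect_equal(accuracy(list(TP = 50, TN = 45, FP = 3, FN = 2)), 0.95)
  expect_equal(accuracy(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "no samples")
})

test_that("confusion matrices tally truth vs prediction", {
  log <- make_toy_log()
  cm <- confusion_matrix(log, 1L)
  expect_equal(sum(cm$matrix), 4L)                 # conservation
  expect_equal(cm$matrix["CA", "CB"], 1L)
  expect_equal(cm$matrix["CA", "CA"], 1L)
  expect_equal(cm$matrix["normal", "normal"], 1L)
  # binary collapse: all cancer classes become tumor
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 4L)
  expect_equal(cm$TP, 3L)   # t1 predicted CB still counts as tumor
  expect_equal(cm$TN, 1L)
  expect_error(confusion_matrix(log, 99L), "99")
})

test_that("random prediction logs match a brute-force tally", {
  set.seed(20)
  classes <- c("CA", "CB", "CC", "normal")
  log <- data.frame(experiment_id = 1L, sample_id = sprintf("s%02d", 1:40),
                    truth = sample(classes, 40L, replace = TRUE),
                    predicted = sample(classes, 40L, replace = TRUE),
                    role = "validation")
  cm <- confusion_matrix(log, 1L)
  for (i in classes) for (j in classes)
    expect_equal(cm$matrix[i, j], sum(log$truth == i & log$predicted == j))
  expect_equal(accuracy(cm),
               mean((log$truth == "normal") == (log$predicted == "normal")))
})

test_that("error frequency counts validation appearances per sample", {
  log <- make_toy_log()
  ef <- error_frequency(log)
  t1 <- ef[ef$sample_id == "t1", ]
  expect_equal(t1$times_selected, 3L)
  expect_equal(t1$times_misjudged, 3L)   # CB in exps 1/3, normal in exp 2
  expect_equal(error_frequency(log, "t3")$pct, 0)
  # a sample always misjudged scores 100
  always <- data.frame(experiment_id = 1:40, sample_id = "x", truth = "LUAD",
                       predicted = "LUSC", role = "validation")
  expect_equal(error_frequency(always, "x")$pct, 100)
  expect_true(is.na(error_frequency(log, "ghost")$pct))
})

test_that("per-sample frequencies equal a recount over synthetic logs", {
  set.seed(30)
  ids <- sprintf("s%02d", 1:12)
  log <- do.call(rbind, lapply(1:50, function(e) {
    sel <- sample(ids, 6L)
    data.frame(experiment_id = e, sample_id = sel,
               truth = "CA",
               predicted = sample(c("CA", "CB"), 6L, replace = TRUE,
                                  prob = c(0.8, 0.2)),
               role = "validation")
  }))
  ef <- error_frequency(log)
  for (id in ids) {
    r <- log[log$sample_id == id, ]
    expect_equal(ef$times_selected[ef$sample_id == id], nrow(r))
    expect_equal(ef$pct[ef$sample_id == id],
                 100 * sum(r$predicted != r$truth) / nrow(r))
  }
})

test_that("class similarity averages Pearson r with self-exclusion", {
  genes <- sprintf("g%02d", 1:20)
  set.seed(40)
  x <- stats::setNames(rnorm(20), genes)
  cls <- sapply(1:3, function(i) rnorm(20))
  dimnames(cls) <- list(genes, c("m1", "m2", "m3"))
  got <- class_similarity(x, cls)
  oracle <- mean(apply(cls, 2L, function(y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      ((n - 1) * stats::sd(x) * stats::sd(y))
  }))
  expect_equal(got, oracle, tolerance = 1e-12)
  # identical to every member -> 1; anti-correlated single member -> -1
  same <- matrix(rep(x, 3L), ncol = 3L, dimnames = list(genes, c("a", "b", "c")))
  expect_equal(class_similarity(x, same), 1)
  anti <- matrix(-x, ncol = 1L, dimnames = list(genes, "a"))
  expect_equal(class_similarity(x, anti), -1)
  # excluding self drops the r = 1 term
  with_self <- cbind(same[, 1L, drop = FALSE], cls)
  colnames(with_self)[1L] <- "me"
  expect_equal(class_similarity(x, with_self, self = "me"), oracle,
               tolerance = 1e-12)
})

test_that("zero-variance class members are excluded with a warning", {
  genes <- sprintf("g%02d", 1:10)
  x <- stats::setNames(rnorm(10), genes)
  cls <- cbind(m1 = x, m2 = rep(1, 10))
  rownames(cls) <- genes
  expect_warning(r <- class_similarity(x, cls), "zero-variance")
  expect_equal(r, 1)
})
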