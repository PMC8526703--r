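toy_groups <- function(seed = 11, n_genes = 20L, n = 8L, het = TRUE) {
  set.seed(seed)
  sds <- if (het) exp(rnorm(n_genes, 0, 0.8)) else rep(1, n_genes)
  A <- t(sapply(seq_len(n_genes), function(g) 2^rnorm(n, 6 + g %% 3, sds[g])))
  B <- t(sapply(seq_len(n_genes), function(g) 2^rnorm(n, 6, sds[g])))
  rownames(A) <- rownames(B) <- sprintf("g%02d", seq_len(n_genes))
  list(A = A, B = B)
}

test_that("identical groups give zero fold change and p = 1", {
  g <- toy_groups()
  res <- moderated_t(g$A, g$A)
  expect_equal(res$log2_fc, rep(0, nrow(g$A)))
  expect_equal(res$p_raw, rep(1, nrow(g$A)))
})

test_that("with prior df 0 the statistic is the ordinary pooled t", {
  g <- toy_groups()
  res <- moderated_t(g$A, g$B, prior_df = 0)
  la <- log2(g$A + 1); lb <- log2(g$B + 1)
  ordinary <- vapply(seq_len(nrow(la)), function(i)
    stats::t.test(la[i, ], lb[i, ], var.equal = TRUE)$statistic, numeric(1L))
  expect_lt(max(abs(res$t_mod - ordinary)), 1e-10)
})

test_that("with infinite prior df every gene uses the common variance", {
  g <- toy_groups()
  res <- moderated_t(g$A, g$B, prior_df = Inf)
  la <- log2(g$A + 1); lb <- log2(g$B + 1)
  nA <- ncol(la); nB <- ncol(lb)
  s2 <- (apply(la, 1L, stats::var) * (nA - 1) +
           apply(lb, 1L, stats::var) * (nB - 1)) / (nA + nB - 2)
  s02 <- attr(res, "prior_var")
  expected <- (rowMeans(la) - rowMeans(lb)) / sqrt(s02 * (1 / nA + 1 / nB))
  expect_equal(res$t_mod, unname(expected), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s02, s2[1L])))  # truly common, not per-gene
})

test_that("swapping the groups negates fold change and t", {
  g <- toy_groups(seed = 3)
  ab <- moderated_t(g$A, g$B)
  ba <- moderated_t(g$B, g$A)
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$t_mod, -ba$t_mod)
  expect_equal(ab$p_raw, ba$p_raw)
})

test_that("empirical Bayes fit agrees with limma on both prior branches", {
  skip_if_not_installed("limma")
  for (het in c(TRUE, FALSE)) {
    g <- toy_groups(seed = 11, het = het)
    res <- moderated_t(g$A, g$B)
    design <- cbind(1, c(rep(1, ncol(g$A)), rep(0, ncol(g$B))))
    eb <- limma::eBayes(limma::lmFit(cbind(log2(g$A + 1), log2(g$B + 1)), design))
    expect_equal(attr(res, "prior_df"), eb$df.prior, tolerance = 1e-8)
    expect_equal(attr(res, "prior_var"), eb$s2.prior, tolerance = 1e-8)
    expect_lt(max(abs(res$t_mod - eb$t[, 2L])), 1e-10)
    if (is.finite(eb$df.prior)) {
      expect_lt(max(abs(res$p_raw - eb$p.value[, 2L])), 1e-10)
    } else {
      # with an infinite prior limma caps the total df at the pooled
      # residual df while this package uses df + d0 directly, so the
      # p-values agree only to a few thousandths there
      expect_lt(max(abs(res$p_raw - eb$p.value[, 2L])), 5e-3)
    }
  }
})

test_that("degenerate genes and undersized groups are handled", {
  A <- matrix(5, 3, 3, dimnames = list(c("a", "b", "c"), NULL))
  res <- moderated_t(A, A)
  expect_equal(res$t_mod, rep(0, 3L))
  expect_equal(res$p_raw, rep(1, 3L))
  expect_error(moderated_t(A[, 1L, drop = FALSE], A), "at least 2 samples")
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(adjust_p(rep(1, 5L)), rep(1, 5L))
  expect_equal(adjust_p(0.37), 0.37)
  expect_identical(adjust_p(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(50)
  expect_true(all(adjust_p(p) >= p))
})

test_that("deg_union applies the threshold rule per cancer", {
  rec <- data.frame(
    gene = c("g1", "g2", "g2", "g3"),
    cancer = c("CA", "CA", "CB", "CA"),
    log2_fc = c(1.0, 3.0, 3.0, 0.5),
    p_adj = c(0.005, 0.02, 0.02, 0.001))
  # boundary |log2FC| = 1 (FC = 2) is included; p filter is strict
  expect_equal(deg_union(rec), "g1")
})

test_that("deg_union equals a brute-force double loop on random tables", {
  set.seed(9)
  rec <- data.frame(
    gene = sample(sprintf("g%03d", 1:200), 600, replace = TRUE),
    cancer = sample(c("CA", "CB", "CC"), 600, replace = TRUE),
    log2_fc = rnorm(600, 0, 1.2),
    p_adj = runif(600))
  got <- deg_union(rec, fc_threshold = 2, p_threshold = 0.05)
  oracle <- character(0)
  for (g in unique(rec$gene)) {
    for (cx in unique(rec$cancer)) {
      r <- rec[rec$gene == g & rec$cancer == cx, ]
      if (nrow(r) && any(abs(r$log2_fc) >= 1 & r$p_adj < 0.05))
        oracle <- c(oracle, g)
    }
  }
  expect_setequal(got, unique(oracle))
  # monotonicity: relaxing thresholds never loses genes
  expect_true(all(got %in% deg_union(rec, 1.5, 0.05)))
  expect_true(all(got %in% deg_union(rec, 2, 0.10)))
})

test_that("recall of planted signatures approaches 1 as the shift grows", {
  recalls <- vapply(c(0.5, 4), function(eff) {
    cfg <- synth_config(n_genes = 120L, n_classes = 2L, samples_per_class = 10L,
                        signature_size = 15L, effect_log2fc = eff,
                        noise_sd = 0.5, seed = 77L)
    co <- make_cohort(cfg)
    degs <- deg_union(deg_table(co$expr, co$metadata))
    planted <- unique(unlist(co$signatures))
    mean(planted %in% degs)
  }, numeric(1L))
  expect_lt(recalls[1L], recalls[2L])
  expect_gt(recalls[2L], 0.95)
})
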