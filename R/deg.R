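#' Moderated t-statistics for a two-group comparison
#'
#' Computes per-gene log2 fold changes and empirical-Bayes moderated
#' t-statistics between two groups of non-negative expression values
#' (e.g. tumor vs matched normal). Values are log2(x + 1) transformed; the
#' per-gene pooled residual variance is shrunk toward a common prior fitted
#' by method of moments on the log sample variances, and the moderated t is
#' referred to a t distribution with the augmented degrees of freedom.
#'
#' The shrunken variance is \eqn{\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)}
#' where \eqn{d} is the residual degrees of freedom and \eqn{(d_0, s_0^2)} the
#' fitted prior. With `prior_df = 0` the statistic reduces to the ordinary
#' pooled-variance t; with `prior_df = Inf` every gene uses \eqn{s_0^2}.
#'
#' @param groupA,groupB Numeric matrices (genes x samples) of non-negative
#'   values on the raw scale, with matching row names; each must have at
#'   least 2 columns.
#' @param prior_df Optional fixed prior degrees of freedom \eqn{d_0};
#'   `NULL` (default) fits it from the data.
#' @param log_transform Apply log2(x + 1) before computing means/variances
#'   (default `TRUE`; set `FALSE` if the input is already on the log scale).
#' @return A data frame with columns `gene`, `log2_fc` (mean A minus mean B
#'   on the log2 scale), `t_mod`, `p_raw`, plus attributes `prior_df` and
#'   `prior_var` holding the fitted hyperparameters.
#' @export
moderated_t <- function(groupA, groupB, prior_df = NULL, log_transform = TRUE) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) < 2L || ncol(groupB) < 2L)
    stop("each group needs at least 2 samples")
  if (nrow(groupA) != nrow(groupB))
    stop("groups must cover the same genes")
  if (log_transform) {
    if (any(groupA < 0) || any(groupB < 0)) stop("expression values must be non-negative")
    groupA <- log2(groupA + 1); groupB <- log2(groupB + 1)
  }
  nA <- ncol(groupA); nB <- ncol(groupB)
  df <- nA + nB - 2L

  mA <- rowMeans(groupA); mB <- rowMeans(groupB)
  vA <- rowSums((groupA - mA)^2) / (nA - 1L)
  vB <- rowSums((groupB - mB)^2) / (nB - 1L)
  s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
  fc <- mA - mB

  if (is.null(prior_df)) {
    fit <- fit_f_dist(s2, df)
    d0 <- fit$df_prior; s02 <- fit$var_prior
  } else {
    d0 <- prior_df
    s02 <- if (d0 > 0) fit_f_dist(s2, df)$var_prior else 0
  }

  if (is.infinite(d0)) {
    s_tilde2 <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s_tilde2 <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- df + d0
  }

  se <- sqrt(s_tilde2 * (1 / nA + 1 / nB))
  t_mod <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_raw[se == 0 & fc == 0] <- 1

  out <- data.frame(gene = if (is.null(rownames(groupA))) as.character(seq_len(nrow(groupA))) else rownames(groupA),
                    log2_fc = fc, t_mod = t_mod, p_raw = p_raw,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

# Method-of-moments fit of a scaled F distribution to sample variances:
# s^2 ~ s0^2 F(df, d0), estimated on z = log(s^2) via digamma/trigamma
# moments. Genes with zero variance are excluded from the fit.
fit_f_dist <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(df_prior = Inf, var_prior = if (length(s2)) s2 else 0))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # log-variances no more dispersed than chi-square sampling noise: all
    # genes share one variance, estimated by the plain mean
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(df_prior = d0, var_prior = s02)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing branch.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone in rank and capped at 1.
#'
#' @param p_raw Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_p <- function(p_raw) {
  if (length(p_raw) == 0L) return(numeric(0))
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Per-cancer differential expression table
#'
#' Runs [moderated_t()] once per cancer type (tumors of that cancer vs its
#' normals) and applies [adjust_p()] within each comparison.
#'
#' @param expr Genes x samples numeric matrix of non-negative values, with
#'   gene row names and sample column names.
#' @param metadata Data frame with columns `sample_id`, `cancer`, `status`
#'   (`"tumor"` or `"normal"`).
#' @param ... Passed to [moderated_t()].
#' @return A data frame with columns `gene`, `cancer`, `log2_fc`, `t_mod`,
#'   `p_raw`, `p_adj`.
#' @export
deg_table <- function(expr, metadata, ...) {
  stopifnot(all(c("sample_id", "cancer", "status") %in% names(metadata)))
  missing <- setdiff(metadata$sample_id, colnames(expr))
  if (length(missing)) stop("samples absent from expression matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  cancers <- sort(unique(metadata$cancer))
  res <- lapply(cancers, function(cx) {
    tum <- metadata$sample_id[metadata$cancer == cx & metadata$status == "tumor"]
    nor <- metadata$sample_id[metadata$cancer == cx & metadata$status == "normal"]
    tab <- moderated_t(expr[, tum, drop = FALSE], expr[, nor, drop = FALSE], ...)
    tab$cancer <- cx
    tab$p_adj <- adjust_p(tab$p_raw)
    tab[, c("gene", "cancer", "log2_fc", "t_mod", "p_raw", "p_adj")]
  })
  do.call(rbind, res)
}

#' Union differentially-expressed-gene filter
#'
#' A gene is a DEG if, in at least one cancer type, its absolute fold change
#' reaches `fc_threshold` (inclusive) and its adjusted p-value is below
#' `p_threshold` (exclusive). Fold change is compared on the log2 scale:
#' `|FC| >= 2` is `|log2_fc| >= 1`.
#'
#' @param records DEG table as produced by [deg_table()] (needs columns
#'   `gene`, `log2_fc`, `p_adj`).
#' @param fc_threshold Fold-change threshold on the linear scale (default 2).
#' @param p_threshold Adjusted-p threshold (default 0.01).
#' @return Sorted character vector of DEG symbols.
#' @export
deg_union <- function(records, fc_threshold = 2, p_threshold = 0.01) {
  if (nrow(records) == 0L) return(character(0))
  hit <- abs(records$log2_fc) >= log2(fc_threshold) & records$p_adj < p_threshold
  sort(unique(records$gene[hit]))
}
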