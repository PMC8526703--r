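#' Configuration for synthetic cohorts
#'
#' Bundles the parameters of the synthetic data generator: a random PPI-like
#' graph plus a multi-class expression cohort with class-specific
#' differential signatures planted on top of a lognormal baseline, and a
#' clinical table. Defaults produce a small, well-separated 3-class design
#' whose signal strength (4 log2 units, i.e. 16-fold) and noise (0.5 sd on
#' the log2 scale) are comfortably inside what bulk RNA-Seq tumor/normal
#' comparisons show for strong markers.
#'
#' @param n_genes Number of genes (>= 10); symbols are `g0001`, `g0002`, ...
#' @param n_classes Number of tumor classes ("cancer types").
#' @param samples_per_class Tumor samples per class.
#' @param normals_per_class Normal samples per class (default: one third of
#'   the tumors, rounded up, echoing typical TCGA normal/tumor imbalance).
#' @param signature_size Genes planted as differential per class.
#' @param effect_log2fc Mean shift (log2 units) applied to a class's
#'   signature genes in its tumors.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param graph_model `"erdos_renyi"`, `"scale_free"`, or
#'   `"planted_partition"` (signatures become dense communities).
#' @param edge_density Edge probability (Erdos-Renyi; within-community
#'   probability for the planted partition is 10x this, capped at 0.5).
#' @param attachment Edges per new vertex for the scale-free model.
#' @param shared_fraction Fraction of signature genes the first two classes
#'   share (0 = disjoint signatures; 0.8 emulates histologically related
#'   tumor types that confuse classifiers).
#' @param death_rate Probability a tumor patient is recorded dead.
#' @param seed Integer seed; fully determines all generated output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 200L, n_classes = 3L,
                         samples_per_class = 15L, normals_per_class = NULL,
                         signature_size = 20L, effect_log2fc = 4,
                         noise_sd = 0.5,
                         graph_model = c("erdos_renyi", "scale_free",
                                         "planted_partition"),
                         edge_density = 0.05, attachment = 3L,
                         shared_fraction = 0, death_rate = 0.3, seed = 1L) {
  graph_model <- match.arg(graph_model)
  if (is.null(normals_per_class))
    normals_per_class <- ceiling(samples_per_class / 3)
  stopifnot(n_genes >= 10L, n_classes >= 1L, samples_per_class >= 1L,
            normals_per_class >= 1L,
            signature_size * n_classes <= n_genes,
            death_rate >= 0, death_rate <= 1,
            shared_fraction >= 0, shared_fraction <= 1,
            noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 normals_per_class = as.integer(normals_per_class),
                 signature_size = as.integer(signature_size),
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 graph_model = graph_model, edge_density = edge_density,
                 attachment = as.integer(attachment),
                 shared_fraction = shared_fraction,
                 death_rate = death_rate, seed = as.integer(seed)),
            class = "synth_config")
}

# Signature gene indices per class, honoring the shared fraction between
# classes 1 and 2. Blocks are deterministic (leading genes), which also
# lets the planted-partition graph align its communities with them.
signature_genes <- function(config) {
  k <- config$signature_size
  sig <- lapply(seq_len(config$n_classes), function(c) ((c - 1L) * k + 1L):(c * k))
  if (config$shared_fraction > 0 && config$n_classes >= 2L) {
    n_shared <- round(k * config$shared_fraction)
    if (n_shared > 0) sig[[2L]][seq_len(n_shared)] <- sig[[1L]][seq_len(n_shared)]
  }
  lapply(sig, function(idx) sprintf("g%04d", idx))
}

#' Generate a random PPI-like graph
#'
#' Simple, undirected, connected graph on synthetic gene symbols. The
#' planted-partition model puts each class signature into its own dense
#' community (mirroring the assumption that functionally related genes
#' cluster in the interaction network). If the sampled graph is
#' disconnected, bridging edges between components are added (logged).
#'
#' @param config A [synth_config()].
#' @return A connected [igraph::graph] with vertex names `g0001`, ...
#' @export
make_graph <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_genes
  with_seed(derive_seed(config$seed, "graph"), {
    g <- switch(config$graph_model,
      erdos_renyi = igraph::sample_gnp(n, config$edge_density),
      scale_free = igraph::sample_pa(n, m = config$attachment,
                                     directed = FALSE),
      planted_partition = {
        sig <- signature_genes(config)
        member <- rep(config$n_classes + 1L, n)          # background block
        for (c in seq_along(sig))
          member[as.integer(sub("g", "", sig[[c]]))] <- c
        blocks <- sort(unique(member))
        p_in <- min(10 * config$edge_density, 0.5)
        pm <- matrix(config$edge_density, length(blocks), length(blocks))
        diag(pm) <- p_in
        ord <- order(member)
        gg <- igraph::sample_sbm(n, pref.matrix = pm,
                                 block.sizes = as.vector(table(member)))
        # sample_sbm fills blocks contiguously; send sbm vertex j back to
        # the gene it stands for (ord[j])
        igraph::permute(gg, ord)
      })
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(n))
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      message("bridging ", comp$no, " components to connect the graph")
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1L], integer(1L))
      for (i in seq_len(length(reps) - 1L))
        g <- igraph::add_edges(g, c(reps[i], reps[i + 1L]))
    }
    g
  })
}

#' Generate a synthetic expression cohort with planted signatures
#'
#' Baseline expression is lognormal (per-gene log2 mean ~ N(6, 2), matching
#' the right-skewed scale of RSEM-style RNA-Seq quantifications at toy
#' scale). Tumors of class c shift their signature genes up by
#' `effect_log2fc` on the log2 scale; normals are unshifted. Gaussian noise
#' (sd `noise_sd`) is added on the log2 scale and values are back-
#' transformed with negatives clipped to 0. The clinical table assigns
#' death with probability `death_rate` and survival days uniform on
#' \[0, 3650\].
#'
#' @param config A [synth_config()].
#' @param graph Optional graph from [make_graph()] (only used to check gene
#'   names agree; the cohort itself does not depend on it).
#' @return A list with `expr` (genes x samples matrix, raw scale),
#'   `metadata` (`sample_id`, `cancer`, `status`), `clinical` (`sample_id`,
#'   `vital_status`, `survival_days`), and `signatures` (list of planted
#'   gene sets per class).
#' @export
make_cohort <- function(config, graph = NULL) {
  stopifnot(inherits(config, "synth_config"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  if (!is.null(graph))
    stopifnot(identical(sort(igraph::V(graph)$name), genes))
  sig <- signature_genes(config)
  classes <- sprintf("C%02d", seq_len(config$n_classes))

  n_tum <- config$samples_per_class
  n_nor <- config$normals_per_class
  metadata <- do.call(rbind, lapply(seq_along(classes), function(c) {
    data.frame(
      sample_id = c(sprintf("%s_T%03d", classes[c], seq_len(n_tum)),
                    sprintf("%s_N%03d", classes[c], seq_len(n_nor))),
      cancer = classes[c],
      status = c(rep("tumor", n_tum), rep("normal", n_nor)),
      stringsAsFactors = FALSE)
  }))

  with_seed(derive_seed(config$seed, "cohort"), {
    baseline <- stats::rnorm(config$n_genes, mean = 6, sd = 2)
    names(baseline) <- genes
    log2expr <- matrix(baseline, nrow = config$n_genes,
                       ncol = nrow(metadata),
                       dimnames = list(genes, metadata$sample_id))
    for (c in seq_along(classes)) {
      tum <- metadata$sample_id[metadata$cancer == classes[c] &
                                  metadata$status == "tumor"]
      log2expr[sig[[c]], tum] <- log2expr[sig[[c]], tum] + config$effect_log2fc
    }
    log2expr <- log2expr + matrix(stats::rnorm(length(log2expr),
                                               sd = config$noise_sd),
                                  nrow = nrow(log2expr))
    expr <- pmax(2^log2expr - 1, 0)

    tumors <- metadata$sample_id[metadata$status == "tumor"]
    clinical <- data.frame(
      sample_id = tumors,
      vital_status = ifelse(stats::runif(length(tumors)) < config$death_rate,
                            "dead", "alive"),
      survival_days = round(stats::runif(length(tumors), 0, 3650)),
      stringsAsFactors = FALSE)

    list(expr = expr, metadata = metadata, clinical = clinical,
         signatures = stats::setNames(sig, classes))
  })
}

#' Write a synthetic cohort and graph to TSV files
#'
#' Emits `expression.tsv` (first column `gene`), `metadata.tsv`,
#' `clinical.tsv` and `edges.tsv` into a directory.
#'
#' @param cohort Output of [make_cohort()].
#' @param graph Output of [make_graph()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_df <- data.frame(gene = rownames(cohort$expr), cohort$expr,
                        check.names = FALSE)
  utils::write.table(expr_df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(geneA = edges[, 1L], geneB = edges[, 2L]),
                     file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
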