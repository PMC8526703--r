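#' Read a protein-protein interaction edge list
#'
#' Reads a two-column, tab-separated edge list of gene symbols and returns a
#' simple undirected graph. Self-loops and duplicate pairs (in either
#' orientation) are dropped; an optional identifier map is applied before
#' deduplication so that synonymous symbols collapse onto one node.
#'
#' A header line is assumed only when the first token is literally `geneA` or
#' the line starts with `#`. Gene symbols are treated as case-sensitive
#' strings.
#'
#' @param path Path to a TSV file with at least two columns (`geneA`,
#'   `geneB`); extra columns are ignored.
#' @param id_map Optional two-column data frame (`from`, `to`) mapping input
#'   symbols to canonical symbols. Symbols absent from the map are kept
#'   verbatim.
#' @return An undirected [igraph::graph] with vertex `name` attributes. The
#'   load report (edges read, duplicates, self-loops, malformed lines, mapped
#'   symbols) is attached as the graph attribute `load_report` and emitted
#'   with [message()].
#' @export
load_edge_list <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no edges: file '", path, "' is empty")

  # header iff first token is literally 'geneA' or the line is '#'-prefixed
  repeat {
    if (length(lines) == 0L) stop("no edges: file '", path, "' has only header lines")
    first_tok <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]][1L]
    if (identical(first_tok, "geneA") || startsWith(lines[[1L]], "#")) {
      lines <- lines[-1L]
    } else break
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 2L && nzchar(f[1L]) && nzchar(f[2L]),
               logical(1L))
  n_malformed <- sum(!ok)
  if (n_malformed > 0L) {
    warning(n_malformed, " malformed line(s) skipped in '", path, "'")
  }
  fields <- fields[ok]
  if (length(fields) == 0L) stop("no edges: no well-formed lines in '", path, "'")

  a <- vapply(fields, `[`, character(1L), 1L)
  b <- vapply(fields, `[`, character(1L), 2L)

  n_mapped <- 0L
  if (!is.null(id_map)) {
    stopifnot(ncol(id_map) >= 2L)
    map <- stats::setNames(as.character(id_map[[2L]]), as.character(id_map[[1L]]))
    hit_a <- a %in% names(map)
    hit_b <- b %in% names(map)
    n_mapped <- sum(hit_a) + sum(hit_b)
    a[hit_a] <- map[a[hit_a]]
    b[hit_b] <- map[b[hit_b]]
  }

  n_read <- length(a)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  # canonical (sorted) orientation so A-B and B-A collapse
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0L) stop("no edges: all records were self-loops")

  g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  report <- list(edges_read = n_read, duplicates = n_dup,
                 self_loops = n_self, malformed = n_malformed,
                 symbols_mapped = n_mapped)
  g <- igraph::set_graph_attr(g, "load_report", report)
  message(sprintf(
    "loaded %d edges (%d records read; %d duplicate, %d self-loop, %d malformed dropped; %d symbols mapped)",
    igraph::ecount(g), n_read, n_dup, n_self, n_malformed, n_mapped))
  g
}

#' Maximum connected subnetwork induced by a gene set
#'
#' Induces the subgraph of `graph` on `genes` and returns its largest
#' connected component by node count. Ties are broken deterministically in
#' favor of the component containing the lexicographically smallest gene
#' symbol.
#'
#' @param graph An undirected [igraph::graph] with named vertices.
#' @param genes Character vector of gene symbols (non-empty).
#' @return The largest connected component as an igraph object. When the
#'   induced subgraph has no edges, a single-vertex graph on the smallest
#'   matching gene (or smallest requested gene if none match) is returned
#'   with a warning.
#' @export
max_subnetwork <- function(graph, genes) {
  if (length(genes) == 0L) stop("'genes' must be non-empty")
  genes <- unique(as.character(genes))
  present <- intersect(genes, igraph::V(graph)$name)
  if (length(present) == 0L) {
    warning("no requested gene is present in the graph; returning a single-vertex graph")
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(min(genes)))
  }
  sub <- igraph::induced_subgraph(graph, present)
  if (igraph::ecount(sub) == 0L) {
    warning("induced subgraph has no edges; returning a single-vertex graph")
    return(igraph::induced_subgraph(sub, min(present)))
  }
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest member symbol decides among equally-sized components
    anchor <- vapply(best, function(k) {
      min(igraph::V(sub)$name[comp$membership == k])
    }, character(1L))
    best <- best[order(anchor)][1L]
  }
  igraph::induced_subgraph(sub, igraph::V(sub)$name[comp$membership == best])
}
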