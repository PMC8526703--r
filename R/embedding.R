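#' Graph Laplacian of a PPI network
#'
#' Builds the combinatorial Laplacian L = D - A of an undirected simple
#' graph: off-diagonal entries are -1 where two genes interact and 0
#' otherwise, and each diagonal entry is the node degree. Rows sum to zero
#' and the matrix is symmetric positive semidefinite.
#'
#' @param graph An undirected [igraph::graph] with named vertices.
#' @return A list of class `laplacian_spec` with elements `node_order`
#'   (sorted gene symbols) and `L` (dense symmetric matrix in that order).
#' @export
build_laplacian <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph is empty")
  node_order <- sort(igraph::V(graph)$name)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE))
  A <- A[node_order, node_order, drop = FALSE]
  A[A > 0] <- 1
  L <- diag(rowSums(A), n) - A
  dimnames(L) <- list(node_order, node_order)
  structure(list(node_order = node_order, L = L), class = "laplacian_spec")
}

#' Spectral coordinates from the two smallest non-zero eigenpairs
#'
#' Eigendecomposes the Laplacian and takes the eigenvectors of the smallest
#' and second-smallest non-zero eigenvalues as x and y coordinates (the
#' first being the Fiedler vector). Eigenvectors are unit-norm with the sign
#' fixed so the largest-magnitude entry is positive (ties broken by the
#' earliest node in `node_order`), making the layout reproducible.
#'
#' @param spec A `laplacian_spec` from [build_laplacian()].
#' @param tol Relative zero tolerance for eigenvalues; the absolute cutoff is
#'   `tol * max(degree)`.
#' @return A list with `coords` (two-column matrix `x`, `y`, rownames =
#'   genes) and `eigenvalues` (the selected pair, ascending).
#' @export
fiedler_coords <- function(spec, tol = 1e-8) {
  L <- spec$L
  n <- nrow(L)
  if (n < 3L) stop("need at least 3 nodes for two non-zero eigenpairs")
  eig <- eigen(L, symmetric = TRUE)
  vals <- rev(eig$values)              # ascending
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  cutoff <- tol * max(diag(L), 1)
  zero <- which(vals <= cutoff)
  if (length(zero) > 1L)
    stop("graph is disconnected (", length(zero),
         " numerically-zero eigenvalues); extract the maximum connected ",
         "subnetwork first (max_subnetwork)")
  nz <- which(vals > cutoff)
  if (length(nz) < 2L) stop("fewer than two non-zero eigenvalues")
  sel <- nz[1:2]
  v1 <- fix_sign(vecs[, sel[1L]])
  v2 <- fix_sign(vecs[, sel[2L]])
  coords <- cbind(x = v1, y = v2)
  rownames(coords) <- spec$node_order
  list(coords = coords, eigenvalues = vals[sel])
}

# Sign convention: largest-magnitude entry positive; on magnitude ties the
# earliest entry decides.
fix_sign <- function(v) {
  i <- which(abs(v) == max(abs(v)))[1L]
  if (v[i] < 0) -v else v
}

#' Bin spectral coordinates into a square grid
#'
#' Each axis is min-max scaled to \[0, 1\] and cut into `grid_size` equal
#' bins; the maximum falls in the last bin. A constant axis maps every node
#' to bin 0.
#'
#' @param coords Two-column coordinate matrix (rownames = genes).
#' @param grid_size Number of cells per side, G (default 100).
#' @return Integer matrix with columns `row`, `col` (0-based; row = y bin,
#'   col = x bin), rownames = genes.
#' @export
bin_to_grid <- function(coords, grid_size = 100L) {
  stopifnot(nrow(coords) >= 1L, grid_size >= 1L)
  bin_axis <- function(u) {
    r <- range(u)
    if (r[1L] == r[2L]) return(rep(0L, length(u)))
    scaled <- (u - r[1L]) / (r[2L] - r[1L])
    pmin(as.integer(floor(scaled * grid_size)), grid_size - 1L)
  }
  cells <- cbind(row = bin_axis(coords[, 2L]), col = bin_axis(coords[, 1L]))
  rownames(cells) <- rownames(coords)
  cells
}

#' Embed a connected gene network into a G x G grid
#'
#' Convenience wrapper: Laplacian, two smallest non-zero eigenpairs, grid
#' binning.
#'
#' @inheritParams build_laplacian
#' @inheritParams bin_to_grid
#' @return An object of class `grid_embedding`: list with `grid_size`,
#'   `coords`, `cells`, `eigenvalues`.
#' @export
grid_embedding <- function(graph, grid_size = 100L) {
  spec <- build_laplacian(graph)
  fc <- fiedler_coords(spec)
  cells <- bin_to_grid(fc$coords, grid_size)
  structure(list(grid_size = as.integer(grid_size), coords = fc$coords,
                 cells = cells, eigenvalues = fc$eigenvalues),
            class = "grid_embedding")
}

#' @export
print.grid_embedding <- function(x, ...) {
  occ <- nrow(unique(x$cells))
  cat(sprintf("grid_embedding: %d genes on a %dx%d grid (%d occupied cells)\n",
              nrow(x$coords), x$grid_size, x$grid_size, occ))
  cat(sprintf("  eigenvalues: %.6g, %.6g\n", x$eigenvalues[1L], x$eigenvalues[2L]))
  invisible(x)
}

#' Write / read a grid embedding as TSV
#'
#' Plain-text round-trip: columns `gene x y row col` with `grid_size`,
#' `lambda1`, `lambda2` stored as `#`-comment header lines.
#'
#' @param embedding A `grid_embedding`.
#' @param path Output/input file path.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# grid_size=%d", embedding$grid_size),
               sprintf("# lambda1=%.17g", embedding$eigenvalues[1L]),
               sprintf("# lambda2=%.17g", embedding$eigenvalues[2L]),
               "gene\tx\ty\trow\tcol"), con)
  df <- data.frame(gene = rownames(embedding$coords),
                   x = sprintf("%.17g", embedding$coords[, 1L]),
                   y = sprintf("%.17g", embedding$coords[, 2L]),
                   row = embedding$cells[, "row"], col = embedding$cells[, "col"])
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  hdr <- readLines(path, n = 3L)
  get_num <- function(key) as.numeric(sub(paste0("# ", key, "="), "", hdr[grepl(key, hdr)]))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  coords <- cbind(x = df$x, y = df$y)
  cells <- cbind(row = as.integer(df$row), col = as.integer(df$col))
  rownames(coords) <- rownames(cells) <- df$gene
  structure(list(grid_size = as.integer(get_num("grid_size")), coords = coords,
                 cells = cells,
                 eigenvalues = c(get_num("lambda1"), get_num("lambda2"))),
            class = "grid_embedding")
}
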