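# Fixtures built in code: no data files.

# Linearly-separable image set: each class lights up its own quadrant of the
# grid on a dim noise floor. Supports 2 or 4 classes.
make_quadrant_set <- function(n_per_class, G = 32L, n_classes = 2L,
                              noise = 0.1, seed = 1L) {
  stopifnot(n_classes %in% c(2L, 4L))
  set.seed(seed)
  n <- n_classes * n_per_class
  px <- array(0, c(G, G, n))
  lab <- character(n)
  h <- G %/% 2L
  corners <- list(list(1:h, 1:h), list((h + 1L):G, (h + 1L):G),
                  list(1:h, (h + 1L):G), list((h + 1L):G, 1:h))
  for (i in seq_len(n)) {
    cls <- (i - 1L) %% n_classes + 1L
    img <- matrix(stats::runif(G * G, 0, noise), G, G)
    img[corners[[cls]][[1L]], corners[[cls]][[2L]]] <-
      img[corners[[cls]][[1L]], corners[[cls]][[2L]]] + 0.8
    px[, , i] <- pmin(img, 1)
    lab[i] <- paste0("K", cls)
  }
  structure(list(pixels = px, sample_id = sprintf("s%03d", seq_len(n)),
                 label = lab),
            class = "network_image_set")
}

# Small connected random graph with named vertices.
make_test_graph <- function(n = 30L, p = 0.15, seed = 4L) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Write a temporary edge-list TSV and return its path.
write_edge_file <- function(lines, header = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

# A tiny grid embedding with known cell assignments, for imaging tests.
make_toy_embedding <- function() {
  coords <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 0), d = c(1, 1))
  colnames(coords) <- c("x", "y")
  structure(list(grid_size = 2L, coords = coords,
                 cells = bin_to_grid(coords, 2L),
                 eigenvalues = c(1, 2)),
            class = "grid_embedding")
}

# Prediction log covering several experiments, built by hand.
make_toy_log <- function() {
  data.frame(
    experiment_id = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
    sample_id = c("t1", "t2", "t3", "n1", "t1", "t2", "n1", "t1", "t3"),
    truth = c("CA", "CA", "CB", "normal", "CA", "CA", "normal", "CA", "CB"),
    predicted = c("CB", "CA", "CB", "normal", "normal", "CA", "CA", "CB", "CB"),
    role = "validation", stringsAsFactors = FALSE)
}
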