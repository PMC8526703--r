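#' Paint one expression profile onto a grid embedding
#'
#' Produces a G x G network image: each occupied grid cell holds the
#' arithmetic mean of the (log2(x + 1)-transformed) expression of the genes
#' binned there; cells with no mapped gene are exactly 0. When several genes
#' share a cell their values are averaged. Genes present in the profile but
#' absent from the embedding are ignored (count reported); embedded genes
#' missing from the profile contribute nothing to their cell's mean.
#'
#' @param embedding A `grid_embedding` from [grid_embedding()].
#' @param profile Named numeric vector of non-negative expression values
#'   (names = gene symbols); must cover at least one embedded gene.
#' @param normalize Rescale pixels so the maximum occupied value is 1
#'   (default `TRUE`); an all-zero image stays all-zero.
#' @param log_transform Apply log2(x + 1) before averaging (default `TRUE`).
#' @param sample_id,label Optional identifiers stored on the image.
#' @return An object of class `network_image`: list with `sample_id`,
#'   `pixels` (G x G matrix), `label`, and attribute `n_ignored` (profile
#'   genes not in the embedding).
#' @export
render_image <- function(embedding, profile, normalize = TRUE,
                         log_transform = TRUE, sample_id = NA_character_,
                         label = NA_character_) {
  stopifnot(inherits(embedding, "grid_embedding"))
  if (any(profile < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  genes <- intersect(rownames(embedding$cells), names(profile))
  n_ignored <- length(profile) - length(genes)
  if (length(genes) == 0L) stop("profile shares no gene with the embedding")

  vals <- profile[genes]
  if (log_transform) vals <- log2(vals + 1)
  G <- embedding$grid_size
  cells <- embedding$cells[genes, , drop = FALSE]
  idx <- cells[, "row"] + 1L + cells[, "col"] * G   # linear index into G x G

  pixels <- matrix(0, G, G)
  sums <- tapply(vals, idx, sum)
  counts <- tapply(vals, idx, length)
  pixels[as.integer(names(sums))] <- sums / counts
  if (normalize) {
    mx <- max(pixels)
    if (mx > 0) pixels <- pixels / mx
  }
  structure(list(sample_id = sample_id, pixels = pixels, label = label,
                 n_ignored = n_ignored),
            class = "network_image")
}

#' Render network images for a whole cohort
#'
#' One image per metadata row, in metadata order. Tumor samples are labeled
#' with their cancer type and normals with `"normal"`.
#'
#' @inheritParams render_image
#' @param expr Genes x samples numeric matrix (raw scale).
#' @param metadata Data frame with `sample_id`, `cancer`, `status`; sample
#'   ids must be unique and present in `expr`.
#' @return An object of class `network_image_set`: list with `pixels`
#'   (G x G x n array), `sample_id`, `label`.
#' @export
render_cohort <- function(embedding, expr, metadata, normalize = TRUE,
                          log_transform = TRUE) {
  stopifnot(all(c("sample_id", "cancer", "status") %in% names(metadata)))
  ids <- as.character(metadata$sample_id)
  if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  missing <- setdiff(ids, colnames(expr))
  if (length(missing)) stop("sample missing from expression matrix: ", missing[1L])
  labels <- ifelse(metadata$status == "normal", "normal", as.character(metadata$cancer))

  G <- embedding$grid_size
  pixels <- array(0, dim = c(G, G, length(ids)))
  for (i in seq_along(ids)) {
    img <- render_image(embedding, expr[, ids[i]], normalize = normalize,
                        log_transform = log_transform,
                        sample_id = ids[i], label = labels[i])
    pixels[, , i] <- img$pixels
  }
  structure(list(pixels = pixels, sample_id = ids, label = labels),
            class = "network_image_set")
}

#' @export
print.network_image_set <- function(x, ...) {
  cat(sprintf("network_image_set: %d images of %dx%d\n",
              length(x$sample_id), dim(x$pixels)[1L], dim(x$pixels)[2L]))
  print(table(x$label))
  invisible(x)
}

#' Subset a network image set
#'
#' @param x A `network_image_set`.
#' @param i Index vector (positions, logicals, or sample ids).
#' @param ... Ignored.
#' @export
`[.network_image_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_id)
  structure(list(pixels = x$pixels[, , i, drop = FALSE],
                 sample_id = x$sample_id[i], label = x$label[i]),
            class = "network_image_set")
}

#' Write a cohort of network images to disk
#'
#' One tab-separated G x G matrix file per sample, plus a manifest TSV with
#' columns `sample_id`, `label`, `path`.
#'
#' @param images A `network_image_set`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file, invisibly.
#' @export
write_images <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(images$sample_id, ".tsv"))
  for (i in seq_along(paths)) {
    utils::write.table(images$pixels[, , i], paths[i], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(sample_id = images$sample_id, label = images$label,
                         path = paths)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}
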