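#' Specify the network-image CNN architecture
#'
#' The classifier takes a single-channel G x G image through three valid
#' (unpadded) convolution stages — 64 kernels of 5x5, 3x3 and 3x3 by default
#' — each followed by ReLU and a 2x2 stride-2 max pooling, then flattens the
#' feature maps into a ReLU multilayer head (1000, 800, 60 neurons) with a
#' softmax output over the classes. With G = 100 the spatial side evolves
#' 100 -> 96 -> 48 -> 46 -> 23 -> 21 -> 11, so the flattened feature vector
#' has length 11 * 11 * 64 = 7744. Reproducing the final side of 11 requires
#' ceil-mode pooling (odd sides round up); floor mode ends at side 10.
#'
#' @param grid_size Input side length G (>= 16 for the default stack).
#' @param classes Number of output classes (normal + cancer types).
#' @param conv List of `c(kernels, size)` pairs, one per convolution stage.
#' @param hidden Sizes of the fully-connected hidden layers.
#' @param pool_mode `"ceil"` (default) or `"floor"` for odd-sided pooling.
#' @return An object of class `cnn_spec` with the per-stage shape chain
#'   (`shapes`), flattened length (`flat`) and parameter count (`n_params`).
#' @export
cnn_spec <- function(grid_size = 100L, classes = 12L,
                     conv = list(c(64L, 5L), c(64L, 3L), c(64L, 3L)),
                     hidden = c(1000L, 800L, 60L),
                     pool_mode = c("ceil", "floor")) {
  pool_mode <- match.arg(pool_mode)
  s <- as.integer(grid_size)
  if (s < 1L) stop("grid_size must be positive")
  in_ch <- 1L
  shapes <- list()
  for (j in seq_along(conv)) {
    k <- conv[[j]][2L]; nk <- conv[[j]][1L]
    s_conv <- s - k + 1L
    if (s_conv < 1L)
      stop(sprintf("convolution stage %d: input side %d is smaller than kernel %d",
                   j, s, k))
    s_pool <- if (pool_mode == "ceil") (s_conv + 1L) %/% 2L else s_conv %/% 2L
    if (s_pool < 1L)
      stop(sprintf("pooling stage %d: conv output side %d pools to zero", j, s_conv))
    shapes[[j]] <- c(conv_side = s_conv, pool_side = s_pool, channels = nk)
    s <- s_pool
    in_ch <- nk
  }
  flat <- s * s * in_ch
  sizes <- c(flat, hidden, classes)
  n_params <- 0L
  in_ch <- 1L
  for (j in seq_along(conv)) {
    n_params <- n_params + conv[[j]][2L]^2 * in_ch * conv[[j]][1L] + conv[[j]][1L]
    in_ch <- conv[[j]][1L]
  }
  n_params <- n_params + sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
  structure(list(grid_size = as.integer(grid_size), classes = as.integer(classes),
                 conv = conv, hidden = as.integer(hidden),
                 pool_mode = pool_mode, shapes = shapes,
                 final_side = s, flat = flat, n_params = n_params),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("cnn_spec: %dx%d input, %d classes, %s-mode pooling\n",
              x$grid_size, x$grid_size, x$classes, x$pool_mode))
  for (j in seq_along(x$shapes)) {
    sh <- x$shapes[[j]]
    cat(sprintf("  stage %d: conv %dx%d -> side %d, pool -> side %d (%d maps)\n",
                j, x$conv[[j]][2L], x$conv[[j]][2L], sh["conv_side"],
                sh["pool_side"], sh["channels"]))
  }
  cat(sprintf("  flatten: %d; hidden: %s; parameters: %d\n",
              x$flat, paste(x$hidden, collapse = ", "), x$n_params))
  invisible(x)
}

#' Instantiate a CNN with randomly initialized weights
#'
#' He-style initialization (`sd = sqrt(2 / fan_in)`); all randomness is
#' drawn from R's RNG under `seed`, so models are reproducible.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_model` (spec + weight list).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  with_seed(seed, {
    conv_W <- list(); conv_b <- list()
    in_ch <- 1L
    for (j in seq_along(spec$conv)) {
      k <- spec$conv[[j]][2L]; nk <- spec$conv[[j]][1L]
      fan_in <- k * k * in_ch
      conv_W[[j]] <- matrix(stats::rnorm(fan_in * nk, sd = sqrt(2 / fan_in)),
                            fan_in, nk)
      conv_b[[j]] <- rep(0, nk)
      in_ch <- nk
    }
    sizes <- c(spec$flat, spec$hidden, spec$classes)
    dense_W <- list(); dense_b <- list()
    for (j in seq_len(length(sizes) - 1L)) {
      dense_W[[j]] <- matrix(stats::rnorm(sizes[j] * sizes[j + 1L],
                                          sd = sqrt(2 / sizes[j])),
                             sizes[j], sizes[j + 1L])
      dense_b[[j]] <- rep(0, sizes[j + 1L])
    }
    structure(list(spec = spec,
                   weights = list(conv_W = conv_W, conv_b = conv_b,
                                  dense_W = dense_W, dense_b = dense_b),
                   class_levels = NULL),
              class = "cnn_model")
  })
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed controlling initialization and shuffling.
#' @param test_fraction Fraction held out (stratified by class) for the
#'   per-epoch test-accuracy curve (default 0.25).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                         seed = 1L, test_fraction = 0.25) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            test_fraction >= 0, test_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 test_fraction = test_fraction),
            class = "train_config")
}

kernel_sizes <- function(spec) vapply(spec$conv, `[`, integer(1L), 2L)

#' Train the CNN on labeled network images
#'
#' Minimizes categorical cross-entropy with Adam. The input set is split
#' (stratified by class) into training and test parts per
#' `config$test_fraction`; accuracy on both is recorded after every epoch.
#' Fully deterministic given `config$seed`.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param images A `network_image_set` with at least two classes.
#' @param config A [train_config()].
#' @return The trained `cnn_model`, with `history` (data frame `epoch`,
#'   `train_acc`, `test_acc`, `loss`) and `class_levels` attached.
#' @export
cnn_train <- function(model, images, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(images, "network_image_set"))
  labels <- images$label
  if (any(is.na(labels))) stop("every image must have a label")
  levels <- sort(unique(labels))
  if (length(levels) < 2L) stop("training requires at least 2 classes")
  if (length(levels) > model$spec$classes)
    stop("more classes in data than in the model spec")
  y <- match(labels, levels) - 1L
  G <- dim(images$pixels)[1L]
  if (G != model$spec$grid_size) stop("image size does not match model input")

  w <- model$weights
  ks <- kernel_sizes(model$spec)
  ceil_pool <- model$spec$pool_mode == "ceil"

  with_seed(config$seed, {
    # stratified train/test split
    test_idx <- integer(0)
    for (lv in levels) {
      members <- which(labels == lv)
      n_test <- floor(length(members) * config$test_fraction)
      if (n_test > 0L) test_idx <- c(test_idx, sample(members, n_test))
    }
    train_idx <- setdiff(seq_along(labels), test_idx)

    adam <- list(m = rapply(w, function(x) x * 0, how = "replace"),
                 v = rapply(w, function(x) x * 0, how = "replace"), t = 0L)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    history <- data.frame(epoch = seq_len(config$epochs), train_acc = NA_real_,
                          test_acc = NA_real_, loss = NA_real_)

    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(train_idx)
      n_correct <- 0L; loss_sum <- 0
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      for (batch in batches) {
        res <- cnn_batch_cpp(images$pixels[, , batch, drop = FALSE],
                             y[batch], w$conv_W, w$conv_b, w$dense_W, w$dense_b,
                             ks, ceil_pool, TRUE)
        pred <- max.col(res$probs, ties.method = "first") - 1L
        n_correct <- n_correct + sum(pred == y[batch])
        loss_sum <- loss_sum + res$loss * length(batch)

        adam$t <- adam$t + 1L
        corr1 <- 1 - b1^adam$t; corr2 <- 1 - b2^adam$t
        for (part in c("conv_W", "conv_b", "dense_W", "dense_b")) {
          for (j in seq_along(w[[part]])) {
            g <- res$grad[[part]][[j]]
            adam$m[[part]][[j]] <- b1 * adam$m[[part]][[j]] + (1 - b1) * g
            adam$v[[part]][[j]] <- b2 * adam$v[[part]][[j]] + (1 - b2) * g^2
            w[[part]][[j]] <- w[[part]][[j]] - config$learning_rate *
              (adam$m[[part]][[j]] / corr1) /
              (sqrt(adam$v[[part]][[j]] / corr2) + eps)
          }
        }
      }
      history$train_acc[epoch] <- n_correct / length(train_idx)
      history$loss[epoch] <- loss_sum / length(train_idx)
      if (length(test_idx) > 0L) {
        tp <- cnn_batch_cpp(images$pixels[, , test_idx, drop = FALSE],
                            y[test_idx], w$conv_W, w$conv_b, w$dense_W,
                            w$dense_b, ks, ceil_pool, FALSE)
        pred <- max.col(tp$probs, ties.method = "first") - 1L
        history$test_acc[epoch] <- mean(pred == y[test_idx])
      }
    }

    model$weights <- w
    model$class_levels <- levels
    model$history <- history
    model$trained <- TRUE
    model
  })
}

#' Predict class probabilities for network images
#'
#' @param object A trained `cnn_model`.
#' @param images A `network_image_set` matching the model's input size.
#' @param ... Ignored.
#' @return A list with `probs` (samples x classes matrix, columns named by
#'   class, rows summing to 1) and `label` (argmax class; ties resolve to
#'   the lowest class index).
#' @export
predict.cnn_model <- function(object, images, ...) {
  if (is.null(object$class_levels)) stop("model has not been trained")
  G <- dim(images$pixels)[1L]
  if (G != object$spec$grid_size)
    stop(sprintf("image side %d does not match model input %d", G,
                 object$spec$grid_size))
  w <- object$weights
  res <- cnn_batch_cpp(images$pixels, rep(-1L, dim(images$pixels)[3L]),
                       w$conv_W, w$conv_b, w$dense_W, w$dense_b,
                       kernel_sizes(object$spec),
                       object$spec$pool_mode == "ceil", FALSE)
  probs <- res$probs[, seq_along(object$class_levels), drop = FALSE]
  probs <- probs / rowSums(probs)   # renormalize over observed classes
  colnames(probs) <- object$class_levels
  rownames(probs) <- images$sample_id
  label <- object$class_levels[max.col(probs, ties.method = "first")]
  list(probs = probs, label = stats::setNames(label, images$sample_id))
}
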