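# Small architecture used where the full 64-kernel stack would be overkill.
tiny_spec <- function(G = 20L, classes = 2L)
  cnn_spec(G, classes, conv = list(c(8L, 5L), c(8L, 3L), c(8L, 3L)),
           hidden = c(16L, 12L, 8L))

test_that("the printed shape chain is reproduced for 100x100 inputs", {
  spec <- cnn_spec(100L, 12L)
  sides <- t(vapply(spec$shapes, function(s) s[c("conv_side", "pool_side")],
                    numeric(2L)))
  expect_equal(sides[, 1L], c(96, 46, 21), ignore_attr = TRUE)
  expect_equal(sides[, 2L], c(48, 23, 11), ignore_attr = TRUE)
  expect_equal(spec$final_side, 11L)
  expect_equal(spec$flat, 11L * 11L * 64L)
  expect_equal(spec$shapes[[3L]][["channels"]], 64L)
})

test_that("floor-mode pooling breaks the 11x11 contract", {
  spec <- cnn_spec(100L, 12L, pool_mode = "floor")
  expect_equal(spec$final_side, 10L)
  expect_false(spec$final_side == 11L)
})

test_that("shape recurrence matches the conv/pool oracle at other sizes", {
  # oracle: conv side = s - k + 1, pool side = ceil(s'/2)
  oracle <- function(G, ks) {
    s <- G
    out <- matrix(NA_integer_, length(ks), 2L)
    for (j in seq_along(ks)) {
      s <- s - ks[j] + 1L
      out[j, 1L] <- s
      s <- as.integer(ceiling(s / 2))
      out[j, 2L] <- s
    }
    out
  }
  for (G in c(32L, 48L, 100L)) {
    spec <- cnn_spec(G, 3L)
    got <- t(vapply(spec$shapes, function(s) s[c("conv_side", "pool_side")],
                    numeric(2L)))
    expect_equal(got, oracle(G, c(5L, 3L, 3L)), ignore_attr = TRUE)
  }
  expect_equal(cnn_spec(32L, 3L)$flat, 2L * 2L * 64L)
})

test_that("inputs too small for the stack fail naming the stage", {
  expect_error(cnn_spec(12L, 3L), "stage 3")
  expect_error(cnn_spec(4L, 3L), "stage 1")
})

test_that("output width follows the class count and parameters are counted", {
  expect_equal(cnn_spec(100L, 12L)$classes, 12L)
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1L)
  n_weights <- sum(vapply(unlist(m$weights, recursive = FALSE), length,
                          integer(1L)))
  expect_equal(n_weights, spec$n_params)
  expect_equal(ncol(m$weights$dense_W[[4L]]), 2L)
})

test_that("probabilities are a softmax: nonnegative rows summing to 1", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 2L)
  imgs <- make_quadrant_set(3L, G = 20L)
  m <- cnn_train(m, imgs, train_config(epochs = 1L, batch_size = 4L, seed = 2L))
  p <- predict(m, imgs)
  expect_true(all(p$probs >= 0))
  expect_lt(max(abs(rowSums(p$probs) - 1)), 1e-5)
})

test_that("a separable fixture is learned and its training images recalled", {
  imgs <- make_quadrant_set(10L, G = 20L, seed = 3L)
  m <- build_model(tiny_spec(), seed = 3L)
  m <- cnn_train(m, imgs, train_config(epochs = 10L, batch_size = 8L, seed = 3L))
  expect_gte(tail(m$history$train_acc, 1L), 0.95)
  p <- predict(m, imgs)
  expect_gte(mean(p$label == imgs$label), 0.95)
})

test_that("training is deterministic given the seed", {
  imgs <- make_quadrant_set(6L, G = 20L, seed = 5L)
  cfg <- train_config(epochs = 4L, batch_size = 8L, seed = 11L)
  m1 <- cnn_train(build_model(tiny_spec(), seed = 7L), imgs, cfg)
  m2 <- cnn_train(build_model(tiny_spec(), seed = 7L), imgs, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("randomly permuted labels yield chance-level accuracy", {
  imgs <- make_quadrant_set(16L, G = 20L, seed = 6L)
  set.seed(41)
  imgs$label <- sample(imgs$label)   # destroy the image-label association
  m <- cnn_train(build_model(tiny_spec(), seed = 8L), imgs,
                 train_config(epochs = 8L, batch_size = 8L, seed = 8L))
  # accuracy against fresh random labels on a fresh balanced set; 100
  # draws keep the estimator noise well inside the band
  fresh <- make_quadrant_set(50L, G = 20L, seed = 61L)
  set.seed(42)
  fresh$label <- sample(fresh$label)
  acc <- mean(predict(m, fresh)$label == fresh$label)
  expect_gte(acc, 0.5 - 0.15)
  expect_lte(acc, 0.5 + 0.15)
})

test_that("batch and one-by-one prediction agree", {
  imgs <- make_quadrant_set(4L, G = 20L, seed = 9L)
  m <- cnn_train(build_model(tiny_spec(), seed = 9L), imgs,
                 train_config(epochs = 2L, batch_size = 4L, seed = 9L))
  batch <- predict(m, imgs)
  single <- vapply(seq_along(imgs$sample_id),
                   function(i) predict(m, imgs[i])$label, character(1L))
  expect_equal(unname(batch$label), unname(single))
})

test_that("analytic gradients match finite differences", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 42L)
  set.seed(7)
  X <- array(runif(20 * 20 * 3), c(20L, 20L, 3L))
  y <- c(0L, 1L, 0L)
  w <- m$weights
  ks <- c(5L, 3L, 3L)
  engine <- function(wts, grad)
    netimg:::cnn_batch_cpp(X, y, wts$conv_W, wts$conv_b, wts$dense_W,
                           wts$dense_b, ks, TRUE, grad)
  res <- engine(w, TRUE)
  numeric_grad <- function(part, j, idx, eps = 1e-6) {
    wp <- w; wp[[part]][[j]][idx] <- wp[[part]][[j]][idx] + eps
    wm <- w; wm[[part]][[j]][idx] <- wm[[part]][[j]][idx] - eps
    (engine(wp, FALSE)$loss - engine(wm, FALSE)$loss) / (2 * eps)
  }
  set.seed(1)
  for (part in c("conv_W", "conv_b", "dense_W", "dense_b")) {
    for (j in seq_along(w[[part]])) {
      for (idx in sample(length(w[[part]][[j]]),
                         min(3L, length(w[[part]][[j]])))) {
        ng <- numeric_grad(part, j, idx)
        expect_equal(res$grad[[part]][[j]][idx], ng, tolerance = 1e-4)
      }
    }
  }
})

test_that("training input is validated", {
  imgs <- make_quadrant_set(3L, G = 20L)
  one_class <- imgs
  one_class$label <- rep("K1", length(one_class$label))
  m <- build_model(tiny_spec(), seed = 1L)
  expect_error(cnn_train(m, one_class, train_config(epochs = 1L)),
               "at least 2 classes")
  wrong_size <- make_quadrant_set(3L, G = 24L)
  expect_error(cnn_train(m, wrong_size, train_config(epochs = 1L)),
               "does not match")
  expect_error(predict(m, imgs), "not been trained")
})
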