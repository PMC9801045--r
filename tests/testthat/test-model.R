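# Small configurations used throughout: full-size networks are exercised
# only for structural contracts.
tiny_config <- function(task = "regression", ablation = "full",
                        dropout = 0) {
  model_config(first_kernels = 6L, first_kernel_size = 5L, n_blocks = 2L,
               layers_per_block = 2L, growth_rate = 3L,
               bottleneck_factor = 2L, pool_widths = c(2L, 2L),
               dropout_rate = dropout, hidden_units = 7L, seq_len = 40L,
               task = task, ablation = ablation)
}

tiny_data <- function(n, n_tfs = 4L, seq_len = 40L, binary = FALSE) {
  seqs <- matrix(sample(1:4, n * seq_len, replace = TRUE), n)
  fused <- matrix(rnorm(n * n_tfs), n)
  target <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  list(seq = seqs, fused = fused, target = target)
}

test_that("default architecture exposes the stated structure", {
  set.seed(1)
  m <- build_model(model_config(), n_tfs = 402L)
  k <- first_layer_kernels(m)
  expect_equal(dim(k), c(4L, 15L, 160L))
  expect_equal(dim(m$params$conv0$W), c(160L, 60L))
  # 3 dense blocks x 5 layers, each layer a bottleneck + conv pair
  layer_names <- grep("^b\\dl\\d\\.conv$", names(m$params), value = TRUE)
  expect_length(layer_names, 15L)
  expect_equal(sort(unique(sub("l.*", "", layer_names))),
               c("b1", "b2", "b3"))
  # dense connectivity: bottleneck j of a block takes
  # C_in + (j-1) * growth channels
  g <- m$config$growth_rate
  C_in <- m$config$first_kernels
  for (j in 1:5) {
    expect_equal(ncol(m$params[[sprintf("b1l%d.bott", j)]]$W),
                 C_in + (j - 1L) * g)
  }
})

test_that("kernel accessor matches the raw weight layout", {
  set.seed(2)
  m <- build_model(tiny_config(), n_tfs = 4L)
  k <- first_layer_kernels(m)
  # W rows are kernels; columns are position-major blocks of 4 bases
  expect_equal(unname(k[3, 2, 5]),
               m$params$conv0$W[5, (2 - 1) * 4 + 3])
})

test_that("loss follows the task definitions", {
  expect_equal(model_loss(c(1, 2), c(1, 2), "regression"), 0)
  expect_equal(model_loss(c(1, 2), c(0, 2), "regression"), 0.5)
  expect_equal(model_loss(rep(0.5, 8), rbinom(8, 1, 0.5),
                          "classification"), log(2))
  expect_error(model_loss(c(1, NA), c(1, 2), "regression"), "non-finite")
})

test_that("classification outputs probabilities, regression is free", {
  set.seed(3)
  mc <- build_model(tiny_config("classification"), 4L)
  d <- tiny_data(10)
  pc <- predict_model(mc, d$seq, d$fused)
  expect_true(all(pc > 0 & pc < 1))
  mr <- build_model(tiny_config("regression"), 4L)
  expect_type(predict_model(mr, d$seq, d$fused), "double")
  # shape: single locus, 3 cell types via the accessibility matrix helper
  motif <- matrix(abs(rnorm(4)), 1)
  expr <- matrix(abs(rnorm(12)), 3)
  pm <- predict_accessibility(mr, d$seq[1, , drop = FALSE], motif, expr)
  expect_equal(dim(pm), c(1L, 3L))
  # duplicated cell-type row gives duplicated predictions
  expr2 <- expr[c(1, 1, 2), ]
  pm2 <- predict_accessibility(mr, d$seq[1, , drop = FALSE], motif, expr2)
  expect_equal(pm2[, 1], pm2[, 2])
})

test_that("analytic gradients match finite differences", {
  for (ablation in c("full", "resnet_backbone")) {
    set.seed(42)
    m <- build_model(tiny_config(ablation = ablation), n_tfs = 4L)
    d <- tiny_data(3)
    Fv <- t(d$fused)
    fw <- chromdense:::net_forward(m, d$seq, Fv, mode = "train")
    dz <- 2 * (fw$z - d$target) / 3
    bw <- chromdense:::net_backward(m, fw$cache, dz)
    lossfun <- function(mm) {
      mean((chromdense:::net_forward(mm, d$seq, Fv,
                                     mode = "train")$z - d$target)^2)
    }
    h <- 1e-5
    for (nm in names(bw$grads)) {
      for (f in names(bw$grads[[nm]])) {
        g <- bw$grads[[nm]][[f]]
        for (rep in seq_len(min(length(g), 3))) {
          ii <- sample(length(g), 1)
          m2 <- m
          m2$params[[nm]][[f]][ii] <- m2$params[[nm]][[f]][ii] + h
          m3 <- m
          m3$params[[nm]][[f]][ii] <- m3$params[[nm]][[f]][ii] - h
          num <- (lossfun(m2) - lossfun(m3)) / (2 * h)
          expect_equal(g[ii], num, tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("training is deterministic and selects a checkpoint", {
  set.seed(7)
  d <- tiny_data(40, binary = TRUE)
  set.seed(100)
  m1 <- build_model(tiny_config("classification", dropout = 0.2), 4L)
  set.seed(100)
  m2 <- build_model(tiny_config("classification", dropout = 0.2), 4L)
  t1 <- train_model(m1, d, epochs = 3, batch_size = 16, seed = 5)
  t2 <- train_model(m2, d, epochs = 3, batch_size = 16, seed = 5)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$params, t2$params)
  expect_error(train_model(m1, list(seq = matrix(0L, 0, 40),
                                    fused = matrix(0, 0, 4),
                                    target = numeric(0))),
               "empty")
})

test_that("a small network overfits a small training set", {
  set.seed(12)
  d <- tiny_data(80, binary = TRUE)
  set.seed(200)
  m <- build_model(tiny_config("classification"), 4L)
  m <- train_model(m, d, epochs = 150, batch_size = 20, lr = 3e-3,
                   seed = 9, validation_frac = 0)
  p <- predict_model(m, d$seq, d$fused)
  expect_lt(model_loss(p, d$target, "classification"), 0.05)
})

test_that("predictions are invariant to batch partitioning", {
  set.seed(31)
  m <- build_model(tiny_config(), 4L)
  d <- tiny_data(65)
  p1 <- predict_model(m, d$seq, d$fused, batch_size = 1L)
  p64 <- predict_model(m, d$seq, d$fused, batch_size = 64L)
  expect_lt(max(abs(p1 - p64)), 1e-5)
})

test_that("the residual backbone honours the same I/O contract", {
  set.seed(55)
  m <- build_model(tiny_config("regression", ablation = "resnet_backbone"),
                   4L)
  d <- tiny_data(30)
  m <- train_model(m, d, epochs = 2, batch_size = 16, seed = 1)
  p <- predict_model(m, d$seq, d$fused)
  expect_length(p, 30)
  expect_true(all(is.finite(p)))
})

test_that("first-layer convolution agrees with dense one-hot convolution", {
  set.seed(77)
  seqs <- matrix(sample(0:4, 3 * 40, replace = TRUE), 3)
  W <- matrix(rnorm(6 * 20), 6)
  b <- rnorm(6)
  y_sparse <- chromdense:::cpp_cube_get(
    chromdense:::cpp_seqconv_fw(seqs, W, b, 5L))
  X <- chromdense:::cpp_onehot(seqs)
  y_dense <- chromdense:::cpp_cube_get(
    chromdense:::cpp_conv1d_fw(chromdense:::cpp_cube_create(X), W, b,
                               5L, 0L))
  expect_equal(y_sparse, y_dense, tolerance = 1e-12)
})
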