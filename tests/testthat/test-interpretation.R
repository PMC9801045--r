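onehot_pwm <- function(codes) {
  m <- matrix(0, 4, length(codes), dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
  m[cbind(codes, seq_along(codes))] <- 1
  m
}

test_that("information content matches the entropy formula", {
  unif <- matrix(0.25, 4, 6)
  expect_equal(information_content(unif), 0)
  expect_equal(information_content(onehot_pwm(2L)), 2)
  expect_equal(information_content(onehot_pwm(sample(1:4, 15, TRUE))), 30)
  # equals the Kullback-Leibler form for a uniform background
  set.seed(44)
  for (i in 1:100) {
    w <- sample(4:12, 1)
    m <- matrix(rgamma(4 * w, 0.7), 4)
    m <- sweep(m, 2, colSums(m), `/`)
    kl <- sum(ifelse(m > 0, m * log2(m / 0.25), 0))
    expect_equal(information_content(m), kl, tolerance = 1e-12)
  }
})

test_that("PWM matching recognises identity and reverse complements", {
  set.seed(3)
  m <- matrix(rgamma(4 * 8, 1), 4, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
  m <- sweep(m, 2, colSums(m), `/`)
  lib <- list(target = m, decoy = matrix(0.25, 4, 8))
  hit <- match_pwms(m, lib)
  expect_equal(hit$match, "target")
  expect_equal(hit$similarity, 1, tolerance = 1e-12)
  rc <- m[4:1, 8:1]
  hit_rc <- match_pwms(rc, lib)
  expect_equal(hit_rc$match, "target")
  expect_equal(hit_rc$similarity, 1, tolerance = 1e-12)
  expect_true(hit_rc$reverse_complement)
  # an uninformative uniform query cannot resemble a sharp motif
  sharp <- onehot_pwm(c(1L, 3L, 2L, 4L, 1L, 1L, 3L, 2L))
  unif_hit <- match_pwms(matrix(0.25, 4, 8), list(s = sharp))
  expect_lte(unif_hit$similarity, 0.5)
})

test_that("kernel_to_pwm counts activating subsequences", {
  # a model whose first kernel is the one-hot of a known 15-mer
  cfg <- model_config(first_kernels = 4L, first_kernel_size = 15L,
                      n_blocks = 1L, layers_per_block = 1L,
                      growth_rate = 2L, pool_widths = 4L,
                      dropout_rate = 0, hidden_units = 4L, seq_len = 60L)
  set.seed(5)
  m <- build_model(cfg, 3L)
  motif_codes <- sample(1:4, 15, replace = TRUE)
  W <- matrix(-1, 4, 15)
  W[cbind(motif_codes, 1:15)] <- 1
  m$params$conv0$W[1, ] <- as.vector(W)
  # one sequence with exactly one planted occurrence
  seq1 <- sample(1:4, 60, replace = TRUE)
  seq1[20:34] <- motif_codes
  # ensure no chance second perfect match elsewhere
  got <- kernel_to_pwm(m, matrix(seq1, 1), kernel_id = 1, alpha = 0.99)
  expect_equal(got$pwm, onehot_pwm(motif_codes), ignore_attr = TRUE)
  expect_equal(got$n_activating, 1L)
  expect_true(all(abs(colSums(got$pwm) - 1) < 1e-12))
  # two activating subsequences differing at one position average to 0.5
  seq2 <- seq1
  seq2[20] <- if (motif_codes[1] == 1) 2L else 1L
  # alpha low enough that the one-mismatch copy also activates
  got2 <- kernel_to_pwm(m, rbind(seq1, seq2), kernel_id = 1, alpha = 0.8)
  expect_equal(got2$n_activating, 2L)
  expect_equal(sort(got2$pwm[, 1][got2$pwm[, 1] > 0]), c(0.5, 0.5),
               ignore_attr = TRUE)
  expect_equal(unname(got2$pwm[motif_codes[5], 5]), 1)
  expect_error(kernel_to_pwm(m, matrix(seq1, 1), 1, alpha = 1), "alpha")
})

test_that("gis vanishes for TFs the model cannot see", {
  cfg <- model_config(first_kernels = 6L, first_kernel_size = 5L,
                      n_blocks = 1L, layers_per_block = 2L,
                      growth_rate = 3L, pool_widths = 4L, dropout_rate = 0,
                      hidden_units = 6L, seq_len = 40L,
                      task = "regression")
  set.seed(6)
  m <- build_model(cfg, 4L)
  n <- 12
  seqs <- matrix(sample(1:4, n * 40, TRUE), n)
  motif <- cbind(abs(rnorm(n)) + 1, abs(rnorm(n)) + 1, 0, abs(rnorm(n)))
  colnames(motif) <- paste0("TF", 1:4)
  d <- list(seq = seqs, fused = fuse(motif, c(1, 1, 1, 1)),
            target = rnorm(n))
  m <- train_model(m, d, epochs = 2, batch_size = 6, seed = 1,
                   validation_frac = 0)
  expr <- matrix(abs(rnorm(8)) + 0.5, 2, 4,
                 dimnames = list(c("k1", "k2"), paste0("TF", 1:4)))
  g <- gis(m, seqs, motif, expr)
  expect_true(all(g >= 0))
  expect_true(all(g[, "TF3"] == 0))  # motif score 0 everywhere
  expect_true(any(g[, "TF1"] > 0))
  expect_error(gis(m, seqs[0, , drop = FALSE], motif[0, , drop = FALSE],
                   expr), "empty")
})

test_that("gis agrees with central finite differences", {
  cfg <- model_config(first_kernels = 6L, first_kernel_size = 5L,
                      n_blocks = 1L, layers_per_block = 2L,
                      growth_rate = 3L, pool_widths = 4L, dropout_rate = 0,
                      hidden_units = 6L, seq_len = 40L,
                      task = "regression")
  set.seed(61)
  m <- build_model(cfg, 4L)
  n <- 20
  seqs <- matrix(sample(1:4, n * 40, TRUE), n)
  motif <- matrix(abs(rnorm(n * 4)) + 0.5, n)
  d <- list(seq = seqs, fused = fuse(motif, rep(1, 4)), target = rnorm(n))
  m <- train_model(m, d, epochs = 3, batch_size = 10, seed = 2,
                   validation_frac = 0)
  expr <- abs(rnorm(4)) + 0.5
  g_signed <- gis(m, seqs, motif, matrix(expr, 1), absolute = FALSE)
  h <- 1e-3
  for (i in 1:4) {
    ep <- expr
    em <- expr
    ep[i] <- ep[i] + h
    em[i] <- em[i] - h
    fp <- predict_model(m, seqs, fuse(motif, ep))
    fm <- predict_model(m, seqs, fuse(motif, em))
    fd <- mean((fp - fm) / (2 * h))
    expect_equal(g_signed[1, i], fd, tolerance = 1e-3)
  }
})

test_that("rank_tfs orders deterministically", {
  g <- c(B = 0.2, A = 0.2, C = 0.9)
  rk <- rank_tfs(g)
  expect_equal(rk$tf, c("C", "A", "B"))  # tie broken lexicographically
  expect_equal(rk$rank, 1:3)
  zero <- rank_tfs(c(Z = 0, M = 0, A = 0))
  expect_equal(zero$tf, c("A", "M", "Z"))
  one <- rank_tfs(c(Z = 0, M = 1, A = 0))
  expect_equal(one$tf[1], "M")
  # permutation invariance of the input ordering
  expect_equal(rank_tfs(g[c(3, 1, 2)]), rk)
})

test_that("kernel influence restores the model and scores all kernels", {
  cfg <- model_config(first_kernels = 5L, first_kernel_size = 5L,
                      n_blocks = 1L, layers_per_block = 1L,
                      growth_rate = 2L, pool_widths = 4L, dropout_rate = 0,
                      hidden_units = 5L, seq_len = 40L,
                      task = "regression")
  set.seed(8)
  m <- build_model(cfg, 3L)
  n <- 15
  seqs <- matrix(sample(1:4, n * 40, TRUE), n)
  motif <- matrix(abs(rnorm(n * 3)), n)
  expr <- matrix(abs(rnorm(6)) + 0.5, 2, 3)
  truth <- matrix(rnorm(n * 2), n)
  d <- list(seq = seqs, fused = fuse(motif, expr[1, ]), target = rnorm(n))
  m <- train_model(m, d, epochs = 2, batch_size = 8, seed = 3,
                   validation_frac = 0)
  before <- predict_accessibility(m, seqs, motif, expr)
  infl <- kernel_influence(m, seqs, motif, expr, truth)
  expect_length(infl, 5L)
  after <- predict_accessibility(m, seqs, motif, expr)
  expect_identical(before, after)
  # zeroing a kernel that is already all-zero changes nothing
  m$params$conv0$W[2, ] <- 0
  m$params$conv0$b[2] <- 0
  infl2 <- kernel_influence(m, seqs, motif, expr, truth, kernels = 2L)
  expect_equal(unname(infl2), 0)
})
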