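test_that("one-hot encoding maps bases to unit rows and N to zero", {
  expect_equal(unname(one_hot_encode("ACGT")), diag(4), ignore_attr = TRUE)
  expect_equal(sum(one_hot_encode("NNNN")), 0)
  long <- paste(rep("ACGTN", 200), collapse = "")
  oh <- one_hot_encode(long)
  expect_equal(dim(oh), c(1000L, 4L))
  expect_true(all(rowSums(oh) %in% c(0L, 1L)))
  expect_error(one_hot_encode("ACGX"), "invalid base")
  # encode / decode round-trips called bases
  codes <- encode_sequences("TtAaCcGgNn")[1, ]
  expect_equal(codes, c(4L, 4L, 1L, 1L, 2L, 2L, 3L, 3L, 0L, 0L))
})

test_that("extend_loci centers windows and pads chromosome ends with N", {
  set.seed(5)
  chrom <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  loci <- data.frame(chrom = "chr1", start = 400L, end = 600L, id = 0L)
  w <- extend_loci(loci, genome, 1000L)
  expect_equal(dim(w), c(1L, 1000L))
  # midpoint 500 -> window [0, 1000)
  expect_equal(w[1, ], encode_sequences(substr(chrom, 1, 1000))[1, ],
               ignore_attr = TRUE)
  # locus at the chromosome start: midpoint 100, left-pad 400 Ns
  edge <- data.frame(chrom = "chr1", start = 0L, end = 200L, id = 0L)
  we <- extend_loci(edge, genome, 1000L)
  expect_true(all(we[1, 1:400] == 0L))
  expect_equal(we[1, 401:1000],
               encode_sequences(substr(chrom, 1, 600))[1, ],
               ignore_attr = TRUE)
  # target length equal to the locus width returns the locus itself
  same <- extend_loci(loci, genome, 200L)
  expect_equal(same[1, ], encode_sequences(substr(chrom, 401, 600))[1, ],
               ignore_attr = TRUE)
  expect_error(extend_loci(data.frame(chrom = "chrX", start = 0L,
                                      end = 200L, id = 0L), genome, 1000L),
               "absent")
})

test_that("scan_max_scores matches spec examples", {
  # uniform PWM scores 0 at every offset
  unif <- matrix(0.25, 4, 6)
  s <- scan_max_scores("ACGTACGTACGT", list(u = unif))
  expect_equal(unname(s[1, 1]), 0)
  # one-hot PWM of ACGT on TTACGTTT peaks where the motif sits
  oh <- diag(4)[, 1:4]
  rownames(oh) <- c("A", "C", "G", "T")
  pw <- matrix(0, 4, 4)
  pw[cbind(1:4, 1:4)] <- 1
  codes <- encode_sequences("TTACGTTT")[1, ]
  expect_equal(unname(scan_max_scores("TTACGTTT", list(m = pw))[1, 1]),
               brute_scan(codes, pw))
  # sequences shorter than the motif fall back to the floor
  wide <- matrix(0.25, 4, 30)
  expect_equal(unname(scan_max_scores("ACGT", list(w = wide))[1, 1]), -10)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(91)
  pwms <- list(
    a = {
      m <- matrix(rgamma(4 * 5, 1), 4)
      sweep(m, 2, colSums(m), `/`)
    },
    b = {
      m <- matrix(rgamma(4 * 9, 0.5), 4)
      sweep(m, 2, colSums(m), `/`)
    })
  for (i in 1:200) {
    codes <- sample(0:4, 60, replace = TRUE,
                    prob = c(0.03, rep(0.2425, 4)))
    got <- scan_max_scores(matrix(codes, 1), pwms)
    for (p in names(pwms)) {
      expect_identical(unname(got[1, p]), brute_scan(codes, pwms[[p]]))
    }
  }
})

test_that("scanner is strand symmetric", {
  set.seed(17)
  m <- matrix(rgamma(4 * 7, 1), 4)
  m <- sweep(m, 2, colSums(m), `/`)
  for (i in 1:20) {
    codes <- sample(1:4, 60, replace = TRUE)
    rc <- rev(5L - codes)
    s1 <- scan_max_scores(matrix(codes, 1), list(m = m))
    s2 <- scan_max_scores(matrix(rc, 1), list(m = m))
    expect_equal(unname(s1), unname(s2))
  }
})

test_that("expression normalization performs quantile normalization", {
  # samples identical -> output equals log2(TPM + 1)
  tpm <- matrix(c(3, 7, 15), 3, 2,
                dimnames = list(c("TF1", "TF2", "TF3"), c("s1", "s2")))
  rm <- data.frame(sample = c("s1", "s2"), cell_type = c("k1", "k2"))
  out <- normalize_expression(tpm, c("TF1", "TF2", "TF3"), rm)
  expect_equal(out["k1", ], log2(tpm[, 1] + 1), ignore_attr = TRUE)
  # hand-computed quantile normalization: log-values (1,2,3) and (4,5,6)
  # both map to the sorted reference means (2.5, 3.5, 4.5)
  tpm2 <- cbind(s1 = 2^(1:3) - 1, s2 = 2^(4:6) - 1)
  rownames(tpm2) <- c("TF1", "TF2", "TF3")
  out2 <- normalize_expression(tpm2, c("TF1", "TF2", "TF3"), rm)
  expect_equal(unname(out2["k1", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out2["k2", ]), c(2.5, 3.5, 4.5))
  # replicate averaging with one replicate per cell type is the identity
  rm1 <- data.frame(sample = c("s1", "s2"), cell_type = c("k1", "k1"))
  out3 <- normalize_expression(tpm2, c("TF1", "TF2", "TF3"), rm1)
  expect_equal(unname(out3["k1", ]), c(2.5, 3.5, 4.5))
  expect_error(normalize_expression(tpm, c("TF1", "TF9"), rm), "TF9")
})

test_that("quantile-normalized samples share one distribution", {
  set.seed(4)
  tpm <- matrix(rlnorm(40 * 6, 2, 1), 40,
                dimnames = list(sprintf("TF%02d", 1:40),
                                sprintf("s%d", 1:6)))
  rm <- data.frame(sample = sprintf("s%d", 1:6),
                   cell_type = sprintf("k%d", 1:6))
  out <- normalize_expression(tpm, rownames(tpm), rm)
  sorted <- apply(out, 1, sort)
  for (k in 2:6) expect_equal(sorted[, 1], sorted[, k], tolerance = 1e-10)
})

test_that("fuse is an element-wise product with panel checks", {
  expect_equal(fuse(c(1, 2), c(3, 0.5)), c(3, 1))
  expect_equal(fuse(c(0, 0), c(5, 5)), c(0, 0))
  expect_equal(fuse(c(1, 2), c(3, 0.5)), fuse(c(3, 0.5), c(1, 2)))
  expect_equal(fuse(2 * c(1, 2), c(3, 0.5)), 2 * fuse(c(1, 2), c(3, 0.5)))
  expect_error(fuse(c(1, 2, 3), c(1, 2)), "panel")
  m <- matrix(1:6, 2)
  expect_equal(fuse(m, c(1, 10, 100)),
               m * matrix(c(1, 10, 100), 2, 3, byrow = TRUE))
})

test_that("MEME motif files round-trip", {
  set.seed(8)
  pwms <- list(M1 = {
    m <- matrix(rgamma(4 * 8, 1), 4)
    rownames(m) <- c("A", "C", "G", "T")
    sweep(m, 2, colSums(m), `/`)
  }, M2 = {
    m <- matrix(rgamma(4 * 11, 1), 4)
    rownames(m) <- c("A", "C", "G", "T")
    sweep(m, 2, colSums(m), `/`)
  })
  path <- tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), names(pwms))
  for (nm in names(pwms)) {
    expect_equal(back[[nm]], pwms[[nm]], tolerance = 1e-5)
    expect_true(all(abs(colSums(back[[nm]]) - 1) < 1e-4))
  }
})
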