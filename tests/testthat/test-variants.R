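test_that("variant filtering removes indels, multiallelics and rare SNVs", {
  variants <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 400, 500),
    id = paste0("v", 1:5),
    ref = c("A", "AT", "C", "G", "T"),
    alt = c("G", "A", "T", "A,C", "C"),
    stringsAsFactors = FALSE)
  # 10 individuals; alt dosages chosen for MAC 6, -, 5, -, 8
  gt <- cbind(c(rep(1, 6), rep(0, 4)),
              c(rep(1, 6), rep(0, 4)),
              c(rep(1, 5), rep(0, 5)),
              c(rep(1, 6), rep(0, 4)),
              c(rep(2, 4), rep(0, 6)))
  colnames(gt) <- variants$id
  suppressMessages(out <- filter_variants(variants, gt))
  expect_equal(out$variants$id, c("v1", "v5"))  # MAC 6 and 8 kept
  expect_equal(colnames(out$genotypes), c("v1", "v5"))
  # boundary: MAC == 5 removed, MAC == 6 kept
  expect_false("v3" %in% out$variants$id)
})

test_that("apply_variant substitutes alleles and checks the reference", {
  seq <- encode_sequences("ACGTACGT")[1, ]
  same <- apply_variant(seq, 3, "G", "T", dosage = 0)
  expect_equal(same, seq)
  hom <- apply_variant(seq, 3, "G", "T", dosage = 2)
  expect_equal(hom[3], 4L)
  het <- apply_variant(seq, 3, "G", "T", dosage = 1)
  expect_equal(het, hom)  # heterozygous applied as alt
  expect_error(apply_variant(seq, 3, "A", "T", dosage = 1), "mismatch")
})

test_that("cohort score averages over carriers only", {
  expect_equal(cohort_score(c(1, 3, 99), c(1, 2, 0)), 2)
  expect_equal(cohort_score(c(5, 0, 0), c(2, 0, 0)), 5)
  # permutation invariance and carrier bounds
  sc <- c(0.5, 1.5, 2.5, 7)
  ds <- c(1, 1, 2, 0)
  expect_equal(cohort_score(sc, ds), cohort_score(sc[c(3, 1, 2, 4)],
                                                  ds[c(3, 1, 2, 4)]))
  expect_gte(cohort_score(sc, ds), min(sc[ds > 0]))
  expect_lte(cohort_score(sc, ds), max(sc[ds > 0]))
  expect_error(cohort_score(c(1, 2), c(0, 0)), "carriers")
})

test_that("deleterious scores are zero without an alternate allele", {
  set.seed(14)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 4100, TRUE), collapse = "")))
  loci <- tile_genome(c(chr1 = 4100L), 200L)
  cfg <- model_config(first_kernels = 4L, first_kernel_size = 5L,
                      n_blocks = 1L, layers_per_block = 1L,
                      growth_rate = 2L, pool_widths = 4L, dropout_rate = 0,
                      hidden_units = 4L, seq_len = 400L,
                      task = "regression")
  m <- build_model(cfg, 2L)
  pwms <- list(TF1 = matrix(0.25, 4, 4,
                            dimnames = list(c("A", "C", "G", "T"), NULL)),
               TF2 = matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6,
                            dimnames = list(c("A", "C", "G", "T"), NULL)))
  expr <- c(TF1 = 1, TF2 = 2)
  ref_base <- substr(as.character(genome[["chr1"]]), 1000, 1000)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  variant <- data.frame(chrom = "chr1", pos = 1000L, ref = ref_base,
                        alt = alt_base, stringsAsFactors = FALSE)
  s0 <- individual_score(m, genome, loci, variant, dosage = 0, pwms, expr,
                         seq_len = 400L)
  expect_equal(s0, 0)
  s2 <- individual_score(m, genome, loci, variant, dosage = 2, pwms, expr,
                         seq_len = 400L)
  expect_gte(s2, 0)
  bad <- variant
  bad$ref <- alt_base
  expect_error(individual_score(m, genome, loci, bad, 2, pwms, expr,
                                seq_len = 400L), "mismatch")
  outside <- variant
  outside$pos <- 4050L  # beyond the last full tile
  expect_error(individual_score(m, genome, loci, outside, 2, pwms, expr,
                                seq_len = 400L), "locus")
})

test_that("region ranking orders by score then position", {
  variants <- data.frame(chrom = "chr1",
                         pos = c(1000, 2000, 3000, 400000),
                         id = paste0("v", 1:4), stringsAsFactors = FALSE)
  scores <- setNames(c(0.5, 0.9, 0.5, 2), variants$id)
  anchor <- data.frame(chrom = "chr1", pos = 2000)
  rk <- rank_region(anchor, variants, scores)
  expect_equal(rk$id, c("v2", "v1", "v3"))  # far variant excluded
  expect_equal(rk$score, c(0.9, 0.5, 0.5))
  # empty region
  far <- data.frame(chrom = "chr2", pos = 5000)
  expect_equal(nrow(rank_region(far, variants, scores)), 0)
  # equal scores fall back to position order
  eq <- setNames(rep(1, 4), variants$id)
  expect_equal(rank_region(anchor, variants, eq)$id, c("v1", "v2", "v3"))
})

test_that("phenotype lasso recovers planted signal and rejects noise", {
  set.seed(99)
  n <- 80
  X <- matrix(abs(rnorm(n * 30)), n)
  beta <- c(6, -5, 7, 4, -6)
  y <- as.numeric(X[, 1:5] %*% beta)
  fit <- phenotype_lasso(X, y, l1_coef = 0.5, n_folds = 10, seed = 2)
  expect_gt(fit$r2, 0.9)
  # permuted phenotype carries no signal
  null_r2 <- vapply(1:20, function(i) {
    phenotype_lasso(X, sample(y), l1_coef = 0.5, n_folds = 10,
                    seed = i)$r2
  }, numeric(1))
  expect_lte(mean(null_r2), 0.05)
  # an all-zero design is intercept-only
  expect_lte(phenotype_lasso(matrix(0, n, 3) +
                               matrix(rnorm(n * 3, sd = 1e-8), n),
                             y, seed = 1)$r2, 0.05)
  # extreme penalty shrinks to the intercept
  expect_lte(phenotype_lasso(X, y, l1_coef = 1e6, seed = 1)$r2, 0.05)
  expect_error(phenotype_lasso(X, rep(1, n)), "constant")
})

test_that("vcf round trip preserves variants and dosages", {
  spec <- synthetic_spec(chrom_length = 20000L, n_variants = 40L,
                         n_individuals = 12L)
  dir <- file.path(tempdir(), "cd-vcf")
  ds <- generate_dataset(spec, dir, seed = 5)
  v <- read_vcf_variants(file.path(dir, "variants.vcf"))
  expect_equal(nrow(v$variants), nrow(ds$variants))
  expect_equal(v$variants$pos, ds$variants$pos)
  expect_equal(unname(v$genotypes), unname(ds$genotypes))
  suppressMessages(f <- filter_variants(v$variants, v$genotypes))
  expect_false(any(f$variants$id %in%
                     ds$variants$id[ds$variant_class %in%
                                      c("indel", "multiallelic", "rare")]))
  expect_true(all(ds$variants$id[ds$variant_class == "ablating"] %in%
                    f$variants$id))
})
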