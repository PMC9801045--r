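# Self-contained synthetic datasets with known ground truth.  The generative
# rule mirrors the assumption behind the model: a locus is accessible in a
# cell type when the TFs whose motifs it carries are expressed there.
# Concretely, locus l is accessible in cell type k iff
#   sum_o affinity_o * activity(tf_o, k) > threshold
# over the motif occurrences o planted in the locus (affinity ~ U(0.5, 1)
# models unobserved binding context), plus a small sequence-independent
# background accessibility (assay noise).  Everything (sequences, peaks, counts,
# expression, variants, phenotype) is derived from that latent state and
# written in the standard formats the pipeline reads.

#' Specification of a synthetic dataset
#'
#' Defaults give a desk-scale dataset: 2 chromosomes of 200 kb (2000 loci
#' of 200 bp), 8 cell types with 3 DNase replicates each, a panel of 30
#' TFs of which 3 are causal, a 100-donor cohort and 250 variants.
#'
#' @param n_chroms,chrom_length,tile_width Genome layout (bp).
#' @param n_cell_types,n_replicates Cell types and DNase replicates each.
#' @param n_tfs,n_causal_tfs TF panel size and number of causal TFs.
#' @param pwm_width Width of planted motifs (bp).
#' @param consensus_prob Probability mass of the consensus base at each
#'   motif position (sharp, information-rich planted motifs).
#' @param motif_rate Fraction of loci that receive planted motif
#'   occurrences.
#' @param access_threshold Threshold of the generative accessibility rule.
#' @param background_access_prob Sequence-independent accessibility
#'   probability (assay noise).
#' @param replicate_dropout Probability that a replicate misses an
#'   accessible locus's peak (never below half of the replicates, so
#'   labels round-trip exactly).
#' @param false_peak_prob Probability that an inaccessible locus shows a
#'   spurious peak in fewer than half of the replicates.
#' @param n_expr_replicates RNA-seq replicates per cell type.
#' @param n_individuals,n_variants Cohort size and variant count.
#' @param frac_ablating Fraction of variants planted to destroy the
#'   highest-information position of a motif occurrence.
#' @param n_causal_variants Variants with a phenotype effect.
#' @param phenotype_noise_sd Gaussian noise of the phenotype (0 gives an
#'   exactly linear phenotype).
#' @return A `chromdense_synth_spec` list.
#' @export
synthetic_spec <- function(n_chroms = 2L, chrom_length = 200000L,
                           tile_width = 200L, n_cell_types = 8L,
                           n_replicates = 3L, n_tfs = 30L,
                           n_causal_tfs = 3L, pwm_width = 8L,
                           consensus_prob = 0.95, motif_rate = 0.15,
                           access_threshold = 0.6,
                           background_access_prob = 0.02,
                           replicate_dropout = 0.15,
                           false_peak_prob = 0.05,
                           n_expr_replicates = 2L, n_individuals = 100L,
                           n_variants = 250L, frac_ablating = 0.2,
                           n_causal_variants = 10L,
                           phenotype_noise_sd = 1) {
  spec <- as.list(environment())
  if (spec$n_causal_tfs > spec$n_tfs) {
    stop("more causal TFs than the TF panel holds")
  }
  stopifnot(spec$n_chroms >= 1, spec$chrom_length >= spec$tile_width,
            spec$tile_width > 0, spec$n_cell_types >= 2,
            spec$n_replicates >= 1, spec$pwm_width >= 4,
            spec$motif_rate >= 0, spec$motif_rate <= 1,
            spec$n_individuals >= 2)
  class(spec) <- "chromdense_synth_spec"
  spec
}

#' Generate a synthetic dataset on disk
#'
#' Writes a complete dataset (FASTA genome, chromosome sizes, per-replicate
#' narrow peaks and count tables, TPM expression with a replicate map, TF
#' panel, MEME motif library, VCF with genotypes, phenotype table) together
#' with ground-truth files (`labels.tsv`, `signal.tsv`, `occurrences.tsv`,
#' `truth.json`).  Fully deterministic given `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the in-memory dataset (see [load_dataset()]).
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir, seed = 1L) {
  stopifnot(inherits(spec, "chromdense_synth_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  chrom_sizes <- setNames(rep(as.integer(spec$chrom_length),
                              spec$n_chroms), chroms)
  loci <- tile_genome(chrom_sizes, spec$tile_width)
  L <- nrow(loci)
  K <- spec$n_cell_types
  cell_types <- sprintf("cell%02d", seq_len(K))

  ## TF panel and motif library
  tf_names <- sprintf("TF%03d", seq_len(spec$n_tfs))
  causal_tfs <- sort(sample(tf_names, spec$n_causal_tfs))
  pwms <- list()
  for (tf in tf_names) {
    if (tf %in% causal_tfs) {
      cons <- sample(4L, spec$pwm_width, replace = TRUE)
      m <- matrix((1 - spec$consensus_prob) / 3, 4, spec$pwm_width)
      m[cbind(cons, seq_len(spec$pwm_width))] <- spec$consensus_prob
    } else {
      w <- sample(6:12, 1)
      m <- matrix(rgamma(4 * w, shape = 0.6), 4, w)
      m <- sweep(m, 2, colSums(m), `/`)
    }
    rownames(m) <- bases
    pwms[[tf]] <- m
  }

  ## genome with planted motif occurrences
  genome_chars <- lapply(chroms, function(ch) {
    sample(bases, spec$chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms
  # planted loci keep >= 3 tiles of separation, so one locus's extended
  # window never overlaps another locus's planted motifs
  n_planted <- round(spec$motif_rate * L)
  cand <- sample(L)
  taken <- logical(L)
  planted <- integer(0)
  for (l in cand) {
    if (length(planted) >= n_planted) break
    lo <- max(1L, l - 2L)
    hi <- min(L, l + 2L)
    if (any(taken[lo:hi] &
            loci$chrom[lo:hi] == loci$chrom[l])) next
    taken[l] <- TRUE
    planted <- c(planted, l)
  }
  planted <- sort(planted)
  occ <- matrix(0, L, spec$n_causal_tfs,
                dimnames = list(loci$id, causal_tfs))
  occ_rows <- list()
  for (l in planted) {
    n_occ <- 1L + rpois(1, 0.5)
    used <- matrix(integer(0), ncol = 2)  # occupied [start, end) in locus
    for (o in seq_len(n_occ)) {
      tf <- sample(causal_tfs, 1)
      m <- pwms[[tf]]
      w <- ncol(m)
      inst <- vapply(seq_len(w), function(j) sample(4L, 1, prob = m[, j]),
                     integer(1))
      strand <- sample(c("+", "-"), 1)
      planted_codes <- if (strand == "+") inst else rev(5L - inst)
      # occurrences within a locus never overlap (instances stay verbatim)
      rel <- NA_integer_
      for (try in 1:10) {
        cand_rel <- sample.int(spec$tile_width - w + 1L, 1) - 1L
        if (!nrow(used) || all(cand_rel + w <= used[, 1] |
                                 cand_rel >= used[, 2])) {
          rel <- cand_rel
          break
        }
      }
      if (is.na(rel)) next
      used <- rbind(used, c(rel, rel + w))
      pos <- loci$start[l] + rel
      ch <- loci$chrom[l]
      genome_chars[[ch]][pos + seq_len(w)] <- bases[planted_codes]
      affinity <- runif(1, 0.5, 1)  # unobserved binding context
      occ[l, tf] <- occ[l, tf] + affinity
      occ_rows[[length(occ_rows) + 1L]] <-
        data.frame(locus_id = loci$id[l], tf = tf, chrom = ch,
                   pos = pos, strand = strand, width = w,
                   affinity = affinity,
                   instance = paste(bases[planted_codes], collapse = ""),
                   stringsAsFactors = FALSE)
    }
  }
  occurrences <- if (length(occ_rows)) {
    do.call(rbind, occ_rows)
  } else {
    data.frame(locus_id = integer(0), tf = character(0),
               chrom = character(0), pos = integer(0),
               strand = character(0), width = integer(0),
               affinity = numeric(0), instance = character(0))
  }

  ## latent TF activity per cell type and the accessibility rule
  activity <- matrix(runif(spec$n_causal_tfs * K), spec$n_causal_tfs, K,
                     dimnames = list(causal_tfs, cell_types))
  strength <- occ %*% activity  # L x K, affinity-weighted
  noise_acc <- matrix(runif(L * K) < spec$background_access_prob, L, K)
  labels <- matrix(as.integer(strength > spec$access_threshold | noise_acc),
                   L, K, dimnames = list(loci$id, cell_types))

  ## replicate peak files, consistent with the half-of-replicates rule
  R <- spec$n_replicates
  need <- ceiling(R / 2)
  peak_files <- list()
  for (k in seq_len(K)) {
    present <- matrix(FALSE, L, R)
    acc <- which(labels[, k] == 1)
    for (l in acc) {
      keep <- runif(R) >= spec$replicate_dropout
      if (sum(keep) < need) {
        keep[sample.int(R, need)] <- TRUE
      }
      present[l, ] <- keep
    }
    inacc <- which(labels[, k] == 0)
    spurious <- inacc[runif(length(inacc)) < spec$false_peak_prob]
    max_false <- need - 1L
    for (l in spurious) {
      if (max_false >= 1L) {
        present[l, sample.int(R, sample.int(max_false, 1))] <- TRUE
      }
    }
    for (r in seq_len(R)) {
      idx <- which(present[, r])
      # jitter peak edges inward so a peak never crosses into a
      # neighbouring tile (labels then round-trip exactly)
      jit_l <- sample(0:30, length(idx), replace = TRUE)
      jit_r <- sample(0:30, length(idx), replace = TRUE)
      pk <- data.frame(chrom = loci$chrom[idx],
                       start = loci$start[idx] + jit_l,
                       end = loci$end[idx] - jit_r,
                       stringsAsFactors = FALSE)
      f <- file.path(dir, "peaks",
                     sprintf("%s_rep%d.bed", cell_types[k], r))
      write_bed(pk, f)
      peak_files[[cell_types[k]]][[r]] <- pk
    }
  }

  ## read counts per replicate and depths
  depths <- matrix(0, K, R, dimnames = list(cell_types, NULL))
  counts_pooled <- matrix(0L, L, K, dimnames = list(loci$id, cell_types))
  for (k in seq_len(K)) {
    lambda_pm <- 0.2 + 3 * strength[, k] + 1.5 * noise_acc[, k]
    for (r in seq_len(R)) {
      depth <- round(runif(1, 6e5, 1.8e6))
      cts <- rpois(L, lambda_pm * depth / 1e6)
      depths[k, r] <- round(sum(cts) * 1.25)  # reads also fall outside loci
      counts_pooled[, k] <- counts_pooled[, k] + cts
      write.table(data.frame(locus_id = loci$id, count = cts),
                  file.path(dir, "counts",
                            sprintf("%s_rep%d.tsv", cell_types[k], r)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  depth_df <- data.frame(cell_type = rep(cell_types, each = R),
                         replicate = rep(seq_len(R), K),
                         depth = as.integer(t(depths)))
  write.table(depth_df, file.path(dir, "depths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pooled_depths <- setNames(rowSums(depths), cell_types)
  signal <- normalize_signal(counts_pooled, pooled_depths)

  ## TF expression (TPM): causal TFs track their activity
  E <- spec$n_expr_replicates
  samples <- as.vector(t(outer(cell_types, seq_len(E),
                               function(c, r) sprintf("%s_r%d", c, r))))
  rep_map <- data.frame(sample = samples,
                        cell_type = rep(cell_types, each = E),
                        stringsAsFactors = FALSE)
  base_tpm <- setNames(rlnorm(spec$n_tfs, 2.5, 0.8), tf_names)
  tpm <- matrix(0, spec$n_tfs, length(samples),
                dimnames = list(tf_names, samples))
  for (k in seq_len(K)) {
    for (tf in tf_names) {
      # causal TFs vary multiplicatively with their activity, staying
      # interleaved with the rest of the panel so quantile normalization
      # (rank based) preserves the cross-cell-type signal
      mu <- if (tf %in% causal_tfs) {
        base_tpm[tf] * (0.5 + 3 * activity[tf, k])
      } else {
        base_tpm[tf] * rlnorm(1, 0, 0.5)
      }
      for (r in seq_len(E)) {
        tpm[tf, sprintf("%s_r%d", cell_types[k], r)] <-
          mu * rlnorm(1, 0, 0.08)
      }
    }
  }
  decoys <- matrix(rlnorm(20 * length(samples), 2, 1), 20,
                   dimnames = list(sprintf("GENE%03d", 1:20), samples))
  expr_out <- rbind(tpm, decoys)
  write.table(data.frame(gene = rownames(expr_out), expr_out,
                         check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(rep_map, file.path(dir, "replicate_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(tf_names, file.path(dir, "tf_panel.txt"))
  write_meme(pwms, file.path(dir, "motifs.meme"))

  ## variants: motif-ablating, neutral, plus records the filter must drop
  variants <- synth_variants(spec, loci, labels, occurrences, pwms,
                             genome_chars)
  vcf_path <- file.path(dir, "variants.vcf")
  write_synth_vcf(variants, vcf_path, spec$n_individuals)

  ## phenotype: linear in carrier status of the causal variants
  causal_idx <- which(variants$class == "ablating")
  causal_idx <- causal_idx[seq_len(min(spec$n_causal_variants,
                                       length(causal_idx)))]
  beta <- rnorm(length(causal_idx), 0, 1.5)
  carrier <- (variants$genotypes[, causal_idx, drop = FALSE] > 0) * 1
  pheno <- 170 + as.numeric(carrier %*% beta) +
    rnorm(spec$n_individuals, 0, spec$phenotype_noise_sd)
  individuals <- sprintf("IND%03d", seq_len(spec$n_individuals))
  write.table(data.frame(individual = individuals, value = pheno),
              file.path(dir, "phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  ## genome FASTA, sizes, loci and truth
  fa <- file(file.path(dir, "genome.fa"), "w")
  for (ch in chroms) {
    writeLines(paste0(">", ch), fa)
    s <- paste(genome_chars[[ch]], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 80),
                         pmin(seq(80, nchar(s) + 79, 80), nchar(s))), fa)
  }
  close(fa)
  write.table(data.frame(chrom = chroms, length = chrom_sizes),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(loci, file.path(dir, "loci.bed"))
  write_matrix_tsv(labels, file.path(dir, "labels.tsv"))
  write_matrix_tsv(signal, file.path(dir, "signal.tsv"))
  write.table(occurrences, file.path(dir, "occurrences.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- list(seed = seed,
                causal_tfs = causal_tfs,
                tf_activity = activity,
                access_threshold = spec$access_threshold,
                noise_accessible = which(noise_acc),
                variant_class = variants$class,
                variant_id = variants$table$id,
                causal_variants = variants$table$id[causal_idx],
                causal_beta = beta,
                spec = unclass(spec))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = dir, spec = spec, loci = loci, labels = labels,
                 signal = signal, pwms = pwms, tf_panel = tf_names,
                 occurrences = occurrences, activity = activity,
                 expression = expr_out, replicate_map = rep_map,
                 variants = variants$table,
                 genotypes = variants$genotypes,
                 variant_class = variants$class, phenotype = pheno,
                 truth = truth))
}

# Plant variant positions and genotypes (see generate_dataset).
synth_variants <- function(spec, loci, labels, occurrences, pwms,
                           genome_chars) {
  bases <- c("A", "C", "G", "T")
  n_abl <- round(spec$frac_ablating * spec$n_variants)
  n_extra <- 8L
  n_neu <- spec$n_variants - n_abl - n_extra
  rows <- list()
  ## ablating: hit the highest-information position of a planted occurrence
  ## in a locus accessible somewhere
  acc_any <- rownames(labels)[rowSums(labels) > 0]
  cand <- occurrences[as.character(occurrences$locus_id) %in% acc_any, ]
  cand <- cand[!duplicated(cand$locus_id), ]
  cand <- cand[sample.int(nrow(cand)), ]
  n_abl <- min(n_abl, nrow(cand))
  for (i in seq_len(n_abl)) {
    oc <- cand[i, ]
    m <- pwms[[oc$tf]]
    ic_col <- which.max(vapply(seq_len(ncol(m)), function(j) {
      information_content(m[, j, drop = FALSE])
    }, numeric(1)))
    j <- if (oc$strand == "+") ic_col else ncol(m) - ic_col + 1L
    pos <- oc$pos + j - 1L  # 0-based genome position
    ref <- genome_chars[[oc$chrom]][pos + 1L]
    worst <- bases[which.min(m[, ic_col])]
    if (oc$strand == "-") worst <- chartr("ACGT", "TGCA", worst)
    if (worst == ref) worst <- sample(setdiff(bases, ref), 1)
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = oc$chrom, pos = pos + 1L, ref = ref, alt = worst,
                 class = "ablating", stringsAsFactors = FALSE)
  }
  ## neutral: positions in loci with no planted motif within 600 bp
  occ_pos <- split(occurrences$pos, occurrences$chrom)
  tries <- 0L
  while (n_neu > 0 && tries < 50L * spec$n_variants) {
    tries <- tries + 1L
    l <- sample.int(nrow(loci), 1)
    ch <- loci$chrom[l]
    pos <- loci$start[l] + sample.int(spec$tile_width, 1) - 1L
    near <- occ_pos[[ch]]
    if (!is.null(near) && any(abs(near - pos) < 600)) next
    ref <- genome_chars[[ch]][pos + 1L]
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = ch, pos = pos + 1L, ref = ref,
                 alt = sample(setdiff(bases, ref), 1), class = "neutral",
                 stringsAsFactors = FALSE)
    n_neu <- n_neu - 1L
  }
  ## records the variant filter must remove
  mkextra <- function(class) {
    l <- sample.int(nrow(loci), 1)
    pos <- loci$start[l] + sample.int(spec$tile_width - 2L, 1) - 1L
    ch <- loci$chrom[l]
    ref1 <- genome_chars[[ch]][pos + 1L]
    if (class == "indel") {
      data.frame(chrom = ch, pos = pos + 1L,
                 ref = paste0(ref1, genome_chars[[ch]][pos + 2L]),
                 alt = ref1, class = "indel", stringsAsFactors = FALSE)
    } else if (class == "multiallelic") {
      others <- setdiff(bases, ref1)
      data.frame(chrom = ch, pos = pos + 1L, ref = ref1,
                 alt = paste(others[1:2], collapse = ","),
                 class = "multiallelic", stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = ch, pos = pos + 1L, ref = ref1,
                 alt = sample(setdiff(bases, ref1), 1), class = "rare",
                 stringsAsFactors = FALSE)
    }
  }
  for (cl in c("indel", "indel", "indel", "multiallelic", "multiallelic",
               "rare", "rare", "rare")) {
    rows[[length(rows) + 1L]] <- mkextra(cl)
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  tab$id <- sprintf("var%04d", seq_len(nrow(tab)))
  ## genotypes: Hardy-Weinberg draws; common classes resampled until the
  ## minor-allele count clears the rarity filter, "rare" forced below it
  n_ind <- spec$n_individuals
  gt <- matrix(0L, n_ind, nrow(tab))
  for (v in seq_len(nrow(tab))) {
    if (tab$class[v] == "rare") {
      g <- integer(n_ind)
      g[sample.int(n_ind, 2)] <- 1L
      gt[, v] <- g
    } else {
      repeat {
        maf <- runif(1, 0.2, 0.45)
        g <- rbinom(n_ind, 2, maf)
        mac <- min(sum(g), 2L * n_ind - sum(g))
        if (mac > 5L && mac < 2L * n_ind - 5L) break
      }
      gt[, v] <- g
    }
  }
  rownames(gt) <- sprintf("IND%03d", seq_len(n_ind))
  colnames(gt) <- tab$id
  list(table = tab, genotypes = gt, class = setNames(tab$class, tab$id))
}

write_synth_vcf <- function(variants, path, n_ind) {
  tab <- variants$table
  gt <- variants$genotypes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=chromdense-synthetic",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(gt)),
                     collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt))
  for (v in seq_len(nrow(tab))) {
    writeLines(paste(c(tab$chrom[v], tab$pos[v], tab$id[v], tab$ref[v],
                       tab$alt[v], ".", "PASS", ".", "GT", gt_str[, v]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read the ground-truth report of a generated dataset
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @return List with the latent truth: causal TFs, TF activity, planted
#'   occurrences, variant classes, causal variants and effects, plus the
#'   emitted label/signal matrices.
#' @export
truth_report <- function(dir) {
  tj <- file.path(dir, "truth.json")
  if (!file.exists(tj)) stop("no truth.json in ", dir)
  truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  truth$tf_activity <- as.matrix(truth$tf_activity)
  rownames(truth$tf_activity) <- truth$causal_tfs
  truth$occurrences <- read.table(file.path(dir, "occurrences.tsv"),
                                  sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  truth$labels <- read_matrix_tsv(file.path(dir, "labels.tsv"))
  truth$signal <- read_matrix_tsv(file.path(dir, "signal.tsv"))
  truth
}
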