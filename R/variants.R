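# Deleterious scoring of personal-genome variants: predicted accessibility
# change between the reference and the variant-carrying sequence at the
# 200 bp locus containing the variant, aggregated over cohort carriers, and
# an l1-penalized regression of a phenotype on the per-individual scores.

#' Filter variants to common biallelic SNVs
#'
#' Removes insertions/deletions, multiallelic records and rare variants
#' whose minor-allele count across donors is less than or equal to the
#' threshold.
#'
#' @param variants Data frame from [read_vcf_variants()].
#' @param genotypes Individuals x variants dosage matrix.
#' @param min_minor_allele_count Keep variants with minor-allele count
#'   strictly greater than this (default 5).
#' @return List with the filtered `variants` and `genotypes`.
#' @export
filter_variants <- function(variants, genotypes,
                            min_minor_allele_count = 5L) {
  snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    !grepl(",", variants$alt, fixed = TRUE) &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T") &
    variants$ref != variants$alt
  ac <- colSums(genotypes, na.rm = TRUE)
  an <- 2L * colSums(!is.na(genotypes))
  mac <- pmin(ac, an - ac)
  keep <- snv & mac > min_minor_allele_count
  n_bad <- sum(!snv)
  if (n_bad) {
    message(n_bad, " non-SNV or malformed record(s) removed")
  }
  list(variants = variants[keep, , drop = FALSE],
       genotypes = genotypes[, keep, drop = FALSE])
}

#' Apply a variant to a reference window sequence
#'
#' Substitutes the alternate allele when the genotype carries at least one
#' alt allele (heterozygous and homozygous variants are applied
#' identically, a single-sequence model of the personal genome); a 0/0
#' genotype leaves the sequence unchanged.
#'
#' @param window_seq Integer-coded reference window (vector).
#' @param offset 1-based position of the variant within the window.
#' @param ref,alt Single-base alleles.
#' @param dosage Alt-allele dosage (0, 1 or 2).
#' @return The (possibly modified) integer-coded sequence.
#' @export
apply_variant <- function(window_seq, offset, ref, alt, dosage) {
  ref_code <- unname(BASE_CODES[ref])
  if (is.na(ref_code) || window_seq[offset] != ref_code) {
    stop("reference allele mismatch at window offset ", offset)
  }
  if (!is.na(dosage) && dosage > 0) {
    window_seq[offset] <- unname(BASE_CODES[alt])
  }
  window_seq
}

#' Deleterious score of one variant for one individual
#'
#' Locates the fixed-width locus containing the variant, builds the
#' extended sequence window for the reference and the personal genome,
#' recomputes the motif features for both, predicts accessibility with the
#' regression model under the supplied tissue expression profile, and
#' returns `|log2((pred_personal + eps) / (pred_ref + eps))|`.  Negative
#' regression outputs are floored at 0 before the ratio (predicted signals
#' are non-negative by construction).
#'
#' @param model Trained regression model.
#' @param genome [Biostrings::DNAStringSet] reference genome.
#' @param loci Loci data frame ([tile_genome()]).
#' @param variant One-row data frame (chrom, pos 1-based, ref, alt).
#' @param dosage Alt dosage for the individual.
#' @param pwms Motif library (probability matrices).
#' @param expr_profile Named TF expression vector (e.g. muscle).
#' @param seq_len Window length (default 1000).
#' @param eps Pseudo-signal inside the fold change (default 0.01).
#' @return Non-negative deleterious score.
#' @export
individual_score <- function(model, genome, loci, variant, dosage, pwms,
                             expr_profile, seq_len = 1000L, eps = 1e-2) {
  pos0 <- variant$pos - 1L  # 0-based
  hit <- loci$chrom == variant$chrom & loci$start <= pos0 & loci$end > pos0
  if (!any(hit)) stop("variant does not fall in any tiled locus")
  locus <- loci[which(hit)[1], ]
  scores <- variant_pair_scores(model, genome, locus, variant, pwms,
                                expr_profile, seq_len)
  if (is.na(dosage) || dosage == 0) return(0)
  abs(log2((max(scores["personal"], 0) + eps) /
             (max(scores["ref"], 0) + eps)))
}

# Predict accessibility of the locus window with and without the variant.
variant_pair_scores <- function(model, genome, locus, variant, pwms,
                                expr_profile, seq_len = 1000L) {
  wseq <- extend_loci(locus, genome, seq_len)[1, ]
  mid <- (locus$start + locus$end) %/% 2L
  w0 <- mid - seq_len %/% 2L
  offset <- variant$pos - w0  # 1-based within window
  if (offset < 1L || offset > seq_len) {
    stop("variant outside the extended window")
  }
  pseq <- apply_variant(wseq, offset, variant$ref, variant$alt, dosage = 2L)
  seqs <- rbind(wseq, pseq)
  motif <- scan_max_scores(seqs, pwms)
  fused <- fuse_ablated(motif, expr_profile, model$config$ablation)
  pred <- predict_model(model, seqs, fused)
  c(ref = pred[1], personal = pred[2])
}

#' Cohort-level deleterious score
#'
#' Arithmetic mean of the individual-level scores over the individuals who
#' carry the variant; non-carriers are excluded.
#'
#' @param ind_scores Numeric vector of individual scores.
#' @param dosages Alt dosages aligned with `ind_scores`.
#' @return Mean score over carriers.
#' @export
cohort_score <- function(ind_scores, dosages) {
  carriers <- !is.na(dosages) & dosages > 0
  if (!any(carriers)) stop("no carriers: cohort score undefined")
  mean(ind_scores[carriers])
}

#' Score a set of variants across a cohort
#'
#' Computes individual-level deleterious scores for every (individual,
#' variant) pair and the cohort-level score per variant.  Because
#' heterozygous and homozygous genotypes are applied identically, carriers
#' of a variant share one score, which is computed once.
#'
#' @param model,genome,loci,pwms,expr_profile See [individual_score()].
#' @param variants Data frame of filtered variants.
#' @param genotypes Individuals x variants dosage matrix.
#' @param seq_len,eps See [individual_score()].
#' @return List: `individual` (individuals x variants score matrix, 0 for
#'   non-carriers), `cohort` (named vector per variant).
#' @export
score_variants <- function(model, genome, loci, variants, genotypes, pwms,
                           expr_profile, seq_len = 1000L, eps = 1e-2) {
  n_ind <- nrow(genotypes)
  n_var <- nrow(variants)
  ind <- matrix(0, n_ind, n_var,
                dimnames = list(rownames(genotypes), variants$id))
  coh <- setNames(rep(NA_real_, n_var), variants$id)
  for (v in seq_len(n_var)) {
    variant <- variants[v, ]
    pos0 <- variant$pos - 1L
    hit <- loci$chrom == variant$chrom & loci$start <= pos0 &
      loci$end > pos0
    if (!any(hit)) next
    locus <- loci[which(hit)[1], ]
    sc <- variant_pair_scores(model, genome, locus, variant, pwms,
                              expr_profile, seq_len)
    score <- abs(log2((max(sc["personal"], 0) + eps) /
                        (max(sc["ref"], 0) + eps)))
    carriers <- !is.na(genotypes[, v]) & genotypes[, v] > 0
    ind[carriers, v] <- score
    if (any(carriers)) coh[v] <- cohort_score(ind[, v], genotypes[, v])
  }
  list(individual = ind, cohort = coh)
}

#' Rank variants within a risk region
#'
#' A risk region is a 200 kb window centered at an anchor SNP; variants in
#' the region are ordered by decreasing cohort-level deleterious score,
#' with ties broken by genomic position.
#'
#' @param anchor One-row data frame (chrom, pos) of the risk SNP.
#' @param variants Data frame of scored variants.
#' @param cohort_scores Named vector aligned with `variants`.
#' @param width Region width in bp (default 200 kb).
#' @return The variants in the region, ranked, with a `score` column.
#' @export
rank_region <- function(anchor, variants, cohort_scores, width = 200000L) {
  lo <- anchor$pos - width %/% 2L
  hi <- anchor$pos + width %/% 2L
  sel <- variants$chrom == anchor$chrom & variants$pos >= lo &
    variants$pos <= hi
  v <- variants[sel, , drop = FALSE]
  s <- cohort_scores[sel]
  ord <- order(-s, v$pos)
  out <- v[ord, , drop = FALSE]
  out$score <- s[ord]
  out
}

#' Cross-validated l1-penalized phenotype regression
#'
#' Fits `h = a0 + sum_k a_k * dScore_k` with an l1 penalty on the
#' coefficients (lasso, [glmnet::glmnet] with `lambda = l1_coef`), using
#' k-fold cross-validation, and reports the per-fold and mean coefficient
#' of determination (R^2) on held-out folds.  Individuals not carrying a
#' variant contribute a score of 0 in the design matrix.
#'
#' @param scores Individuals x variants deleterious-score matrix.
#' @param phenotype Numeric phenotype vector (one value per individual).
#' @param l1_coef Coefficient of the l1 penalty (default 0.5).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List: `r2` (mean held-out R^2), `fold_r2`, `folds`.
#' @export
phenotype_lasso <- function(scores, phenotype, l1_coef = 0.5,
                            n_folds = 10L, seed = 1L) {
  stopifnot(nrow(scores) == length(phenotype))
  if (sd(phenotype) == 0) stop("constant phenotype: R^2 undefined")
  set.seed(seed)
  n <- length(phenotype)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  r2 <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f
    fit <- glmnet::glmnet(scores[tr, , drop = FALSE], phenotype[tr],
                          alpha = 1, lambda = l1_coef)
    pred <- as.numeric(predict(fit, scores[!tr, , drop = FALSE]))
    1 - sum((phenotype[!tr] - pred)^2) /
      sum((phenotype[!tr] - mean(phenotype[!tr]))^2)
  }, numeric(1))
  list(r2 = mean(r2), fold_r2 = r2, folds = fold)
}
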