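# Per-locus model inputs: fixed-length sequence windows, one-hot encoding,
# per-TF maximum motif-binding scores from a log-odds scan, normalized TF
# expression, and the motif (x) expression fusion.

BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L,
                a = 1L, c = 2L, g = 3L, t = 4L, n = 0L)

#' Integer-code DNA sequences
#'
#' Encodes A, C, G, T as 1..4 and N as 0 (case-insensitive); all other
#' characters are rejected.  This compact coding is the input format of the
#' network and the motif scanner.
#'
#' @param seqs Character vector of equal-length sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return Integer matrix (sequences x positions).
#' @export
encode_sequences <- function(seqs) {
  if (inherits(seqs, "DNAStringSet") || inherits(seqs, "DNAString")) {
    seqs <- as.character(seqs)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) stop("sequences must have equal length")
  chars <- strsplit(seqs, "")
  bad <- setdiff(unique(unlist(chars)), names(BASE_CODES))
  if (length(bad)) {
    stop("invalid base(s): ", paste(bad, collapse = ", "))
  }
  t(vapply(chars, function(x) unname(BASE_CODES[x]), integer(lens[1])))
}

#' One-hot encode a DNA sequence
#'
#' A, C, G and T map to the four unit vectors (in that column order); N and
#' other ambiguity codes map to the all-zero row, so row sums are 1 for
#' called bases and 0 otherwise.
#'
#' @param seq A single sequence (character or DNAString) or an integer-coded
#'   vector from [encode_sequences()].
#' @return Length x 4 binary matrix with columns A, C, G, T.
#' @export
one_hot_encode <- function(seq) {
  if (!is.numeric(seq)) {
    seq <- encode_sequences(as.character(seq))[1, ]
  }
  m <- matrix(0L, length(seq), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  called <- seq >= 1L
  m[cbind(which(called), seq[called])] <- 1L
  m
}

#' Extend loci to fixed-length windows centered on their midpoints
#'
#' Each locus is extended to `target_len` bp centered at its midpoint;
#' windows overrunning a chromosome end are padded with N so every window
#' has exactly `target_len` bases.
#'
#' @param loci Data frame (`chrom`, `start`, `end`).
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA).
#' @param target_len Window length in bp (default 1000).
#' @return Integer-coded sequence matrix (loci x target_len), ready for the
#'   network and the motif scanner.
#' @export
extend_loci <- function(loci, genome, target_len = 1000L) {
  if (is.character(genome)) genome <- read_genome(genome)
  target_len <- as.integer(target_len)
  if (any(target_len < loci$end - loci$start)) {
    stop("target_len must be at least the locus width")
  }
  missing <- setdiff(unique(loci$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  }
  mid <- (loci$start + loci$end) %/% 2L
  w0 <- mid - target_len %/% 2L  # 0-based window start
  out <- matrix(0L, nrow(loci), target_len)
  for (ch in unique(loci$chrom)) {
    rows <- which(loci$chrom == ch)
    chrom_seq <- genome[[ch]]
    clen <- length(chrom_seq)
    for (r in rows) {
      s <- w0[r]
      lo <- max(s, 0L)
      hi <- min(s + target_len, clen)
      if (hi > lo) {
        piece <- as.character(Biostrings::subseq(chrom_seq, lo + 1L, hi))
        codes <- unname(BASE_CODES[strsplit(piece, "")[[1]]])
        codes[is.na(codes)] <- 0L
        out[r, (lo - s + 1L):(hi - s)] <- codes
      }
    }
  }
  rownames(out) <- loci$id
  out
}

#' Log-odds score matrices for a PWM set
#'
#' Converts probability matrices to log2-odds against a uniform background;
#' a pseudocount is added to both the motif and background probabilities
#' before the log (so a uniform PWM scores exactly 0 everywhere).
#'
#' @param pwms Named list of 4 x W probability matrices.
#' @param background Background base probability (uniform, default 0.25).
#' @param pseudocount Added to probabilities before the log (default 1e-3).
#' @return Named list of 4 x W log-odds matrices.
#' @export
pwm_log_odds <- function(pwms, background = 0.25, pseudocount = 1e-3) {
  lapply(pwms, function(m) {
    log2((m + pseudocount) / (background + pseudocount))
  })
}

#' Maximum motif-binding score per TF
#'
#' Scores every offset of every PWM on both strands with the log2-odds
#' scheme of [pwm_log_odds()] and keeps, per PWM, the maximum over all
#' offsets and strands.  N bases contribute 0 to a window score (neutral);
#' windows consisting solely of N are skipped, and motifs with no scoreable
#' window (e.g. a sequence shorter than the motif) receive `score_floor`.
#'
#' @param seqs Integer-coded sequence matrix ([encode_sequences()]) or
#'   character vector.
#' @param pwms Named list of 4 x W probability matrices.
#' @param background,pseudocount See [pwm_log_odds()].
#' @param score_floor Finite stand-in for unscoreable motifs (default -10).
#' @return Numeric matrix (sequences x TFs) of maximum scores.
#' @export
scan_max_scores <- function(seqs, pwms, background = 0.25,
                            pseudocount = 1e-3, score_floor = -10) {
  if (!is.matrix(seqs)) seqs <- encode_sequences(seqs)
  storage.mode(seqs) <- "integer"
  lods <- pwm_log_odds(pwms, background, pseudocount)
  out <- cpp_scan_pwm_max(seqs, unname(lods), score_floor)
  dimnames(out) <- list(rownames(seqs), names(pwms))
  out
}

#' Normalize TF expression to per-cell-type profiles
#'
#' TPM values of the panel TFs are log-transformed (`log2(TPM + 1)`),
#' quantile-normalized across samples (reference distribution = mean of the
#' sorted columns, ties averaged), and replicate samples are averaged
#' within each cell type.
#'
#' @param tpm Genes x samples TPM matrix with gene row names.
#' @param tf_panel Character vector of panel TF names (row subset).
#' @param replicate_map Data frame with columns `sample`, `cell_type`
#'   mapping columns of `tpm` to cell types.
#' @return Cell types x TFs matrix of normalized expression.
#' @export
normalize_expression <- function(tpm, tf_panel, replicate_map) {
  missing <- setdiff(tf_panel, rownames(tpm))
  if (length(missing)) {
    stop("TF(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  x <- log2(as.matrix(tpm[tf_panel, , drop = FALSE]) + 1)
  qn <- limma::normalizeQuantiles(x, ties = TRUE)
  cts <- unique(replicate_map$cell_type)
  out <- vapply(cts, function(k) {
    smp <- replicate_map$sample[replicate_map$cell_type == k]
    rowMeans(qn[, smp, drop = FALSE])
  }, numeric(length(tf_panel)))
  t(out)  # cell types x TFs
}

#' Fuse motif and expression features
#'
#' Element-wise product of the per-TF maximum motif score and the
#' normalized TF expression, the TF input of the hybrid network.
#'
#' @param motif Numeric vector (length T) or loci x T matrix of motif
#'   scores.
#' @param expr Numeric vector of length T (one cell type's expression).
#' @return Same shape as `motif`.
#' @export
fuse <- function(motif, expr) {
  tlen <- if (is.matrix(motif)) ncol(motif) else length(motif)
  if (length(expr) != tlen) {
    stop("motif and expression features have different TF panel lengths")
  }
  if (!is.null(names(expr))) {
    mn <- if (is.matrix(motif)) colnames(motif) else names(motif)
    if (!is.null(mn) && !identical(mn, names(expr))) {
      stop("motif and expression TF ordering differ")
    }
  }
  if (is.matrix(motif)) {
    sweep(motif, 2, expr, `*`)
  } else {
    motif * expr
  }
}

# Fused feature under a model ablation: no_expression uses ones for the
# expression vector, no_motif uses ones for the motif scores.
fuse_ablated <- function(motif, expr, ablation = "full") {
  switch(ablation,
         full = fuse(motif, expr),
         resnet_backbone = fuse(motif, expr),
         no_expression = if (is.matrix(motif)) motif else motif,
         no_motif = {
           if (is.matrix(motif)) {
             matrix(expr, nrow(motif), length(expr), byrow = TRUE,
                    dimnames = dimnames(motif))
           } else {
             expr
           }
         },
         stop("unknown ablation: ", ablation))
}
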