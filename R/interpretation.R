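# Model interpretation: gradient importance scores for TF prioritization,
# extraction of binding motifs from first-layer kernels, motif information
# content, kernel influence on prediction quality, and PWM similarity
# matching against a motif library.

#' Predict the loci x cell types accessibility matrix
#'
#' Builds each cell type's fused TF feature (respecting the model's
#' ablation switch) and runs the network over all loci.
#'
#' @param model Trained [build_model()] object.
#' @param seqs Integer-coded sequence windows (loci x seq_len).
#' @param motif Loci x TFs maximum motif-score matrix.
#' @param expr Cell types x TFs normalized expression matrix.
#' @param batch_size Examples per forward pass.
#' @return Numeric matrix (loci x cell types).
#' @export
predict_accessibility <- function(model, seqs, motif, expr,
                                  batch_size = 128L) {
  stopifnot(ncol(motif) == ncol(expr), nrow(motif) == nrow(seqs))
  out <- matrix(0, nrow(seqs), nrow(expr),
                dimnames = list(rownames(seqs), rownames(expr)))
  for (k in seq_len(nrow(expr))) {
    fused <- fuse_ablated(motif, expr[k, ], model$config$ablation)
    out[, k] <- predict_model(model, seqs, fused, batch_size = batch_size)
  }
  out
}

#' Gradient importance scores
#'
#' For each cell type and TF, the average absolute gradient of the
#' predicted accessibility with respect to the TF's expression over a set
#' of loci (typically the accessible loci within a 200 kb window around an
#' anchor locus; see [loci_in_window()]).  The gradient flows through the
#' fused motif-expression product, so TFs whose motif scores are constant
#' at the score floor receive 0.
#'
#' @param model Trained model (full or no_motif ablation; with
#'   no_expression there is no expression input to differentiate).
#' @param seqs Integer-coded windows of the loci in the evaluation set.
#' @param motif Loci x TFs motif-score matrix for those loci.
#' @param expr Cell types x TFs expression matrix (or a single profile).
#' @param absolute Take |gradient| per locus before averaging (default
#'   TRUE, matching the average absolute gradient definition); FALSE
#'   averages signed gradients.
#' @param score_floor The scanner's floor value marking "no scoreable
#'   site"; floored entries denote absent binding and contribute zero
#'   gradient (set to NULL to disable the masking).
#' @param batch_size Examples per pass.
#' @return Cell types x TFs matrix of scores (>= 0 when `absolute`).
#' @export
gis <- function(model, seqs, motif, expr, absolute = TRUE,
                score_floor = -10, batch_size = 128L) {
  if (is.null(dim(expr))) expr <- matrix(expr, 1L,
                                         dimnames = list("profile",
                                                         names(expr)))
  if (model$config$ablation == "no_expression") {
    stop("the no_expression ablation has no expression input")
  }
  if (nrow(seqs) == 0L) stop("empty locus window")
  out <- matrix(0, nrow(expr), ncol(expr),
                dimnames = list(rownames(expr), colnames(expr)))
  for (k in seq_len(nrow(expr))) {
    fused <- fuse_ablated(motif, expr[k, ], model$config$ablation)
    gf <- fused_input_gradient(model, seqs, fused, batch_size = batch_size)
    # d yhat / d g_i = d yhat / d fused_i * motif_i (or * 1 for no_motif)
    gexpr <- if (model$config$ablation == "no_motif") gf else gf * motif
    if (!is.null(score_floor) && model$config$ablation != "no_motif") {
      gexpr[motif == score_floor] <- 0
    }
    out[k, ] <- if (absolute) colMeans(abs(gexpr)) else colMeans(gexpr)
  }
  out
}

#' Accessible loci within a window around an anchor locus
#'
#' @param loci Loci data frame ([tile_genome()]).
#' @param labels Binary label matrix with locus-id row names.
#' @param anchor_id Locus id at the window center.
#' @param cell_type Cell type whose labels select accessible loci.
#' @param window Window width in bp (default 200 kb), centered at the
#'   anchor locus midpoint.
#' @return Integer locus ids of accessible loci in the window.
#' @export
loci_in_window <- function(loci, labels, anchor_id, cell_type,
                           window = 200000L) {
  a <- loci[loci$id == anchor_id, ]
  if (nrow(a) != 1L) stop("anchor locus not found")
  mid <- (a$start + a$end) %/% 2L
  sel <- loci$chrom == a$chrom &
    loci$end > mid - window %/% 2L & loci$start < mid + window %/% 2L
  ids <- loci$id[sel]
  acc <- labels[as.character(ids), cell_type] == 1
  ids[acc]
}

#' Rank TFs by gradient importance
#'
#' @param gis_values Named numeric vector (one cell type's GIS row).
#' @return Data frame of TFs in decreasing score order; ties are broken
#'   lexicographically by TF name so the ranking is deterministic.
#' @export
rank_tfs <- function(gis_values) {
  ord <- order(-gis_values, names(gis_values), method = "radix")
  data.frame(tf = names(gis_values)[ord], gis = unname(gis_values[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Extract a PWM from a first-layer kernel
#'
#' Scans the sequence set with the kernel, collects every subsequence whose
#' activation exceeds `alpha` times the kernel's maximal activation value
#' (MAV) over the set, and returns the position-wise base frequencies of
#' the collected subsequences as a PWM.  Positions where the kernel window
#' would overrun a sequence end are not scored, and subsequences containing
#' N are skipped when counting.
#'
#' @param model Trained model.
#' @param seqs Integer-coded sequence matrix to scan.
#' @param kernel_id Kernel index (1-based, up to `first_kernels`).
#' @param alpha Activation threshold coefficient in (0, 1), default 0.7.
#' @return List of class `chromdense_motif`: `pwm` (4 x kernel width),
#'   `kernel_id`, `n_activating`, `information_content`, `mav`.
#' @export
kernel_to_pwm <- function(model, seqs, kernel_id, alpha = 0.7) {
  if (alpha >= 1) {
    stop("alpha must be < 1: no subsequence can exceed the MAV itself")
  }
  kern <- first_layer_kernels(model)[, , kernel_id]
  storage.mode(seqs) <- "integer"
  act <- cpp_kernel_activations(seqs, kern)
  mav <- max(act)
  hits <- which(act > alpha * mav, arr.ind = TRUE)
  K <- ncol(kern)
  counts <- matrix(0, 4L, K, dimnames = list(c("A", "C", "G", "T"), NULL))
  n_used <- 0L
  for (h in seq_len(nrow(hits))) {
    sub <- seqs[hits[h, 1], hits[h, 2]:(hits[h, 2] + K - 1L)]
    if (any(sub == 0L)) next
    counts[cbind(sub, seq_len(K))] <- counts[cbind(sub, seq_len(K))] + 1
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no activating subsequences found")
  pwm <- counts / n_used
  structure(list(pwm = pwm, kernel_id = kernel_id, n_activating = n_used,
                 information_content = information_content(pwm),
                 mav = mav),
            class = "chromdense_motif")
}

#' @export
print.chromdense_motif <- function(x, ...) {
  cat(sprintf("kernel %d motif: width %d, %d activating subsequences, IC %.2f bits\n",
              x$kernel_id, ncol(x$pwm), x$n_activating,
              x$information_content))
  invisible(x)
}

#' Information content of a PWM
#'
#' `IC = sum_ij (p_ij log2 p_ij - b_i log2 b_i)` with `0 log 0 = 0`; for a
#' uniform background this equals the usual Kullback-Leibler form
#' `sum p log2(p/b)`.
#'
#' @param pwm 4 x W probability matrix.
#' @param background Background base frequency (default 0.25).
#' @return Information content in bits.
#' @export
information_content <- function(pwm, background = 0.25) {
  plogp <- function(p) ifelse(p > 0, p * log2(p), 0)
  sum(plogp(pwm)) - 4 * ncol(pwm) * plogp(background)
}

#' Influence of first-layer kernels on prediction quality
#'
#' Sets a kernel's weights (and bias) to zero, recomputes predictions, and
#' reports the decrease in mean cell type-wise Pearson correlation; the
#' model is restored afterwards.
#'
#' @param model Trained regression model.
#' @param seqs,motif,expr Evaluation set as in [predict_accessibility()].
#' @param truth Loci x cell types true signal matrix.
#' @param kernels Kernel indices (default: all first-layer kernels).
#' @param batch_size Examples per pass.
#' @return Named numeric vector of influence scores (baseline PCC minus
#'   kernel-zeroed PCC).
#' @export
kernel_influence <- function(model, seqs, motif, expr, truth,
                             kernels = NULL, batch_size = 128L) {
  if (is.null(kernels)) kernels <- seq_len(model$config$first_kernels)
  base_pred <- predict_accessibility(model, seqs, motif, expr,
                                     batch_size = batch_size)
  base_pcc <- mean(celltype_wise("pcc", truth, base_pred), na.rm = TRUE)
  W0 <- model$params$conv0$W
  b0 <- model$params$conv0$b
  out <- vapply(kernels, function(k) {
    model$params$conv0$W[k, ] <- 0
    model$params$conv0$b[k] <- 0
    pred <- predict_accessibility(model, seqs, motif, expr,
                                  batch_size = batch_size)
    model$params$conv0$W <- W0
    model$params$conv0$b <- b0
    base_pcc - mean(celltype_wise("pcc", truth, pred), na.rm = TRUE)
  }, numeric(1))
  names(out) <- paste0("kernel", kernels)
  out
}

#' Best match of a query PWM in a motif library
#'
#' Aligns the query against each library motif at every offset (requiring
#' at least `min_overlap` overlapping columns) on both strands, scoring an
#' alignment by the mean per-column Pearson correlation of the probability
#' vectors (columns with zero variance contribute 0).  Returns the best
#' library motif with its similarity in [-1, 1].
#'
#' @param query 4 x W probability matrix (or a `chromdense_motif`).
#' @param library Named list of PWMs.
#' @param min_overlap Minimum overlapping columns (default 4).
#' @return List: `match` (library name), `similarity`, `offset`,
#'   `reverse_complement`, and `all` (similarity per library motif).
#' @export
match_pwms <- function(query, library, min_overlap = 4L) {
  if (inherits(query, "chromdense_motif")) query <- query$pwm
  sims <- vapply(library, function(m) pwm_similarity(query, m, min_overlap),
                 numeric(3))
  best <- which.max(sims[1, ])
  list(match = names(library)[best], similarity = unname(sims[1, best]),
       offset = as.integer(sims[2, best]),
       reverse_complement = sims[3, best] > 0,
       all = sims[1, ])
}

pwm_revcomp <- function(m) {
  m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
}

pwm_similarity <- function(q, m, min_overlap = 4L) {
  best <- c(-Inf, 0, 0)
  for (rc in c(FALSE, TRUE)) {
    t <- if (rc) pwm_revcomp(m) else m
    wq <- ncol(q)
    wt <- ncol(t)
    for (off in seq(-(wq - min_overlap), wt - min_overlap)) {
      qi <- max(1L, 1L - off):min(wq, wt - off)
      ti <- qi + off
      if (length(qi) < min_overlap) next
      cors <- vapply(seq_along(qi), function(j) {
        a <- q[, qi[j]]
        b <- t[, ti[j]]
        if (sd(a) == 0 || sd(b) == 0) return(0)
        cor(a, b)
      }, numeric(1))
      s <- mean(cors)
      if (s > best[1]) best <- c(s, off, as.numeric(rc))
    }
  }
  best
}
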