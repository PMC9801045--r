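# Evaluation statistics: area under the precision-recall curve (cell
# type-wise and locus-wise), Pearson correlation along either axis, the
# prediction squared error, and locus activity statistics used to stratify
# performance by cell type specificity.

#' Precision-recall curve and its area
#'
#' Sweeps the classification threshold over every distinct predicted score
#' (predictions count as positive when strictly greater than the
#' threshold), plus a final threshold below the minimum so the curve
#' reaches recall 1.  The area is the step-wise (rectangle-rule) sum of
#' precision over recall increments, matching the sweep definition exactly
#' rather than interpolating.
#'
#' @param truth Binary vector (at least one positive).
#' @param scores Numeric prediction vector.
#' @param strict Use strict inequality `score > t` (default TRUE); FALSE
#'   uses `score >= t` at the observed thresholds.
#' @return For [pr_curve()], a data frame of threshold, precision, recall;
#'   for [aupr()], the area as a scalar.
#' @export
pr_curve <- function(truth, scores, strict = TRUE) {
  stopifnot(length(truth) == length(scores))
  truth <- as.numeric(truth)
  P <- sum(truth)
  if (P == 0) stop("undefined metric: no positive examples")
  thr <- sort(unique(scores), decreasing = TRUE)
  if (strict) thr <- c(thr, -Inf)  # so the curve reaches recall 1
  pts <- lapply(thr, function(t) {
    sel <- if (strict) scores > t else scores >= t
    pp <- sum(sel)
    if (pp == 0) return(NULL)
    tp <- sum(truth[sel])
    data.frame(threshold = t, precision = tp / pp, recall = tp / P)
  })
  do.call(rbind, pts)
}

#' @rdname pr_curve
#' @export
aupr <- function(truth, scores, strict = TRUE) {
  curve <- pr_curve(truth, scores, strict = strict)
  rec <- c(0, curve$recall)
  sum(curve$precision * diff(rec))
}

#' Pearson correlation between two vectors
#'
#' @param truth,pred Numeric vectors.
#' @return Correlation, or NA if either vector is constant.
#' @export
pcc <- function(truth, pred) {
  if (sd(truth) == 0 || sd(pred) == 0) return(NA_real_)
  cor(truth, pred)
}

#' Apply a metric cell type-wise or locus-wise
#'
#' Cell type-wise metrics are computed within one cell type (a column)
#' across loci; locus-wise metrics are computed for one locus (a row)
#' across cell types.  Entries whose preconditions fail (no positives for
#' auPR, constant vectors for PCC) are reported as NA, not zero.
#'
#' @param metric `"aupr"` or `"pcc"`.
#' @param truth,pred Matrices of identical shape (loci x cell types).
#' @return Named numeric vector over cell types / loci.
#' @export
celltype_wise <- function(metric = c("aupr", "pcc"), truth, pred) {
  metric <- match.arg(metric)
  stopifnot(all(dim(truth) == dim(pred)))
  out <- vapply(seq_len(ncol(truth)), function(k) {
    apply_metric(metric, truth[, k], pred[, k])
  }, numeric(1))
  names(out) <- colnames(truth)
  out
}

#' @rdname celltype_wise
#' @export
locus_wise <- function(metric = c("aupr", "pcc"), truth, pred) {
  metric <- match.arg(metric)
  stopifnot(all(dim(truth) == dim(pred)))
  out <- vapply(seq_len(nrow(truth)), function(l) {
    apply_metric(metric, truth[l, ], pred[l, ])
  }, numeric(1))
  names(out) <- rownames(truth)
  out
}

apply_metric <- function(metric, truth, pred) {
  if (metric == "aupr") {
    if (sum(truth) == 0 || length(unique(truth)) < 2) return(NA_real_)
    aupr(truth, pred)
  } else {
    if (length(truth) < 2) return(NA_real_)
    pcc(truth, pred)
  }
}

#' Prediction squared error
#'
#' Total squared prediction error normalized by the squared deviation of
#' the truth from its per-cell-type means:
#' `sum((y - yhat)^2) / sum((y - colMeans(y))^2)`.  Equals 0 for a perfect
#' prediction and 1 for the predictor that outputs each cell type's mean.
#'
#' @param truth,pred Loci x cell types signal matrices.
#' @return Scalar PSE.
#' @export
pse <- function(truth, pred) {
  stopifnot(all(dim(truth) == dim(pred)))
  denom <- sum(sweep(truth, 2, colMeans(truth))^2)
  if (denom == 0) stop("degenerate truth: constant within every cell type")
  sum((truth - pred)^2) / denom
}

#' Locus activity statistics
#'
#' Cell range (max - min) and cell variability (population standard
#' deviation, dividing by K) of the true signal of each locus across cell
#' types.
#'
#' @param truth Loci x cell types signal matrix (K >= 2).
#' @return Data frame with `cell_range` and `cell_variability` per locus.
#' @export
locus_activity <- function(truth) {
  if (ncol(truth) < 2L) stop("at least two cell types are required")
  rng <- apply(truth, 1, function(y) max(y) - min(y))
  K <- ncol(truth)
  vr <- apply(truth, 1, function(y) sqrt(sum((y - mean(y))^2) / K))
  data.frame(cell_range = rng, cell_variability = vr,
             row.names = rownames(truth))
}

#' Group loci into activity tertiles
#'
#' Splits a statistic at its 1/3 and 2/3 quantiles into low / medium /
#' high groups; values tied with a boundary go to the lower group.
#'
#' @param values Numeric vector (e.g. cell range per locus).
#' @param quantiles Boundary quantiles (default 1/3 and 2/3).
#' @return Factor with levels low, medium, high.
#' @export
group_by_activity <- function(values, quantiles = c(1 / 3, 2 / 3)) {
  q <- quantile(values, quantiles, names = FALSE)
  factor(ifelse(values <= q[1], "low",
                ifelse(values <= q[2], "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Group accessible loci by accessibility breadth
#'
#' Bins loci by the proportion of cell types in which they are accessible,
#' using explicit breakpoint proportions (e.g. `c(0.1, 0.5)` reproduces a
#' "<10%" lowest group).  Loci accessible in no cell type are excluded
#' (NA).
#'
#' @param labels Binary label matrix (loci x cell types).
#' @param breaks Increasing breakpoint proportions in (0, 1).
#' @return Factor of group indices `1..length(breaks)+1` per locus, NA for
#'   inaccessible loci.
#' @export
group_by_accessibility_breadth <- function(labels, breaks = c(1 / 3, 2 / 3)) {
  prop <- rowMeans(labels)
  grp <- findInterval(prop, breaks, left.open = TRUE) + 1L
  grp[prop == 0] <- NA_integer_
  factor(grp, levels = seq_len(length(breaks) + 1L))
}
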