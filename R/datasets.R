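# Genome tiling, accessibility labels from replicate peak sets, depth
# normalization of DNase-seq counts and cell type-level cross-validation.
# All intervals are 0-based half-open.

#' Tile a genome into fixed-width loci
#'
#' Each chromosome is divided into non-overlapping windows of `width` bp
#' starting at position 0; a trailing window shorter than `width` is
#' dropped (the network requires fixed-width inputs).  Locus ids are dense
#' integers 0..L-1 assigned in genome order.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp), or a path
#'   readable by [read_chrom_sizes()].
#' @param width Tile width in bp (default 200).
#' @return Data frame with columns `chrom`, `start`, `end`, `id`.
#' @export
tile_genome <- function(chrom_sizes, width = 200L) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  }
  width <- as.integer(width)
  if (width <= 0L) stop("width must be positive")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    n <- chrom_sizes[[ch]] %/% width
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * width
    data.frame(chrom = ch, start = start, end = start + width,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  }
  out$id <- seq_len(nrow(out)) - 1L
  out
}

loci_granges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(start = loci$start + 1L,
                                          end = loci$end))
}

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

#' Label loci as accessible from replicate peak sets
#'
#' A locus is accessible (1) if it overlaps (by at least 1 bp) a peak in at
#' least half of the replicates, i.e. in `ceiling(R/2)` of `R` replicate
#' peak sets, and inaccessible (0) otherwise.
#'
#' @param loci Data frame from [tile_genome()].
#' @param replicate_peaks List of peak data frames (`chrom`, `start`,
#'   `end`), one per DNase-seq replicate of the cell type.
#' @return Integer 0/1 vector along `loci`.
#' @export
label_loci <- function(loci, replicate_peaks) {
  if (!length(replicate_peaks)) stop("at least one replicate is required")
  if (is.data.frame(replicate_peaks)) replicate_peaks <- list(replicate_peaks)
  gl <- loci_granges(loci)
  hits <- vapply(replicate_peaks, function(p) {
    if (!nrow(p)) return(integer(nrow(loci)))
    as.integer(IRanges::overlapsAny(gl, peaks_granges(p)))
  }, integer(nrow(loci)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(loci))
  need <- ceiling(length(replicate_peaks) / 2)
  as.integer(rowSums(hits) >= need)
}

#' Build the loci x cell types binary label matrix
#'
#' @param loci Data frame from [tile_genome()].
#' @param peak_sets Named list (one element per cell type) of lists of
#'   replicate peak data frames.
#' @return Integer matrix (loci x cell types) with locus ids as row names.
#' @export
build_label_matrix <- function(loci, peak_sets) {
  m <- vapply(peak_sets, function(reps) label_loci(loci, reps),
              integer(nrow(loci)))
  rownames(m) <- loci$id
  m
}

#' Depth-normalized, log-transformed accessibility signal
#'
#' Replicate counts of a cell type are pooled upstream; given the pooled
#' per-locus counts `n_lk` and total pooled read counts `N_k`, the
#' normalized count is `N * n_lk / N_k` where `N = min_k N_k`, and the
#' signal is `log(1 + normalized count)` in base `log_base`.
#'
#' @param counts Loci x cell types matrix of pooled raw counts.
#' @param depths Named vector of total pooled reads per cell type (may
#'   exceed the in-locus sum since reads can fall outside loci).
#' @param log_base Base of the log transform (default 2).
#' @return Numeric matrix of the same shape, the regression target.
#' @export
normalize_signal <- function(counts, depths, log_base = 2) {
  if (is.null(colnames(counts))) {
    stopifnot(length(depths) == ncol(counts))
  } else {
    depths <- depths[colnames(counts)]
  }
  if (any(!is.finite(depths)) || any(depths <= 0)) {
    stop("all cell types must have positive sequencing depth")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  N <- min(depths)
  norm <- sweep(counts, 2, N / depths, `*`)
  log(1 + norm, base = log_base)
}

#' Pool replicate count vectors and depths for one cell type
#'
#' @param count_list List of per-replicate count vectors (aligned to loci).
#' @param depth_list Vector of per-replicate total read counts.
#' @return List with `counts` (summed vector) and `depth` (summed).
#' @export
pool_replicates <- function(count_list, depth_list) {
  list(counts = Reduce(`+`, count_list), depth = sum(depth_list))
}

#' Select putative known accessible loci
#'
#' Loci accessible in at least `min_cell_types` training cell types.
#'
#' @param labels Binary label matrix (loci x cell types).
#' @param train_cell_types Columns forming the training set.
#' @param min_cell_types Minimum accessible training cell types (default 2).
#' @return Integer locus ids (row names of `labels` as integers).
#' @export
select_known_loci <- function(labels, train_cell_types,
                              min_cell_types = 2L) {
  sub <- labels[, train_cell_types, drop = FALSE]
  ids <- rownames(labels)
  if (is.null(ids)) ids <- seq_len(nrow(labels)) - 1L
  as.integer(ids[rowSums(sub) >= min_cell_types])
}

#' Select putative novel accessible loci
#'
#' Loci accessible in at least `min_test_cell_types` testing cell types and
#' not present in the training data.  By default "not present" means both
#' absent from the known-loci set and accessible in zero training cell
#' types; with `strict = FALSE` only the known-loci exclusion applies.
#'
#' @param labels Binary label matrix.
#' @param train_cell_types,test_cell_types Column subsets.
#' @param min_test_cell_types Minimum accessible testing cell types (2).
#' @param strict Require zero accessible training cell types (default TRUE).
#' @return Integer locus ids.
#' @export
select_novel_loci <- function(labels, train_cell_types, test_cell_types,
                              min_test_cell_types = 2L, strict = TRUE) {
  ids <- rownames(labels)
  if (is.null(ids)) ids <- seq_len(nrow(labels)) - 1L
  ids <- as.integer(ids)
  test_ok <- rowSums(labels[, test_cell_types, drop = FALSE]) >=
    min_test_cell_types
  known <- select_known_loci(labels, train_cell_types)
  keep <- test_ok & !(ids %in% known)
  if (strict) {
    keep <- keep & rowSums(labels[, train_cell_types, drop = FALSE]) == 0
  }
  ids[keep]
}

#' Cell type-level cross-validation splits
#'
#' Randomly partitions cell types into `n_folds` test sets of near-equal
#' size (differing by at most one); each cell type appears in exactly one
#' test set, and the corresponding training set is its complement.
#'
#' @param cell_types Character vector of cell type names.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the partition.
#' @return List of `n_folds` lists with `fold_id`, `train`, `test`.
#' @export
make_cv_splits <- function(cell_types, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_folds > length(cell_types)) {
    stop("more folds than cell types")
  }
  set.seed(seed)
  perm <- sample(cell_types)
  fold <- rep(seq_len(n_folds), length.out = length(perm))
  fold <- sort(fold)  # sizes differ by <= 1, assigned to shuffled order
  lapply(seq_len(n_folds), function(f) {
    test <- perm[fold == f]
    list(fold_id = f, train = setdiff(cell_types, test), test = test)
  })
}
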