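# High-level plumbing: load a dataset directory, run preprocessing
# (tiling, labelling, signal normalization), compute per-locus features,
# and assemble (locus, cell type) training pairs.

#' Load a dataset directory
#'
#' Reads the layout written by [generate_dataset()] (and producible from
#' real data with the same file names): genome FASTA, chromosome sizes,
#' per-replicate peak BED and count TSV files, expression TSV with a
#' replicate map, TF panel, and MEME motif library.
#'
#' @param dir Dataset directory.
#' @return List with `genome`, `chrom_sizes`, `loci`, `peak_sets`,
#'   `counts`, `depths`, `expression`, `replicate_map`, `tf_panel`,
#'   `pwms`.
#' @export
load_dataset <- function(dir) {
  chrom_sizes <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  genome <- read_genome(file.path(dir, "genome.fa"))
  peak_paths <- list.files(file.path(dir, "peaks"), full.names = TRUE)
  cell_of <- function(p) sub("_rep\\d+\\.(bed|tsv)$", "", basename(p))
  peak_sets <- lapply(split(peak_paths, cell_of(peak_paths)), function(ps) {
    lapply(sort(ps), read_peaks)
  })
  count_paths <- list.files(file.path(dir, "counts"), full.names = TRUE)
  counts <- lapply(split(count_paths, cell_of(count_paths)), function(ps) {
    lapply(sort(ps), function(p) {
      read.table(p, sep = "\t", header = TRUE)$count
    })
  })
  depths_df <- read.table(file.path(dir, "depths.tsv"), sep = "\t",
                          header = TRUE)
  expr <- read.table(file.path(dir, "expression.tsv"), sep = "\t",
                     header = TRUE, row.names = 1, check.names = FALSE)
  rep_map <- read.table(file.path(dir, "replicate_map.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  list(dir = dir,
       chrom_sizes = chrom_sizes,
       genome = genome,
       peak_sets = peak_sets,
       counts = counts,
       depths = depths_df,
       expression = as.matrix(expr),
       replicate_map = rep_map,
       tf_panel = read_tf_panel(file.path(dir, "tf_panel.txt")),
       pwms = read_meme(file.path(dir, "motifs.meme")))
}

#' Preprocess a dataset into labels and signals
#'
#' Tiles the genome, labels loci per cell type with the half-of-replicates
#' rule, pools replicate counts and computes the depth-normalized
#' log-signal.
#'
#' @param data A [load_dataset()] list.
#' @param width Tile width in bp.
#' @return List with `loci`, `labels`, `signal`.
#' @export
preprocess_dataset <- function(data, width = 200L) {
  loci <- tile_genome(data$chrom_sizes, width)
  labels <- build_label_matrix(loci, data$peak_sets)
  cts <- names(data$counts)
  pooled <- vapply(cts, function(k) {
    Reduce(`+`, data$counts[[k]])
  }, numeric(nrow(loci)))
  rownames(pooled) <- loci$id
  depths <- vapply(cts, function(k) {
    sum(data$depths$depth[data$depths$cell_type == k])
  }, numeric(1))
  signal <- normalize_signal(pooled, depths)
  list(loci = loci, labels = labels, signal = signal)
}

#' Per-locus model features
#'
#' Extends loci to fixed windows, integer-codes the sequences and computes
#' the per-TF maximum motif scores on the same windows; normalizes TF
#' expression into per-cell-type profiles.
#'
#' @param data A [load_dataset()] list.
#' @param loci Loci data frame.
#' @param seq_len Window length (default 1000).
#' @return List with `seqs` (loci x seq_len integer matrix), `motif`
#'   (loci x TFs), `expr` (cell types x TFs).
#' @export
compute_features <- function(data, loci, seq_len = 1000L) {
  seqs <- extend_loci(loci, data$genome, seq_len)
  motif <- scan_max_scores(seqs, data$pwms[data$tf_panel])
  expr <- normalize_expression(data$expression, data$tf_panel,
                               data$replicate_map)
  list(seqs = seqs, motif = motif, expr = expr)
}

#' Assemble (locus, cell type) training pairs
#'
#' One training example pairs a locus with one cell type's fused TF vector
#' and that cell type's target: the binary label (classification; negative
#' examples are putative known loci inaccessible in the cell type) or the
#' normalized signal (regression).  Pairs can be subsampled to a budget,
#' optionally balancing classes.
#'
#' @param features A [compute_features()] list.
#' @param target Label or signal matrix (loci x cell types).
#' @param locus_ids Locus ids to include (e.g. [select_known_loci()]).
#' @param cell_types Cell types to include (training split).
#' @param ablation Ablation switch used to fuse features.
#' @param max_pairs Optional cap on the number of pairs (seeded
#'   subsample).
#' @param balance For binary targets, subsample to roughly equal
#'   positives/negatives within the cap.
#' @param seed Seed for subsampling.
#' @return List with `seq`, `fused`, `target` as expected by
#'   [train_model()], plus `locus` and `cell_type` indices.
#' @export
make_training_pairs <- function(features, target, locus_ids, cell_types,
                                ablation = "full", max_pairs = NULL,
                                balance = FALSE, seed = 1L) {
  rid <- rownames(features$seqs)
  lid <- as.character(locus_ids)
  seq_rows <- match(lid, rid)
  if (anyNA(seq_rows)) stop("locus ids missing from feature matrix")
  tgt_rows <- match(lid, rownames(target))
  tgt_cols <- match(cell_types, colnames(target))
  expr_rows <- match(cell_types, rownames(features$expr))
  if (anyNA(tgt_rows) || anyNA(tgt_cols) || anyNA(expr_rows)) {
    stop("loci or cell types missing from target/expression")
  }
  grid <- expand.grid(l = seq_along(lid), k = seq_along(cell_types))
  grid$row <- seq_rows[grid$l]
  grid$cell <- expr_rows[grid$k]
  y <- target[cbind(tgt_rows[grid$l], tgt_cols[grid$k])]
  set.seed(seed)
  keep <- seq_len(nrow(grid))
  if (balance && all(y %in% c(0, 1))) {
    pos <- which(y == 1)
    neg <- which(y == 0)
    n_half <- if (is.null(max_pairs)) min(length(pos), length(neg)) else
      max_pairs %/% 2L
    keep <- c(sample(pos, min(n_half, length(pos))),
              sample(neg, min(n_half, length(neg))))
    keep <- sample(keep)
  } else if (!is.null(max_pairs) && nrow(grid) > max_pairs) {
    keep <- sort(sample(keep, max_pairs))
  }
  grid <- grid[keep, ]
  y <- y[keep]
  fused <- matrix(0, nrow(grid), ncol(features$motif))
  for (k in unique(grid$cell)) {
    sel <- grid$cell == k
    fused[sel, ] <- fuse_ablated(
      features$motif[grid$row[sel], , drop = FALSE],
      features$expr[k, ], ablation)
  }
  list(seq = features$seqs[grid$row, , drop = FALSE],
       fused = fused, target = as.numeric(y),
       locus = rid[grid$row],
       cell_type = rownames(features$expr)[grid$cell])
}
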