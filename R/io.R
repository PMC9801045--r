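# File formats.  Coordinates are 0-based, half-open (BED convention)
# throughout; VCF positions are converted on read.

#' Read a chromosome sizes file
#'
#' @param path Two-column TSV (chromosome name, length in bp), no header.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "length"),
                  colClasses = c("character", "integer"))
  if (any(d$length <= 0)) stop("non-positive chromosome length in ", path)
  setNames(d$length, d$chrom)
}

#' Read peak intervals from a BED or narrowPeak file
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used.
#'
#' @param path BED-like file.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
read_peaks <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#")
  if (ncol(d) < 3) stop("expected at least 3 BED columns in ", path)
  data.frame(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
             end = as.integer(d[[3]]), stringsAsFactors = FALSE)
}

#' Write loci (or any intervals) as BED
#'
#' @param loci Data frame with `chrom`, `start`, `end` and optionally `id`.
#' @param path Output file.
#' @export
write_bed <- function(loci, path) {
  cols <- loci[, c("chrom", "start", "end")]
  if (!is.null(loci$id)) cols$name <- loci$id
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read/write a numeric matrix as TSV with row and column names
#'
#' Rows are loci (ids) and columns cell types for label/signal matrices.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                  check.names = FALSE)
  as.matrix(d)
}

#' @param x Matrix to write.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  write.table(data.frame(id = rownames(x), x, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a TF panel file
#'
#' @param path Text file with one TF name per line.
#' @return Character vector of TF names.
#' @export
read_tf_panel <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

## ---- MEME minimal motif format -------------------------------------------

#' Read motifs in MEME minimal format
#'
#' Parses the letter-probability matrices of a MEME (minimal) motif file
#' into a named list of 4 x W probability matrices with rows A, C, G, T.
#'
#' @param path MEME-format motif file.
#' @return Named list of PWMs (4 x width matrices, columns summing to 1).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^MOTIF\\b", ln)) {
      name <- strsplit(trimws(sub("^MOTIF", "", ln)), "\\s+")[[1]][1]
      # advance to the letter-probability header
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) stop("motif ", name, " lacks a probability matrix")
      w <- suppressWarnings(
        as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
      rows <- list()
      k <- j + 1L
      while (k <= length(lines) && length(rows) < (w %||% Inf)) {
        row <- suppressWarnings(
          as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]]))
        if (length(row) != 4 || anyNA(row)) break
        rows[[length(rows) + 1L]] <- row
        k <- k + 1L
      }
      m <- t(do.call(rbind, rows))
      rownames(m) <- c("A", "C", "G", "T")
      motifs[[name]] <- m
      i <- k
    } else {
      i <- i + 1L
    }
  }
  if (!length(motifs)) stop("no motifs found in ", path)
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param pwms Named list of 4 x W probability matrices (rows A, C, G, T).
#' @param path Output file.
#' @param background Background letter frequencies (length 4).
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m)), con)
    for (j in seq_len(ncol(m))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", m[1, j], m[2, j],
                         m[3, j], m[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read biallelic variants and genotypes from a VCF file
#'
#' Wraps [vcfR::read.vcfR]; genotypes are returned as alt-allele dosages
#' (0, 1, 2, or NA for missing).
#'
#' @param path VCF (v4.x) file, plain text or gzipped.
#' @return List with `variants` (data frame: chrom, pos (1-based), id, ref,
#'   alt) and `genotypes` (individuals x variants dosage matrix).
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           (as.integer(substr(g, 1, 1) %in% c("1")) +
              as.integer(substr(g, 3, 3) %in% c("1"))))
  }
  gmat <- apply(gt, 2, dosage)
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = nrow(variants))
  storage.mode(gmat) <- "integer"
  list(variants = variants, genotypes = t(gmat))
}
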