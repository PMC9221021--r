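# Plain-text readers and writers for the formats the pipeline exchanges.
# FASTA goes through Biostrings, sparse matrices through Matrix (MatrixMarket),
# JSON through jsonlite. The MEME minimal motif format has no installed R
# reader, so a small parser lives here.

#' Read a BED3+ file (chrom, start, end[, name])
#'
#' @param path BED file; 0-based half-open coordinates.
#' @return data.frame (chrom, start, end, id); ids autogenerated
#'   (`chrom:start-end`) when the name column is absent.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$id <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  genomic_intervals(df$chrom, df$start, df$end, df$id)
}

#' Write intervals as BED4
#' @param intervals data.frame (chrom, start, end, id).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    id = intervals$id, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#' @param path TSV (chrom, length), no header.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

#' Read/write DNA sequences (FASTA)
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read PWMs from a MEME minimal motif file
#'
#' Supports the minimal format: optional `Background letter frequencies`
#' block, and `MOTIF <id>` blocks with `letter-probability matrix` headers.
#'
#' @param path MEME motif file.
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(toks[c(2, 4, 6, 8)])
  }
  motif_i <- grep("^MOTIF\\s", lines)
  out <- list()
  for (i in motif_i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- i + grep("^letter-probability matrix",
                    lines[(i + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(4)))
    # rows are positions; renormalize against file rounding
    probs <- probs / rowSums(probs)
    probs <- t(probs)
    dimnames(probs) <- NULL
    out[[id]] <- pwm(id, probs, background = bg)
  }
  out
}

#' Write PWMs to a MEME minimal motif file
#' @param pwms list of [pwm()] objects (assumed to share a background).
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(p$probs)), con)
    for (j in seq_len(ncol(p$probs)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f", p$probs[1, j], p$probs[2, j],
                         p$probs[3, j], p$probs[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read/write a sparse count matrix (MatrixMarket + feature/barcode TSVs)
#'
#' @param prefix path prefix; reads/writes `<prefix>.mtx`,
#'   `<prefix>.features.tsv`, `<prefix>.barcodes.tsv`.
#' @return `dgCMatrix` with dimnames.
#' @export
read_counts <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  rownames(m) <- readLines(paste0(prefix, ".features.tsv"))
  colnames(m) <- readLines(paste0(prefix, ".barcodes.tsv"))
  m
}

#' @rdname read_counts
#' @param counts feature x nucleus matrix with dimnames.
#' @export
write_counts <- function(counts, prefix) {
  Matrix::writeMM(methods::as(methods::as(counts, "CsparseMatrix"),
                              "generalMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(counts), paste0(prefix, ".features.tsv"))
  writeLines(colnames(counts), paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' Read/write a generic TSV with header
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' @rdname read_tsv
#' @param df data.frame.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix as TSV with header row and column
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(name = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
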