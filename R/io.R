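# Plain-text interchange: FASTA (80-column wrap via Biostrings), TSV
# (data.table), BED for blocks, relaxed PHYLIP for alignments.

#' Write sequences to FASTA (80-column wrap)
#'
#' @param seqs named character vector or list of sequence strings.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write/read a TSV table
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path` / a data.frame.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write labeled blocks as BED
#'
#' Columns chrom, start, end, label (0-based half-open, BED convention).
#'
#' @param blocks data.frame with chrom, start, end and optionally
#'   label/origin.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(blocks, path) {
  name <- if (!is.null(blocks$label)) blocks$label
          else if (!is.null(blocks$origin)) blocks$origin else "."
  data.table::fwrite(data.frame(blocks$chrom, blocks$start, blocks$end, name),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file of labeled blocks
#'
#' @param path BED file (3+ columns).
#' @return data.frame with chrom, start, end, label.
#' @export
read_bed <- function(path) {
  b <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  names(b)[1:3] <- c("chrom", "start", "end")
  b$label <- if (ncol(b) >= 4) b[[4]] else "."
  b[, c("chrom", "start", "end", "label")]
}

#' Write a SNP alignment in relaxed PHYLIP format
#'
#' @param matrix a [extract_snps()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(matrix, path) {
  stopifnot(inherits(matrix, "snp_matrix"))
  n <- length(matrix$strains)
  seqs <- apply(matrix$alignment, 1L, paste, collapse = "")
  lines <- c(sprintf("%d %d", n, nrow(matrix$sites)),
             sprintf("%s  %s", names(seqs), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Write a SNP alignment in FASTA format
#'
#' @inheritParams write_phylip
#' @export
write_snp_fasta <- function(matrix, path) {
  stopifnot(inherits(matrix, "snp_matrix"))
  seqs <- apply(matrix$alignment, 1L, paste, collapse = "")
  write_fasta(setNames(seqs, rownames(matrix$alignment)), path)
}
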