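# Lightweight S3 containers shared across modules.

#' Construct a per-strain read count table
#'
#' Holds competitive per-(ortholog group, species) mapped-read counts for one
#' strain, together with the read length and the strain's median genome
#' depth — the two quantities the coverage statistic and the presence
#' threshold need.
#'
#' @param strain strain identifier.
#' @param counts data.frame with columns `group_id`, `species`, `count`
#'   (non-negative integers).
#' @param read_length read length in bp.
#' @param median_depth median whole-genome fold-coverage (over covered
#'   positions); must be > 0 whenever `total_reads` > 0.
#' @param total_reads total mapped reads (>= sum of per-ORF counts;
#'   intergenic reads allowed).
#' @param skipped reads skipped (e.g. shorter than k during assignment).
#' @return object of class `read_count_table`.
#' @export
read_count_table <- function(strain, counts, read_length, median_depth,
                             total_reads = sum(counts$count), skipped = 0L) {
  stopifnot(all(c("group_id", "species", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
  if (total_reads < sum(counts$count))
    stop("total_reads must be >= sum of per-ORF counts", call. = FALSE)
  if (total_reads > 0 && median_depth <= 0)
    stop("median_depth must be > 0 when reads are present", call. = FALSE)
  structure(list(strain = strain,
                 counts = counts[order(counts$group_id, counts$species), ,
                                 drop = FALSE],
                 read_length = as.integer(read_length),
                 median_depth = median_depth,
                 total_reads = total_reads,
                 skipped = as.integer(skipped)),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("read_count_table: strain %s, %d ORF rows, %d bp reads,\n",
              x$strain, nrow(x$counts), x$read_length),
      sprintf(" median depth %.2fx, %d total reads (%d skipped)\n",
              x$median_depth, x$total_reads, x$skipped))
  invisible(x)
}

#' Construct a per-strain depth profile
#'
#' @param strain strain identifier.
#' @param depth named list, one numeric vector of per-base depths per
#'   chromosome.
#' @return object of class `depth_profile` with a `median_depth` field
#'   computed over positions with depth > 0 (robust to unsequenced gaps).
#' @export
depth_profile <- function(strain, depth) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  all_d <- unlist(depth, use.names = FALSE)
  if (any(all_d < 0)) stop("depths must be non-negative", call. = FALSE)
  md <- if (any(all_d > 0)) median(all_d[all_d > 0]) else 0
  structure(list(strain = strain, depth = depth, median_depth = md),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: strain %s, %d chrom(s), %d bp, median %.2fx\n",
              x$strain, length(x$depth),
              sum(lengths(x$depth)), x$median_depth))
  invisible(x)
}
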