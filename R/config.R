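#' Simulation configuration for the hybridization-then-LOH generator
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' generative model is homoploid hybridization between two diverged parental
#' species (A, the reference species, and B, the foreign species) followed by
#' loss of heterozygosity: each ortholog group in each simulated strain is
#' homozygous reference (`CC`), homozygous foreign (`PP`), or heterozygous
#' with one allele from each parent (`CP`).
#'
#' @param genome_length genome size in bp (single chromosome).
#' @param n_groups number of ortholog groups (ORF pairs) to lay out.
#' @param orf_length_range integer length-2 vector, min/max ORF length in bp.
#' @param divergence interspecies divergence `d`: per-site substitution
#'   probability used to derive parent B from parent A. Default 0.10, the
#'   average divergence between the two parental species.
#' @param origin_state_probs named probabilities over `c("CC","PP","CP")`;
#'   must sum to 1. Defaults emulate a genome that is ~4% homozygous foreign
#'   with rare heterozygous ORFs, the regime described for olive-brine
#'   hybrids.
#' @param foreign_block_mode `"per_orf"` (each ORF's origin drawn
#'   independently; intergenic sequence stays parent A) or `"contiguous"`
#'   (origin states form blocks; intergenic sequence follows the containing
#'   block).
#' @param mean_block_length mean foreign-block length in bp for contiguous
#'   mode. Default 10 kb, the scale of LOH/introgression blocks resolved by
#'   10 kb divergence windows.
#' @param depth mean fold-coverage of the sequencing simulation.
#' @param read_length read length in bp (default 250, MiSeq-like).
#' @param seq_error per-base substitution error probability for emitted reads.
#' @param misassign_rate probability `m` that a read is counted toward the
#'   wrong species' ortholog in the direct count route.
#' @param cnv_specs optional `data.frame(group_id, copies)` giving integer
#'   tandem copy numbers for target genes (ENA/CUP1 analogs).
#' @param consensus_mask_rate fraction of consensus positions independently
#'   masked to `N`, emulating sub-Q40 base calls.
#' @param n_strains number of hybrid strains to simulate.
#' @param seed integer seed; mandatory, drives every random draw.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 1e6,
                       n_groups = 200,
                       orf_length_range = c(500, 1500),
                       divergence = 0.10,
                       origin_state_probs = c(CC = 0.95, PP = 0.04, CP = 0.01),
                       foreign_block_mode = c("per_orf", "contiguous"),
                       mean_block_length = 10000,
                       depth = 20,
                       read_length = 250,
                       seq_error = 0.005,
                       misassign_rate = 0.02,
                       cnv_specs = NULL,
                       consensus_mask_rate = 0.02,
                       n_strains = 1,
                       seed) {
  if (missing(seed)) stop("'seed' is mandatory in sim_config()", call. = FALSE)
  foreign_block_mode <- match.arg(foreign_block_mode)
  for (nm in c("genome_length", "n_groups", "divergence", "mean_block_length",
               "depth", "read_length", "seq_error", "misassign_rate",
               "consensus_mask_rate", "n_strains", "seed"))
    stopifnot_scalar_num(get(nm), nm)
  if (length(orf_length_range) != 2L || any(orf_length_range < 1) ||
      orf_length_range[1] > orf_length_range[2])
    stop("'orf_length_range' must be c(min, max) with 1 <= min <= max",
         call. = FALSE)

  p <- origin_state_probs
  if (is.null(names(p)) || !setequal(names(p), c("CC", "PP", "CP")))
    stop("'origin_state_probs' must be named over {CC, PP, CP}", call. = FALSE)
  p <- p[c("CC", "PP", "CP")]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("'origin_state_probs' must be non-negative and sum to 1 (tol 1e-9)",
         call. = FALSE)

  if (divergence < 0 || divergence > 0.75)
    stop("'divergence' must be in [0, 0.75]", call. = FALSE)
  if (depth <= 0) stop("'depth' must be > 0", call. = FALSE)
  if (read_length < 1) stop("'read_length' must be >= 1", call. = FALSE)
  if (seq_error < 0 || seq_error > 1 || misassign_rate < 0 ||
      misassign_rate > 1 || consensus_mask_rate < 0 || consensus_mask_rate > 1)
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (n_strains < 1 || n_strains != round(n_strains))
    stop("'n_strains' must be a positive integer", call. = FALSE)

  if (!is.null(cnv_specs)) {
    cnv_specs <- as.data.frame(cnv_specs)
    if (!all(c("group_id", "copies") %in% names(cnv_specs)))
      stop("'cnv_specs' needs columns group_id, copies", call. = FALSE)
    if (any(cnv_specs$copies < 0) ||
        any(cnv_specs$copies != round(cnv_specs$copies)))
      stop("copy numbers must be non-negative integers", call. = FALSE)
  }

  structure(list(
    genome_length = as.integer(genome_length),
    n_groups = as.integer(n_groups),
    orf_length_range = as.integer(orf_length_range),
    divergence = divergence,
    origin_state_probs = p,
    foreign_block_mode = foreign_block_mode,
    mean_block_length = mean_block_length,
    depth = depth,
    read_length = as.integer(read_length),
    seq_error = seq_error,
    misassign_rate = misassign_rate,
    cnv_specs = cnv_specs,
    consensus_mask_rate = consensus_mask_rate,
    n_strains = as.integer(n_strains),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d bp, %d ortholog groups, d = %.3f", x$genome_length,
              x$n_groups, x$divergence),
      sprintf("origin probs CC/PP/CP = %.3f/%.3f/%.3f (%s mode)",
              x$origin_state_probs[1], x$origin_state_probs[2],
              x$origin_state_probs[3], x$foreign_block_mode),
      sprintf("depth %gx, reads %d bp, misassign %.3f, %d strain(s), seed %d",
              x$depth, x$read_length, x$misassign_rate, x$n_strains, x$seed),
      sep = "\n  ")
  invisible(x)
}
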