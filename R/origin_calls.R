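# Foreign-ORF detection from competitive per-ORF coverage.
#
# Two written rules drive the caller:
#   1. intra-group read filter: within an ortholog group, a species' ORF is
#      considered only if its read count is at least `group_read_fraction`
#      (default 25%) of the group's maximum count — this controls spurious
#      cross-species alignment counts;
#   2. presence threshold: a retained ORF is "present" if its fold-coverage
#      (count * read_length / orf_length) is at least `presence_fraction`
#      (default 1/4) of the strain's median whole-genome coverage.
# Both boundaries are inclusive.

#' Per-ORF fold-coverage
#'
#' `count * read_length / orf_length`. When reads lie fully inside the ORF
#' this equals the base-by-base mean depth over the ORF.
#'
#' @param count mapped reads for the ORF.
#' @param read_length read length in bp.
#' @param orf_length ORF length in bp (> 0).
#' @return fold-coverage (vectorized).
#' @export
#' @examples
#' orf_coverage(100, 250, 1000)  # 25x
orf_coverage <- function(count, read_length, orf_length) {
  if (any(orf_length <= 0)) stop("orf_length must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  count * read_length / orf_length
}

#' Intra-group read filter
#'
#' Retains the species whose read count is at least `fraction` of the
#' group's maximum count (inclusive). An all-zero group retains nothing.
#'
#' @param counts named numeric vector, one count per species.
#' @param fraction retention fraction of the maximum (default 0.25).
#' @return character vector of retained species names.
#' @export
#' @examples
#' filter_intra_group(c(cer = 100, par = 25))  # both retained (boundary)
#' filter_intra_group(c(cer = 100, par = 24))  # "cer" only
filter_intra_group <- function(counts, fraction = 0.25) {
  if (!length(counts)) stop("at least one species required", call. = FALSE)
  mx <- max(counts)
  if (mx == 0) return(character(0))
  names(counts)[counts >= fraction * mx]
}

.CALLS <- c("REF_ONLY", "FOREIGN", "HETEROZYGOUS", "ABSENT")

#' Call per-ORF origin for one strain
#'
#' Applies the intra-group filter then the presence threshold to every
#' ortholog group and classifies it: only the reference species passes →
#' `REF_ONLY`; only foreign species pass → `FOREIGN` (the max-coverage
#' foreign species is recorded); reference and at least one foreign species
#' pass → `HETEROZYGOUS` (co-existing alleles of both species); nothing
#' passes → `ABSENT`.
#'
#' @param table a [read_count_table()] with `median_depth` > 0.
#' @param annotations annotation data.frame (columns `group_id`, `species`,
#'   `length`) covering every group in `table`.
#' @param ref_species name of the reference species (default `"cer"`).
#' @param presence_fraction presence threshold as a fraction of median
#'   genome coverage (default 0.25, i.e. one-fourth).
#' @param group_read_fraction intra-group read filter fraction (default
#'   0.25).
#' @return data.frame of class `origin_call_set`: strain, group_id, call,
#'   ref_cov, foreign_species, foreign_cov; thresholds kept as attributes.
#' @export
call_origin <- function(table, annotations, ref_species = "cer",
                        presence_fraction = 0.25,
                        group_read_fraction = 0.25) {
  stopifnot(inherits(table, "read_count_table"))
  if (table$median_depth <= 0)
    stop("median genome depth must be > 0", call. = FALSE)
  cnt <- table$counts
  unknown <- setdiff(unique(cnt$group_id), unique(annotations$group_id))
  if (length(unknown))
    stop("unknown group id(s) in count table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  thr <- presence_fraction * table$median_depth

  ann_key <- paste(annotations$group_id, annotations$species)
  len <- annotations$length[match(paste(cnt$group_id, cnt$species), ann_key)]
  if (anyNA(len))
    stop("count table rows without matching annotation (group x species)",
         call. = FALSE)
  cnt$cov <- orf_coverage(cnt$count, table$read_length, len)

  res <- lapply(split(cnt, cnt$group_id), function(g) {
    keep <- filter_intra_group(setNames(g$count, g$species),
                               group_read_fraction)
    pass <- g$species %in% keep & g$cov >= thr
    ref_pass <- any(pass & g$species == ref_species)
    fg <- g[pass & g$species != ref_species, , drop = FALSE]
    call <- if (ref_pass && nrow(fg)) "HETEROZYGOUS"
            else if (ref_pass) "REF_ONLY"
            else if (nrow(fg)) "FOREIGN"
            else "ABSENT"
    top <- if (nrow(fg)) fg[which.max(fg$cov), ] else NULL
    data.frame(group_id = g$group_id[1], call = call,
               ref_cov = if (any(g$species == ref_species))
                 g$cov[g$species == ref_species][1] else 0,
               foreign_species = if (!is.null(top)) top$species else NA,
               foreign_cov = if (!is.null(top)) top$cov else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out <- cbind(strain = table$strain, out)
  out$call <- factor(out$call, levels = .CALLS)
  attr(out, "presence_fraction") <- presence_fraction
  attr(out, "group_read_fraction") <- group_read_fraction
  attr(out, "median_depth") <- table$median_depth
  class(out) <- c("origin_call_set", "data.frame")
  out
}

#' Summarize origin calls across a cohort
#'
#' Foreign content of a strain is taken as groups called `FOREIGN` or
#' `HETEROZYGOUS` (a heterozygous ORF still carries a foreign allele). The
#' union is over all strains; the shared core is the set so called in every
#' strain; the heterozygous percentage is 100 x |groups HETEROZYGOUS in >= 1
#' strain| / |union|, rounded half-up to one decimal.
#'
#' @param call_sets list of [call_origin()] outputs (>= 1 strain).
#' @return list of class `call_summary`: `per_strain` data.frame (strain,
#'   n_foreign, n_het), `union`, `shared_core`, `het_union` (character
#'   vectors of group ids), `het_pct`.
#' @export
summarize_calls <- function(call_sets) {
  if (!length(call_sets)) stop("at least one strain required", call. = FALSE)
  has_foreign <- lapply(call_sets, function(cs)
    cs$group_id[cs$call %in% c("FOREIGN", "HETEROZYGOUS")])
  het <- lapply(call_sets, function(cs)
    cs$group_id[cs$call == "HETEROZYGOUS"])
  union_set <- sort(unique(unlist(has_foreign)))
  core <- union_set
  for (s in has_foreign) core <- intersect(core, s)
  het_union <- sort(unique(unlist(het)))
  per_strain <- data.frame(
    strain = vapply(call_sets, function(cs) as.character(cs$strain[1]), ""),
    n_foreign = lengths(has_foreign),
    n_het = lengths(het), row.names = NULL, stringsAsFactors = FALSE)
  het_pct <- if (length(union_set))
    round_half_up(100 * length(het_union) / length(union_set), 1) else NA_real_
  structure(list(per_strain = per_strain, union = union_set,
                 shared_core = sort(core), het_union = het_union,
                 het_pct = het_pct),
            class = "call_summary")
}

#' @export
print.call_summary <- function(x, ...) {
  cat(sprintf("call_summary: %d strains\n", nrow(x$per_strain)),
      sprintf(" foreign union %d, shared core %d, heterozygous union %d (%.1f%%)\n",
              length(x$union), length(x$shared_core), length(x$het_union),
              x$het_pct))
  invisible(x)
}
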