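# Cohort-level frequency and fraction computations for the survey report.

#' Isolation frequency as a printed percentage
#'
#' `100 * positives / samples`, rounded half-up to one decimal — the form in
#' which isolation frequencies are reported in survey tables.
#'
#' @param positives number of positive samples (0..samples).
#' @param samples number of samples screened (>= 1).
#' @return percentage with one decimal.
#' @export
#' @examples
#' isolation_frequency(6, 7)    # 85.7
#' isolation_frequency(6, 163)  # 3.7
isolation_frequency <- function(positives, samples) {
  stopifnot_scalar_num(positives, "positives")
  stopifnot_scalar_num(samples, "samples")
  if (samples < 1) stop("samples must be >= 1", call. = FALSE)
  if (positives < 0 || positives > samples)
    stop("need 0 <= positives <= samples", call. = FALSE)
  round_half_up(100 * positives / samples, 1)
}

#' Fraction of strains carrying at least one marker region
#'
#' Given a strains x markers logical table (e.g. presence of wine-strain
#' signature regions A/B/C), returns the percentage of strains with any
#' marker, rounded half-up at the configured precision.
#'
#' @param marker_table logical matrix or data.frame, rows = strains.
#' @param digits decimal places of the printed percentage (default 0).
#' @return percentage.
#' @export
#' @examples
#' m <- matrix(FALSE, 23, 3); m[1:3, 1] <- TRUE
#' marker_presence_fraction(m)  # 13
marker_presence_fraction <- function(marker_table, digits = 0) {
  m <- as.matrix(marker_table)
  if (!nrow(m)) stop("at least one strain required", call. = FALSE)
  storage.mode(m) <- "logical"
  any_marker <- apply(m, 1L, any)
  round_half_up(100 * sum(any_marker) / nrow(m), digits)
}

#' Assemble a cohort report
#'
#' Combines isolation frequencies per source, the origin-call summary and a
#' marker table into one flat table of labeled numbers, suitable for writing
#' as TSV.
#'
#' @param sources optional data.frame with `source`, `positives`, `samples`.
#' @param call_summary optional [summarize_calls()] result.
#' @param marker_table optional logical strains x markers table.
#' @return data.frame with columns `metric`, `value`.
#' @export
cohort_report <- function(sources = NULL, call_summary = NULL,
                          marker_table = NULL) {
  rows <- list()
  if (!is.null(sources))
    for (i in seq_len(nrow(sources)))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = sprintf("isolation_frequency_pct[%s]", sources$source[i]),
        value = isolation_frequency(sources$positives[i],
                                    sources$samples[i]))
  if (!is.null(call_summary)) {
    stopifnot(inherits(call_summary, "call_summary"))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("foreign_union", "foreign_shared_core",
                 "heterozygous_union", "heterozygous_pct"),
      value = c(length(call_summary$union),
                length(call_summary$shared_core),
                length(call_summary$het_union),
                call_summary$het_pct))
  }
  if (!is.null(marker_table))
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "marker_presence_pct",
      value = marker_presence_fraction(marker_table))
  do.call(rbind, c(rows, make.row.names = FALSE))
}
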