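# Sliding-window divergence of a strain consensus against a reference, and
# segmentation of the sub-genome mosaic into conspecific / heterospecific
# blocks.

#' Windowed divergence of a consensus against a reference
#'
#' Slides a window of `window` bp with `step` bp increments along each
#' chromosome and counts mismatches only at positions where both sequences
#' are non-N (pairwise deletion). The trailing partial window is included
#' with its true size. Divergence is `mismatches / compared_sites`, or `NA`
#' when no site is comparable.
#'
#' @param consensus named list (or single string) of consensus sequences
#'   over {A,C,G,T,N}, aligned to the reference coordinate system.
#' @param reference named list (or single string) of reference sequences of
#'   identical lengths.
#' @param window window size in bp (default 10000).
#' @param step step increment in bp (default 10000, i.e. tiling windows).
#' @param strain strain label carried into the profile.
#' @return list of class `divergence_profile` with `strain` and `windows`
#'   (data.frame: chrom, start, end, compared, mismatches, divergence;
#'   0-based half-open).
#' @export
window_divergence <- function(consensus, reference, window = 10000,
                              step = 10000, strain = "strain") {
  if (is.character(consensus) && is.null(names(consensus)))
    names(consensus) <- if (length(consensus) == 1L) "chrI"
                        else paste0("chr", seq_along(consensus))
  consensus <- as.list(consensus)
  reference <- as.list(reference)
  if (is.null(names(reference))) names(reference) <- names(consensus)
  if (window < step || step < 1)
    stop("need window >= step >= 1", call. = FALSE)
  rows <- list()
  for (chrom in names(consensus)) {
    cs <- seq_to_raw(consensus[[chrom]])
    rf <- seq_to_raw(reference[[chrom]])
    if (length(cs) != length(rf))
      stop(sprintf("length mismatch on %s: consensus %d vs reference %d",
                   chrom, length(cs), length(rf)), call. = FALSE)
    ok <- cs != .RAW_N & rf != .RAW_N
    mm <- ok & cs != rf
    cum_ok <- c(0, cumsum(ok))
    cum_mm <- c(0, cumsum(mm))
    starts <- seq(0L, max(0L, length(cs) - 1L), by = step)
    ends <- pmin(starts + window, length(cs))
    comp <- cum_ok[ends + 1L] - cum_ok[starts + 1L]
    mism <- cum_mm[ends + 1L] - cum_mm[starts + 1L]
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = starts, end = ends, compared = comp,
      mismatches = mism,
      divergence = ifelse(comp > 0, mism / comp, NA_real_),
      stringsAsFactors = FALSE)
  }
  structure(list(strain = strain,
                 windows = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "divergence_profile")
}

#' Label divergence windows and merge them into blocks
#'
#' A window with enough data (`compared >= min_sites_fraction * window
#' size`) is labeled `HETEROSPECIFIC` when its divergence strictly exceeds
#' `threshold`, `CONSPECIFIC` otherwise (a window at exactly the threshold
#' is conspecific); windows below the data floor are `NO_DATA`. Adjacent
#' same-label windows are merged into blocks, and the foreign fraction is
#' the `HETEROSPECIFIC` share of the labeled (data-bearing) genome.
#'
#' The default decision boundary is 0.05 — half the ~10% average divergence
#' between the parental species — which sits between the conspecific (~0)
#' and heterospecific (~10%) divergence modes. The interspecies average
#' itself cannot serve as the boundary: windows of pure foreign origin have
#' divergence fluctuating symmetrically around it.
#'
#' @param profile a [window_divergence()] result.
#' @param threshold divergence decision boundary in (0, 1); default 0.05.
#' @param min_sites_fraction minimum fraction of a window's span that must
#'   be comparable for labeling (default 0.5).
#' @return the profile with `windows$label`, plus `blocks` (data.frame:
#'   chrom, start, end, label) and `foreign_fraction` (NA when no window has
#'   data).
#' @export
label_windows <- function(profile, threshold = 0.05,
                          min_sites_fraction = 0.5) {
  stopifnot(inherits(profile, "divergence_profile"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be inside (0, 1)", call. = FALSE)
  w <- profile$windows
  span <- w$end - w$start
  has_data <- w$compared >= min_sites_fraction * span & w$compared > 0
  w$label <- ifelse(!has_data, "NO_DATA",
                    ifelse(w$divergence > threshold, "HETEROSPECIFIC",
                           "CONSPECIFIC"))
  blocks <- do.call(rbind, c(lapply(split(w, w$chrom), function(wc) {
    wc <- wc[order(wc$start), ]
    r <- rle(wc$label)
    i_end <- cumsum(r$lengths)
    i_start <- c(1L, head(i_end, -1L) + 1L)
    data.frame(chrom = wc$chrom[1], start = wc$start[i_start],
               end = wc$end[i_end], label = r$values,
               stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
  labeled <- w[w$label != "NO_DATA", ]
  ff <- if (nrow(labeled))
    sum(labeled$end[labeled$label == "HETEROSPECIFIC"] -
          labeled$start[labeled$label == "HETEROSPECIFIC"]) /
      sum(labeled$end - labeled$start)
  else NA_real_
  profile$windows <- w
  profile$blocks <- blocks
  profile$foreign_fraction <- ff
  profile$threshold <- threshold
  profile
}

#' @export
print.divergence_profile <- function(x, ...) {
  cat(sprintf("divergence_profile: strain %s, %d windows", x$strain,
              nrow(x$windows)))
  if (!is.null(x$foreign_fraction))
    cat(sprintf(", foreign fraction %.4f", x$foreign_fraction))
  cat("\n")
  invisible(x)
}
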