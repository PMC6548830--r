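# Read-depth copy-number estimation for tandem gene arrays (ENA/CUP1-like)
# with control-gene calibration and flanking-gene validation.

#' Depth-ratio copy number for target genes
#'
#' For each target gene the raw ratio is mean depth over the gene interval
#' divided by the strain's median genome depth; the calibrated copy number
#' divides this by the same ratio for a single-copy control gene (an ACT1
#' analog), cancelling strain-level depth artifacts. Flank ratios for the
#' neighboring genes are reported so that tandem amplification (flanks ~1)
#' can be told apart from a whole-region duplication. Means (not medians)
#' are used over gene intervals because short genes make medians unstable;
#' genome-level normalization keeps the median for robustness.
#'
#' @param profile a [depth_profile()] with median depth > 0.
#' @param genes data.frame of target intervals: `gene`, `chrom`, `start`,
#'   `end` (0-based half-open, non-empty, within bounds).
#' @param control one-row data.frame (same columns) for the control gene.
#' @param flanks optional data.frame (same columns plus `gene` naming the
#'   target it flanks and `side` in `{"up","down"}`).
#' @param control_tolerance maximum relative deviation of the control ratio
#'   from 1 before `pass_control` is set FALSE (default 0.25).
#' @return data.frame of class `cnv_estimate`: strain, gene, raw_ratio,
#'   control_ratio, cn, pass_control, flank_up, flank_down.
#' @export
estimate_copy_number <- function(profile, genes, control, flanks = NULL,
                                 control_tolerance = 0.25) {
  stopifnot(inherits(profile, "depth_profile"))
  if (profile$median_depth <= 0)
    stop("median genome depth is zero", call. = FALSE)
  mean_depth <- function(chrom, start, end) {
    if (!chrom %in% names(profile$depth))
      stop("unknown chromosome ", chrom, call. = FALSE)
    d <- profile$depth[[chrom]]
    if (end <= start) stop("gene interval of length 0", call. = FALSE)
    if (start < 0 || end > length(d))
      stop("interval out of bounds on ", chrom, call. = FALSE)
    mean(d[(start + 1L):end])
  }
  ctrl_ratio <- mean_depth(control$chrom[1], control$start[1],
                           control$end[1]) / profile$median_depth
  pass <- abs(ctrl_ratio - 1) <= control_tolerance
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    raw <- mean_depth(genes$chrom[i], genes$start[i], genes$end[i]) /
      profile$median_depth
    fu <- fd <- NA_real_
    if (!is.null(flanks)) {
      f <- flanks[flanks$gene == genes$gene[i], , drop = FALSE]
      for (j in seq_len(nrow(f))) {
        r <- mean_depth(f$chrom[j], f$start[j], f$end[j]) /
          profile$median_depth / ctrl_ratio
        if (f$side[j] == "up") fu <- r else fd <- r
      }
    }
    data.frame(strain = profile$strain, gene = genes$gene[i],
               raw_ratio = raw, control_ratio = ctrl_ratio,
               cn = raw / ctrl_ratio, pass_control = pass,
               flank_up = fu, flank_down = fd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("cnv_estimate", "data.frame")
  out
}

# Dunn's post hoc test (rank sums from the pooled Kruskal-Wallis ranking,
# normal approximation with tie correction), Bonferroni-adjusted.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  k <- ncol(combs)
  res <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(k)) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[g1] + 1 / ns[g2]))
    z <- (rbar[g1] - rbar[g2]) / se
    res$z[i] <- z
    res$p[i] <- 2 * pnorm(-abs(z))
  }
  res$p_adj <- pmin(1, res$p * k)
  res
}

#' Compare copy-number distributions between strain groups
#'
#' Per-group medians and quartiles, a Kruskal-Wallis omnibus test, and
#' pairwise Dunn post hoc comparisons with Bonferroni correction. Groups
#' with fewer than 2 strains are excluded with a warning; with a single
#' usable group only the summary is returned.
#'
#' @param estimates a [estimate_copy_number()] result (or any data.frame
#'   with `strain` and `cn`), one row per strain for one gene/array.
#' @param groups named vector mapping strain -> group label.
#' @return list of class `cnv_group_summary`: `summary` data.frame (group,
#'   n, median, q1, q3), `kruskal_p` (or NA), `pairwise` data.frame (or
#'   NULL).
#' @export
cnv_group_summary <- function(estimates, groups) {
  g <- groups[match(estimates$strain, names(groups))]
  if (anyNA(g)) stop("every strain needs a group label", call. = FALSE)
  cn <- estimates$cn
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 strains: ",
            paste(small, collapse = ", "))
    keep <- !g %in% small
    g <- g[keep]; cn <- cn[keep]
  }
  g <- factor(g)
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    x <- cn[g == lv]
    data.frame(group = lv, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  if (nlevels(g) < 2L)
    return(structure(list(summary = summ, kruskal_p = NA_real_,
                          pairwise = NULL), class = "cnv_group_summary"))
  kp <- kruskal.test(cn, g)$p.value
  structure(list(summary = summ, kruskal_p = kp,
                 pairwise = dunn_test(cn, g)),
            class = "cnv_group_summary")
}

#' @export
print.cnv_group_summary <- function(x, ...) {
  cat("cnv_group_summary:\n")
  print(x$summary, row.names = FALSE)
  if (!is.na(x$kruskal_p))
    cat(sprintf("Kruskal-Wallis p = %.3g; %d pairwise Dunn comparisons\n",
                x$kruskal_p, nrow(x$pairwise)))
  invisible(x)
}
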