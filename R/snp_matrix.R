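# SNP extraction with site-occupancy filtering, foreign-region masking, and
# a neighbor-joining tree for monophyly checks on the concatenated matrix.

# normalize a consensus set to strain -> list(chrom -> sequence string)
normalize_consensus_set <- function(consensus_set) {
  lapply(consensus_set, function(x) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)))
      x <- setNames(list(x), "chrI")
    as.list(x)
  })
}

#' Mask foreign (heterospecific) regions with N
#'
#' Sets every position inside a strain's heterospecific blocks to `N`, so
#' downstream SNP extraction sees only the conspecific sub-genome — the
#' standard preparation for a phylogeny that discards the foreign parent's
#' regions in all genomes.
#'
#' @param consensus_set named list (by strain) of consensus sequences
#'   (string, or named list of per-chromosome strings).
#' @param blocks named list (by strain) of BED-like data.frames with columns
#'   `chrom`, `start`, `end` (0-based half-open) and optionally `label`;
#'   when `label` is present only `HETEROSPECIFIC` rows are masked. Strains
#'   without an entry are left untouched.
#' @return the consensus set with masked sequences (same shape as input).
#' @export
mask_foreign <- function(consensus_set, blocks) {
  cs <- normalize_consensus_set(consensus_set)
  single <- vapply(consensus_set, function(x)
    is.character(x) && length(x) == 1L && is.null(names(x)), TRUE)
  for (strain in names(blocks)) {
    if (!strain %in% names(cs)) next
    b <- blocks[[strain]]
    if (!is.null(b$label)) b <- b[b$label == "HETEROSPECIFIC", , drop = FALSE]
    if (!nrow(b)) next
    if (any(b$end < b$start) || any(b$start < 0))
      stop("malformed intervals for strain ", strain, call. = FALSE)
    for (chrom in unique(b$chrom)) {
      if (!chrom %in% names(cs[[strain]]))
        stop("unknown chromosome ", chrom, " for strain ", strain,
             call. = FALSE)
      r <- seq_to_raw(cs[[strain]][[chrom]])
      bc <- b[b$chrom == chrom, ]
      if (any(bc$end > length(r)))
        stop("interval beyond chromosome end for strain ", strain,
             call. = FALSE)
      for (i in seq_len(nrow(bc)))
        if (bc$end[i] > bc$start[i])
          r[(bc$start[i] + 1L):bc$end[i]] <- .RAW_N
      cs[[strain]][[chrom]] <- raw_to_seq(r)
    }
  }
  for (strain in names(cs)[single]) cs[[strain]] <- cs[[strain]][[1L]]
  cs
}

#' Extract a site-occupancy-filtered SNP matrix
#'
#' A site is retained iff (a) it carries unambiguous (non-N) calls in at
#' least `occupancy` of the strains (inclusive boundary) and (b) it is
#' polymorphic — at least two distinct non-N alleles among the strains.
#' Retained sites are ordered by (chromosome, position) and concatenated
#' into a phylogeny-ready alignment. Invariant sites are excluded, which
#' matters when interpreting distances computed from the matrix.
#'
#' @param consensus_set named list (by strain, >= 2) of consensus sequences
#'   aligned to a common reference coordinate system.
#' @param occupancy minimum fraction of strains with non-N calls (default
#'   0.85).
#' @return object of class `snp_matrix`: `strains`, `sites` (data.frame
#'   chrom, pos 0-based), `alignment` (character matrix, strains x sites),
#'   `occupancy`.
#' @export
extract_snps <- function(consensus_set, occupancy = 0.85) {
  cs <- normalize_consensus_set(consensus_set)
  n <- length(cs)
  if (n < 2L) stop("need at least 2 strains", call. = FALSE)
  strains <- names(cs)
  chroms <- names(cs[[1L]])
  site_chrom <- character(0); site_pos <- integer(0)
  cols <- list()
  for (chrom in chroms) {
    mat <- do.call(rbind, lapply(cs, function(x) {
      r <- seq_to_raw(x[[chrom]])
      if (length(r) != nchar(cs[[1L]][[chrom]]))
        stop("consensus lengths differ on ", chrom, call. = FALSE)
      r
    }))
    non_n <- mat != .RAW_N
    occ_ok <- colSums(non_n) / n >= occupancy
    # distinct non-N alleles per column
    n_alleles <- rep(0L, ncol(mat))
    for (b in .RAW_BASES)
      n_alleles <- n_alleles + as.integer(colSums(mat == b & non_n) > 0L)
    keep <- which(occ_ok & n_alleles >= 2L)
    if (length(keep)) {
      site_chrom <- c(site_chrom, rep(chrom, length(keep)))
      site_pos <- c(site_pos, keep - 1L)
      cols[[chrom]] <- mat[, keep, drop = FALSE]
    }
  }
  aln <- if (length(cols)) do.call(cbind, cols)
         else matrix(raw(0), nrow = n, ncol = 0)
  aln_char <- matrix(strsplit(rawToChar(as.raw(t(aln))), "")[[1]],
                     nrow = n, byrow = TRUE)
  if (ncol(aln) == 0L) aln_char <- matrix(character(0), nrow = n, ncol = 0)
  rownames(aln_char) <- strains
  structure(list(strains = strains,
                 sites = data.frame(chrom = site_chrom, pos = site_pos,
                                    stringsAsFactors = FALSE),
                 alignment = aln_char,
                 occupancy = occupancy),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d strains x %d polymorphic sites (occupancy >= %g)\n",
              length(x$strains), nrow(x$sites), x$occupancy))
  invisible(x)
}

#' Pairwise distances and a neighbor-joining tree from a SNP matrix
#'
#' The distance between two strains is their mismatch fraction over sites
#' where both carry non-N calls. The tree is standard neighbor joining
#' (ape), with strains ordered lexicographically beforehand so ties resolve
#' deterministically.
#'
#' @param matrix a [extract_snps()] result with >= 3 strains.
#' @return list of class `snp_tree`: `dist` (symmetric matrix), `tree`
#'   (`phylo`), `newick` (string).
#' @export
distance_tree <- function(matrix) {
  stopifnot(inherits(matrix, "snp_matrix"))
  strains <- sort(matrix$strains)
  if (length(strains) < 3L) stop("need at least 3 strains", call. = FALSE)
  aln <- matrix$alignment[strains, , drop = FALSE]
  n <- length(strains)
  non_n <- aln != "N"
  d <- base::matrix(0, n, n, dimnames = list(strains, strains))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- non_n[i, ] & non_n[j, ]
    if (!any(both))
      stop(sprintf("strains %s and %s share no jointly called site",
                   strains[i], strains[j]), call. = FALSE)
    d[i, j] <- d[j, i] <- sum(aln[i, both] != aln[j, both]) / sum(both)
  }
  tree <- ape::nj(stats::as.dist(d))
  structure(list(dist = d, tree = tree, newick = ape::write.tree(tree)),
            class = "snp_tree")
}

#' Test whether a set of strains forms a clade in a `snp_tree`
#'
#' Roots the (unrooted) NJ tree on an outgroup tip and asks whether `tips`
#' are monophyletic.
#'
#' @param snp_tree a [distance_tree()] result.
#' @param tips strain labels expected to form a clade.
#' @param outgroup a tip outside `tips` used to root the tree (default: the
#'   first non-member).
#' @return logical.
#' @export
is_clade <- function(snp_tree, tips, outgroup = NULL) {
  stopifnot(inherits(snp_tree, "snp_tree"))
  tree <- snp_tree$tree
  others <- setdiff(tree$tip.label, tips)
  if (!length(others)) return(TRUE)
  if (is.null(outgroup)) outgroup <- others[1L]
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
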