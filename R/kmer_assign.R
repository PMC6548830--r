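# Diagnostic k-mer read assignment: a desk-scale stand-in for competitive
# mapping of reads against a combined multi-species ORF reference.

#' @import data.table
NULL

orf_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

#' Build an index of ORF-diagnostic k-mers
#'
#' Enumerates every k-mer of every annotated ORF in both parental genomes.
#' A k-mer occurring in exactly one (species, ortholog group) ORF is
#' diagnostic for it; k-mers present in both species' orthologs (or in
#' several groups) are marked shared and carry no vote.
#'
#' @param parents a [simulate_parents()] result (genomes + annotations).
#' @param k k-mer size (>= 11; default 21). Must not exceed the shortest
#'   ORF.
#' @return list of class `kmer_index`: `k`, `kmers` (data.table: kmer,
#'   species, group_id, diagnostic), `shared_instance_fraction` (fraction
#'   of ORF k-mer instances whose k-mer is non-diagnostic),
#'   `genome_length`, `chrom`, `annotations`.
#' @export
build_kmer_index <- function(parents, k = 21L) {
  stopifnot(inherits(parents, "hybrid_parents"))
  k <- as.integer(k)
  if (k < 11L) stop("k must be >= 11", call. = FALSE)
  ann <- parents$annotations
  if (k > min(ann$length))
    stop(sprintf("k = %d exceeds the shortest ORF (%d bp)", k,
                 min(ann$length)), call. = FALSE)
  parts <- lapply(seq_len(nrow(ann)), function(i) {
    g <- parents$genomes[[ann$species[i]]]
    orf <- substr(g, ann$start[i] + 1L, ann$end[i])
    data.table::data.table(kmer = orf_kmers(orf, k),
                           species = ann$species[i],
                           group_id = ann$group_id[i])
  })
  km <- unique(data.table::rbindlist(parts))
  km[, n_owners := .N, by = kmer]
  km[, diagnostic := n_owners == 1L]
  km[, n_owners := NULL]
  # instance-level shared fraction (duplicates within an ORF count once per
  # (kmer, species, group), close enough for the calibration check)
  shared_frac <- km[, mean(!diagnostic)]
  structure(list(k = k, kmers = km, shared_instance_fraction = shared_frac,
                 genome_length = nchar(parents$genomes$cer),
                 chrom = "chrI", annotations = ann),
            class = "kmer_index")
}

parse_read_meta <- function(nm, field) {
  v <- regmatches(nm, regexpr(paste0(field, "=\\d+"), nm))
  out <- rep(NA_integer_, length(nm))
  hit <- grepl(paste0(field, "="), nm)
  out[hit] <- as.integer(sub(paste0(field, "="), "", v))
  out
}

#' Assign reads to (species, ortholog group) by diagnostic k-mer voting
#'
#' Each read votes with the diagnostic k-mers it contains (sampled every
#' `stride` positions). It is assigned to the (species, group) with strictly
#' the most votes, provided that winner accounts for at least half of the
#' read's votable k-mers (half of `n_kmers * (1 - shared fraction)`, since
#' shared k-mers never vote) — so a read merely brushing an ORF boundary is not
#' counted toward the ORF, mirroring a mapper that requires the read body to
#' lie in the target. Ties and sub-majority winners are left unassigned.
#' Reads shorter than k are skipped and tallied.
#'
#' The per-base depth profile is reconstructed from the `start=` coordinate
#' metadata in the read names (the simulator's stand-in for an aligner's
#' position); reads without metadata contribute to counts but not to depth.
#'
#' @param reads named character vector of read sequences.
#' @param index a [build_kmer_index()].
#' @param stride sample every `stride`-th k-mer of a read (default 4; purely
#'   a speed/accuracy trade-off).
#' @return list of class `read_assignment`: `counts` (a
#'   [read_count_table()] over every annotated group), `depth` (a
#'   [depth_profile()]), `assignments` (data.table: read, species, group_id;
#'   NA when unassigned), `skipped`.
#' @export
assign_reads <- function(reads, index, stride = 4L) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  ann <- index$annotations
  strain <- "strain"
  if (length(reads) && any(grepl("^[^_]+_r\\d+", names(reads))))
    strain <- sub("_r\\d+.*$", "", names(reads)[1])

  lens <- if (length(reads)) nchar(reads) else integer(0)
  short <- lens < k
  skipped <- sum(short)
  use <- which(!short)
  assignments <- NULL
  counts <- data.table::CJ(group_id = unique(ann$group_id),
                           species = unique(ann$species))
  counts[, count := 0L]

  if (length(use)) {
    rs <- reads[use]
    votes_list <- list()
    diag_km <- index$kmers[diagnostic == TRUE]
    data.table::setkey(diag_km, kmer)
    for (L in unique(lens[use])) {
      ii <- use[lens[use] == L]
      offs <- seq.int(1L, L - k + 1L, by = stride)
      dt <- data.table::data.table(
        read = rep(ii, times = length(offs)),
        kmer = as.vector(vapply(offs, function(o)
          substring(reads[ii], o, o + k - 1L), character(length(ii)))))
      dt[, n_kmers := length(offs)]
      votes_list[[as.character(L)]] <- dt
    }
    allk <- data.table::rbindlist(votes_list)
    hits <- diag_km[allk, on = "kmer", nomatch = NULL]
    votes <- hits[, .(v = .N), by = .(read, species, group_id)]
    nk <- unique(allk[, .(read, n_kmers)])
    data.table::setorder(votes, read, -v)
    best <- votes[, {
      top <- v[1L]
      run <- if (.N > 1L) v[2L] else 0L
      .(species = species[1L], group_id = group_id[1L], v = top, runner = run)
    }, by = read]
    best <- nk[best, on = "read"]
    # a fully-contained read can muster at most ~(1 - shared fraction) of
    # its k-mers as votes, so the content-majority floor is half of that
    floor_frac <- 0.5 * (1 - index$shared_instance_fraction)
    best <- best[v > runner & v >= floor_frac * n_kmers]
    if (nrow(best)) {
      agg <- best[, .(count = .N), by = .(group_id, species)]
      counts[agg, count := i.count, on = c("group_id", "species")]
    }
    assignments <- data.table::data.table(read = names(reads)[use])
    assignments[, `:=`(species = NA_character_, group_id = NA_character_)]
    if (nrow(best)) {
      idx <- match(best$read, use)
      assignments$species[idx] <- best$species
      assignments$group_id[idx] <- best$group_id
    }
  }

  # depth over the parent-A coordinate system from read-name metadata
  dp <- numeric(index$genome_length)
  if (length(use)) {
    starts <- parse_read_meta(names(reads)[use], "start")
    ok <- !is.na(starts)
    if (any(ok)) {
      delta <- numeric(index$genome_length + 1L)
      s1 <- starts[ok] + 1L
      e1 <- pmin(index$genome_length, starts[ok] + lens[use][ok])
      for (i in seq_along(s1)) {
        delta[s1[i]] <- delta[s1[i]] + 1
        delta[e1[i] + 1L] <- delta[e1[i] + 1L] - 1
      }
      dp <- cumsum(delta[seq_len(index$genome_length)])
    }
  }
  depth <- depth_profile(strain, setNames(list(dp), index$chrom))
  rl <- if (length(use)) as.integer(median(lens[use])) else 0L
  if (depth$median_depth == 0 && length(use))
    # reads without positional metadata: fall back to a count-based estimate
    depth$median_depth <- length(use) * rl / index$genome_length
  structure(list(
    counts = read_count_table(strain, as.data.frame(counts), rl,
                              median_depth = depth$median_depth,
                              total_reads = length(use), skipped = skipped),
    depth = depth, assignments = assignments, skipped = skipped),
    class = "read_assignment")
}
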