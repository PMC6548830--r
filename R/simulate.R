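# Synthetic cohort generator: homoploid hybridization followed by LOH.
#
# Parent A is the reference species ("cer" analog), parent B the foreign
# species ("par" analog). All coordinates are 0-based half-open on a single
# chromosome named "chrI" unless configured otherwise.

.CHROM <- "chrI"
.SP_REF <- "cer"
.SP_FOREIGN <- "par"

random_genome <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability d, choosing uniformly
# among the three alternative bases (Jukes-Cantor-like).
mutate_genome <- function(seq, d) {
  if (d == 0) return(seq)
  r <- seq_to_raw(seq)
  idx <- which(runif(length(r)) < d)
  if (length(idx)) {
    base_i <- match(r[idx], .RAW_BASES)
    # row b of .ALT holds the three alternatives to base b
    alt <- matrix(0L, 4, 3)
    for (b in 1:4) alt[b, ] <- setdiff(1:4, b)
    pick <- alt[cbind(base_i, sample.int(3, length(idx), replace = TRUE))]
    r[idx] <- .RAW_BASES[pick]
  }
  raw_to_seq(r)
}

#' Simulate a diverged parental genome pair with ortholog annotations
#'
#' Lays out `n_groups` non-overlapping ORFs on a random genome (parent A),
#' then derives parent B by i.i.d. per-site substitution with probability
#' `divergence`. Ortholog pairs occupy identical coordinates in both parents,
#' so a single annotation table (one row per species per group) describes
#' both.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `hybrid_parents` with elements `genomes` (named
#'   list `cer`/`par` of sequence strings), `annotations` (data.frame with
#'   columns group_id, species, chrom, start, end, strand, length; 0-based
#'   half-open), and `config`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  ng <- config$n_groups
  slot <- L %/% ng
  if (slot < config$orf_length_range[2] + 1L)
    stop(sprintf(paste0("cannot lay out %d non-overlapping ORFs of up to ",
                        "%d bp on %d bp: increase genome_length or shrink ",
                        "ORFs"), ng, config$orf_length_range[2], L),
         call. = FALSE)
  with_seed(config$seed, {
    a <- random_genome(L)
    b <- mutate_genome(a, config$divergence)
    lens <- sample(seq(config$orf_length_range[1], config$orf_length_range[2]),
                   ng, replace = TRUE)
    # one ORF per equal-width slot, random offset; half-open coords
    offs <- vapply(lens, function(l) sample.int(slot - l, 1L), 1L)
    starts <- (seq_len(ng) - 1L) * slot + offs
    ann <- data.frame(
      group_id = sprintf("g%04d", seq_len(ng)),
      chrom = .CHROM, start = starts, end = starts + lens,
      strand = "+", length = lens, stringsAsFactors = FALSE)
    ann <- rbind(cbind(species = .SP_REF, ann),
                 cbind(species = .SP_FOREIGN, ann))
    ann <- ann[order(ann$group_id, ann$species),
               c("group_id", "species", "chrom", "start", "end", "strand",
                 "length")]
    rownames(ann) <- NULL
    structure(list(genomes = list(cer = a, par = b), annotations = ann,
                   config = config),
              class = "hybrid_parents")
  })
}

# Sample per-base origin states for one strain. Returns integer vector over
# 1=CC, 2=PP, 3=CP of length L, plus the per-ORF state vector.
.ORIGIN_LEVELS <- c("CC", "PP", "CP")

sample_origin <- function(parents, config) {
  L <- config$genome_length
  ann <- parents$annotations
  orfs <- ann[ann$species == .SP_REF, ]
  p <- config$origin_state_probs
  if (config$foreign_block_mode == "per_orf") {
    st <- sample.int(3L, nrow(orfs), replace = TRUE, prob = p)
    per_base <- rep(1L, L)
    for (i in seq_len(nrow(orfs)))
      if (st[i] != 1L)
        per_base[(orfs$start[i] + 1L):orfs$end[i]] <- st[i]
  } else {
    # Alternating-renewal block process over {CC, PP, CP}: non-CC blocks have
    # mean length mean_block_length; CC stretches are scaled so the long-run
    # state fractions match origin_state_probs.
    mb <- config$mean_block_length
    p_non <- p[2] + p[3]
    draw_non_cc <- function() if (runif(1) < p[2] / p_non) 2L else 3L
    if (p_non <= 0) {
      per_base <- rep(1L, L)
    } else if (p[1] <= 0) {
      # no reference-homozygous stretches: consecutive non-CC blocks
      pos <- 0; segs_start <- integer(); segs_state <- integer()
      while (pos < L) {
        segs_start <- c(segs_start, pos)
        segs_state <- c(segs_state, draw_non_cc())
        pos <- pos + max(1L, as.integer(ceiling(stats::rexp(1, 1 / mb))))
      }
      per_base <- rep(segs_state, times = diff(c(segs_start, L)))
    } else {
      mean_cc <- mb * p[1] / p_non
      pos <- 0; segs_start <- integer(); segs_state <- integer()
      state <- if (runif(1) < p_non) draw_non_cc() else 1L
      while (pos < L) {
        segs_start <- c(segs_start, pos); segs_state <- c(segs_state, state)
        m <- if (state == 1L) mean_cc else mb
        pos <- pos + max(1L, as.integer(ceiling(stats::rexp(1, 1 / m))))
        state <- if (state == 1L) draw_non_cc() else 1L
      }
      per_base <- rep(segs_state, times = diff(c(segs_start, L)))
    }
    # snap breakpoints so no ORF straddles two states: each ORF takes the
    # state found at its midpoint
    st <- per_base[pmin(L, (orfs$start + orfs$end) %/% 2L + 1L)]
    for (i in seq_len(nrow(orfs)))
      per_base[(orfs$start[i] + 1L):orfs$end[i]] <- st[i]
  }
  list(per_base = per_base, orf_states = .ORIGIN_LEVELS[st], orfs = orfs)
}

#' Simulate hybrid strains and their truth table
#'
#' Assigns every ortholog group of every strain an origin state — `CC`
#' (homozygous parent A), `PP` (homozygous parent B, i.e. foreign), or `CP`
#' (heterozygous, one allele from each parent) — builds the two haplotypes,
#' and derives an N-masked consensus: positions where the two haplotypes
#' disagree (heterozygous sites) become `N`, and a further
#' `consensus_mask_rate` fraction of positions is masked at random to emulate
#' low-confidence base calls.
#'
#' The truth table records, per strain, the per-group state, the homozygous
#' foreign genome fraction (PP bases / genome length; heterozygous tracts
#' retain a reference allele and are not counted), the block tiling of the
#' genome, and true copy numbers from `cnv_specs`.
#'
#' @param parents output of [simulate_parents()].
#' @param config the same [sim_config()].
#' @return a list of class `hybrid_cohort`: `strains` (named list; each has
#'   `strain`, `haplotypes` (2 strings), `consensus`, `orf_states`,
#'   `blocks`), `truth` (list `origin` data.frame, `foreign_fraction` named
#'   vector, `blocks` data.frame, `cnv` data.frame or NULL), `parents`,
#'   `config`.
#' @export
simulate_hybrid <- function(parents, config) {
  stopifnot(inherits(parents, "hybrid_parents"))
  L <- config$genome_length
  ra <- seq_to_raw(parents$genomes$cer)
  rb <- seq_to_raw(parents$genomes$par)
  strains <- list()
  origin_rows <- list()
  block_rows <- list()
  ff <- numeric(0)
  for (si in seq_len(config$n_strains)) {
    id <- sprintf("S%02d", si)
    res <- with_seed(config$seed + 1000L + si, {
      o <- sample_origin(parents, config)
      pb <- o$per_base
      h1 <- ra; h1[pb == 2L] <- rb[pb == 2L]
      h2 <- ra; h2[pb != 1L] <- rb[pb != 1L]
      cons <- h1
      het <- h1 != h2
      cons[het] <- .RAW_N
      if (config$consensus_mask_rate > 0)
        cons[runif(L) < config$consensus_mask_rate] <- .RAW_N
      r <- rle(pb)
      ends <- cumsum(r$lengths)
      blocks <- data.frame(chrom = .CHROM, start = c(0L, head(ends, -1L)),
                           end = ends, origin = .ORIGIN_LEVELS[r$values],
                           stringsAsFactors = FALSE)
      list(strain = id,
           haplotypes = list(raw_to_seq(h1), raw_to_seq(h2)),
           consensus = raw_to_seq(cons),
           per_base_origin = pb,
           orf_states = setNames(o$orf_states, o$orfs$group_id),
           blocks = blocks)
    })
    strains[[id]] <- res
    origin_rows[[id]] <- data.frame(strain = id,
                                    group_id = names(res$orf_states),
                                    state = unname(res$orf_states),
                                    stringsAsFactors = FALSE)
    block_rows[[id]] <- cbind(strain = id, res$blocks)
    ff[id] <- sum(res$per_base_origin == 2L) / L
  }
  truth <- list(
    origin = do.call(rbind, c(origin_rows, make.row.names = FALSE)),
    foreign_fraction = ff,
    blocks = do.call(rbind, c(block_rows, make.row.names = FALSE)),
    cnv = config$cnv_specs)
  structure(list(strains = strains, truth = truth, parents = parents,
                 config = config),
            class = "hybrid_cohort")
}

# Per-(group, species) Poisson rate table for one strain.
count_lambdas <- function(orf_states, ann, config) {
  orfs <- ann[ann$species == .SP_REF, ]
  st <- orf_states[orfs$group_id]
  dos_ref <- ifelse(st == "CC", 1, ifelse(st == "CP", 0.5, 0))
  dos_for <- ifelse(st == "PP", 1, ifelse(st == "CP", 0.5, 0))
  mult <- rep(1, nrow(orfs))
  if (!is.null(config$cnv_specs)) {
    i <- match(config$cnv_specs$group_id, orfs$group_id)
    mult[i[!is.na(i)]] <- config$cnv_specs$copies[!is.na(i)]
  }
  base <- config$depth * orfs$length / config$read_length * mult
  data.frame(group_id = orfs$group_id, length = orfs$length,
             start = orfs$start, end = orfs$end,
             lambda_ref = base * dos_ref, lambda_for = base * dos_for,
             stringsAsFactors = FALSE)
}

#' Simulate read counts, depth profiles and (optionally) reads
#'
#' For each strain, per-ORF read counts are drawn as
#' `Poisson(depth * orf_length * allele_dosage / read_length)` per species
#' (dosage 1 for a homozygous state, 0.5/0.5 for heterozygous), multiplied by
#' the integer copy number for genes listed in `cnv_specs`. A fraction
#' `misassign_rate` of each ORF's reads is then re-counted toward the other
#' species' ortholog. The per-base depth profile is Poisson with mean `depth`
#' (times copy number over amplified genes). When `emit_reads = TRUE`,
#' single-end reads of `read_length` bp are also sampled from the two
#' haplotypes with per-base error `seq_error`; read names carry
#' `|start=<0-based>|hap=<1|2>` metadata standing in for an aligner's
#' coordinates.
#'
#' @param cohort a `hybrid_cohort` from [simulate_hybrid()].
#' @param emit_reads also sample read sequences (slower).
#' @return named list (one element per strain) of lists with `counts` (a
#'   `read_count_table`), `depth` (a `depth_profile`), and `reads` (named
#'   character vector or NULL).
#' @export
simulate_reads <- function(cohort, emit_reads = FALSE) {
  stopifnot(inherits(cohort, "hybrid_cohort"))
  config <- cohort$config
  if (config$depth <= 0) stop("depth must be > 0", call. = FALSE)
  ann <- cohort$parents$annotations
  L <- config$genome_length
  rl <- config$read_length
  m <- config$misassign_rate
  out <- list()
  for (si in seq_along(cohort$strains)) {
    strain <- cohort$strains[[si]]
    out[[strain$strain]] <- with_seed(config$seed + 2000L + si, {
      lam <- count_lambdas(strain$orf_states, ann, config)
      t_ref <- rpois(nrow(lam), lam$lambda_ref)
      t_for <- rpois(nrow(lam), lam$lambda_for)
      # misassignment: thin each species' reads, swap the thinned fraction
      x_rf <- rbinom(nrow(lam), t_ref, m)
      x_fr <- rbinom(nrow(lam), t_for, m)
      n_ref <- t_ref - x_rf + x_fr
      n_for <- t_for - x_fr + x_rf
      counts <- data.frame(
        group_id = rep(lam$group_id, 2L),
        species = rep(c(.SP_REF, .SP_FOREIGN), each = nrow(lam)),
        count = c(n_ref, n_for), stringsAsFactors = FALSE)

      mult <- rep(1, L)
      if (!is.null(config$cnv_specs)) {
        orfs <- lam[match(config$cnv_specs$group_id, lam$group_id), ]
        for (i in seq_len(nrow(orfs)))
          if (!is.na(orfs$start[i]))
            mult[(orfs$start[i] + 1L):orfs$end[i]] <- config$cnv_specs$copies[i]
      }
      dp <- rpois(L, config$depth * mult)
      depth <- depth_profile(strain$strain, setNames(list(dp), .CHROM))

      reads <- NULL
      if (emit_reads) {
        nr <- rpois(1L, config$depth * L / rl)
        starts <- sample.int(L - rl + 1L, nr, replace = TRUE)
        haps <- sample.int(2L, nr, replace = TRUE)
        hr <- lapply(strain$haplotypes, seq_to_raw)
        seqs <- character(nr)
        pos_mat <- outer(starts, 0:(rl - 1L), "+")
        for (h in 1:2) {
          ih <- which(haps == h)
          if (!length(ih)) next
          chars <- matrix(hr[[h]][t(pos_mat[ih, , drop = FALSE])],
                          nrow = rl)
          if (config$seq_error > 0) {
            err <- which(runif(length(chars)) < config$seq_error)
            if (length(err)) {
              bi <- match(chars[err], .RAW_BASES)
              alt <- matrix(0L, 4, 3)
              for (b in 1:4) alt[b, ] <- setdiff(1:4, b)
              chars[err] <- .RAW_BASES[
                alt[cbind(bi, sample.int(3, length(err), replace = TRUE))]]
            }
          }
          seqs[ih] <- apply(chars, 2L, rawToChar)
        }
        names(seqs) <- sprintf("%s_r%06d|start=%d|hap=%d", strain$strain,
                               seq_len(nr), starts - 1L, haps)
        reads <- seqs
      }

      tot <- sum(counts$count) +
        rpois(1L, config$depth * max(0L, L - sum(lam$length)) / rl)
      list(counts = read_count_table(strain$strain, counts, rl,
                                     median_depth = depth$median_depth,
                                     total_reads = tot),
           depth = depth, reads = reads)
    })
  }
  out
}

#' Run the full generative pipeline for a cohort
#'
#' Convenience wrapper: [simulate_parents()] then [simulate_hybrid()] then
#' [simulate_reads()].
#'
#' @inheritParams simulate_reads
#' @param config a [sim_config()].
#' @return the `hybrid_cohort` with an extra element `seq` holding the
#'   [simulate_reads()] output.
#' @export
simulate_cohort <- function(config, emit_reads = FALSE) {
  parents <- simulate_parents(config)
  cohort <- simulate_hybrid(parents, config)
  cohort$seq <- simulate_reads(cohort, emit_reads = emit_reads)
  cohort
}
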