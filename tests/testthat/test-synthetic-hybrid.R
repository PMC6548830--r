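# Generator: parental divergence, hybrid mosaics, counts, depth, truth.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(), "seed")
  expect_error(tiny_config(1, origin_state_probs = c(CC = 0.5, PP = 0.5,
                                                     CP = 0.1)),
               "sum to 1")
  expect_error(tiny_config(1, divergence = 0.8), "0.75")
  expect_error(tiny_config(1, depth = 0), "depth")
  expect_error(tiny_config(1, cnv_specs = data.frame(group_id = "g0001",
                                                     copies = 1.5)),
               "integer")
  expect_s3_class(tiny_config(1), "sim_config")
})

test_that("zero divergence yields identical parents; d=0.10 is calibrated", {
  p0 <- simulate_parents(tiny_config(1, divergence = 0))
  expect_identical(p0$genomes$cer, p0$genomes$par)

  cfg <- sim_config(genome_length = 100000, n_groups = 30, seed = 42)
  p <- simulate_parents(cfg)
  a <- strsplit(p$genomes$cer, "")[[1]]
  b <- strsplit(p$genomes$par, "")[[1]]
  obs <- mean(a != b)
  se <- sqrt(0.10 * 0.90 / cfg$genome_length)
  expect_lt(abs(obs - 0.10), 3 * se)
})

test_that("ORF layout is complete, non-overlapping, coordinate-shared", {
  cfg <- sim_config(genome_length = 1e6, n_groups = 200,
                    orf_length_range = c(500, 1500), seed = 2)
  p <- simulate_parents(cfg)
  ann <- p$annotations
  expect_equal(length(unique(ann$group_id)), 200)
  expect_equal(nrow(ann), 400)  # one row per species per group
  cer <- ann[ann$species == "cer", ]
  cer <- cer[order(cer$start), ]
  expect_true(all(diff(cer$start) >= head(cer$end - cer$start, -1)))
  expect_true(all(cer$length == cer$end - cer$start))
  par <- ann[ann$species == "par", ]
  expect_equal(cer$start, par[order(par$start), "start"])

  expect_error(simulate_parents(tiny_config(1, n_groups = 100)),
               "lay out")
})

test_that("degenerate origin probabilities give the trivial hybrids", {
  cfg <- tiny_config(3, origin_state_probs = c(CC = 1, PP = 0, CP = 0),
                     consensus_mask_rate = 0)
  co <- simulate_hybrid(simulate_parents(cfg), cfg)
  expect_identical(co$strains$S01$haplotypes[[1]], co$parents$genomes$cer)
  expect_identical(co$strains$S01$consensus, co$parents$genomes$cer)
  expect_equal(unname(co$truth$foreign_fraction), 0)

  # whole-genome foreign replacement needs contiguous mode: in per-ORF mode
  # intergenic sequence deliberately stays parent A
  cfg2 <- tiny_config(3, origin_state_probs = c(CC = 0, PP = 1, CP = 0),
                      foreign_block_mode = "contiguous")
  co2 <- simulate_hybrid(simulate_parents(cfg2), cfg2)
  expect_equal(unname(co2$truth$foreign_fraction), 1)
  expect_identical(co2$strains$S01$haplotypes[[1]], co2$parents$genomes$par)
})

test_that("truth blocks tile the genome and match the foreign fraction", {
  cfg <- tiny_config(5, origin_state_probs = c(CC = 0.6, PP = 0.3, CP = 0.1),
                     foreign_block_mode = "contiguous", n_strains = 3)
  co <- simulate_hybrid(simulate_parents(cfg), cfg)
  for (s in names(co$strains)) {
    b <- co$truth$blocks[co$truth$blocks$strain == s, ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], cfg$genome_length)
    expect_equal(b$start[-1], head(b$end, -1))  # disjoint, sorted, tiling
    ff <- sum((b$end - b$start)[b$origin == "PP"]) / cfg$genome_length
    expect_equal(unname(co$truth$foreign_fraction[s]), ff, tolerance = 1e-9)
  }
  # contiguous mode: ORF states agree with the block containing the ORF
  ann <- co$parents$annotations[co$parents$annotations$species == "cer", ]
  for (s in names(co$strains)) {
    b <- co$truth$blocks[co$truth$blocks$strain == s, ]
    mid <- (ann$start + ann$end) %/% 2
    blk <- b$origin[findInterval(mid, b$start)]
    expect_equal(unname(co$strains[[s]]$orf_states[ann$group_id]), blk)
  }
})

test_that("contiguous mode recovers a 3.7% foreign target across 20 seeds", {
  ffs <- vapply(1:20, function(s) {
    cfg <- sim_config(genome_length = 1e6, n_groups = 150,
                      origin_state_probs = c(CC = 0.963, PP = 0.037, CP = 0),
                      foreign_block_mode = "contiguous", seed = s)
    unname(simulate_hybrid(simulate_parents(cfg), cfg)$truth$foreign_fraction)
  }, 0)
  expect_lt(abs(mean(ffs) - 0.037), 0.01)
})

test_that("read counts follow the dosage-weighted Poisson model", {
  # m = 0: foreign counts of CC ORFs are exactly zero, mean count matches
  cfg <- sim_config(genome_length = 5e5, n_groups = 100, depth = 20,
                    origin_state_probs = c(CC = 1, PP = 0, CP = 0),
                    misassign_rate = 0, seed = 8)
  co <- simulate_cohort(cfg)
  cnt <- co$seq$S01$counts$counts
  ann <- co$parents$annotations[co$parents$annotations$species == "cer", ]
  expect_true(all(cnt$count[cnt$species == "par"] == 0))
  lam <- 20 * ann$length[match(cnt$group_id[cnt$species == "cer"],
                               ann$group_id)] / 250
  tot <- sum(cnt$count[cnt$species == "cer"])
  expect_lt(abs(tot - sum(lam)), 3 * sqrt(sum(lam)))

  # chi-square goodness of fit of per-ORF counts against their Poisson means
  obs <- cnt$count[cnt$species == "cer"]
  x2 <- sum((obs - lam)^2 / lam)
  expect_gt(pchisq(x2, df = length(lam), lower.tail = FALSE), 0.01)

  # m = 0.05, all-PP: about 5% of each ORF's reads land on the wrong species
  cfg2 <- sim_config(genome_length = 5e5, n_groups = 100, depth = 20,
                     origin_state_probs = c(CC = 0, PP = 1, CP = 0),
                     misassign_rate = 0.05, seed = 9)
  co2 <- simulate_cohort(cfg2)
  cnt2 <- co2$seq$S01$counts$counts
  frac <- sum(cnt2$count[cnt2$species == "cer"]) / sum(cnt2$count)
  expect_lt(abs(frac - 0.05), 0.01)
})

test_that("CNV genes scale the depth profile by their copy number", {
  cfg <- sim_config(genome_length = 2e5, n_groups = 40, depth = 20,
                    origin_state_probs = c(CC = 1, PP = 0, CP = 0),
                    cnv_specs = data.frame(group_id = "g0005", copies = 15),
                    seed = 4)
  co <- simulate_cohort(cfg)
  ann <- co$parents$annotations
  g <- ann[ann$group_id == "g0005" & ann$species == "cer", ]
  d <- co$seq$S01$depth$depth$chrI[(g$start + 1):g$end]
  expect_lt(abs(mean(d) - 300), 3 * sqrt(300 / length(d)))
  expect_equal(co$seq$S01$depth$median_depth, 20, tolerance = 0.1)
})

test_that("identical config and seed reproduce byte-identical output", {
  cfg <- tiny_config(77, n_strains = 2,
                     origin_state_probs = c(CC = 0.7, PP = 0.2, CP = 0.1))
  a <- simulate_cohort(cfg, emit_reads = TRUE)
  b <- simulate_cohort(cfg, emit_reads = TRUE)
  expect_identical(a$parents$genomes, b$parents$genomes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$seq$S02$counts$counts, b$seq$S02$counts$counts)
  expect_identical(a$seq$S01$reads, b$seq$S01$reads)
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_fasta(a$parents$genomes, fa)
  write_fasta(b$parents$genomes, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})
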