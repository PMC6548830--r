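# SNP extraction, occupancy filter, masking, distances and NJ tree.

# build a consensus set from per-strain allele columns: sites x strains
consensus_from_sites <- function(site_mat, pad = 5) {
  n <- ncol(site_mat)
  filler <- strrep("A", pad)
  setNames(lapply(seq_len(n), function(j)
    paste0(filler, paste(site_mat[, j], collapse = ""), filler)),
    colnames(site_mat))
}

test_that("site occupancy boundaries are inclusive at 85%", {
  # 10 strains: 9 non-N calls (0.90) kept, 8 (0.80) dropped
  m <- matrix("A", nrow = 2, ncol = 10,
              dimnames = list(NULL, sprintf("s%02d", 1:10)))
  m[1, 1] <- "C"; m[1, 2] <- "N"                      # site 1: 9 calls, poly
  m[2, 1] <- "C"; m[2, 2] <- "N"; m[2, 3] <- "N"      # site 2: 8 calls
  snps <- extract_snps(consensus_from_sites(m))
  expect_equal(nrow(snps$sites), 1)
  expect_equal(snps$sites$pos, 5)  # 0-based, after the 5-base pad

  # 20 strains with exactly 17 non-N calls (0.85): retained
  m2 <- matrix("G", nrow = 1, ncol = 20,
               dimnames = list(NULL, sprintf("s%02d", 1:20)))
  m2[1, 1] <- "T"; m2[1, 2:4] <- "N"
  expect_equal(nrow(extract_snps(consensus_from_sites(m2))$sites), 1)
  m2[1, 5] <- "N"  # 16/20 = 0.80 < 0.85
  expect_equal(nrow(extract_snps(consensus_from_sites(m2))$sites), 0)
})

test_that("only polymorphic sites are retained and errors are raised", {
  m <- matrix(c("A", "A", "A",    # invariant
                "A", "C", "A",    # polymorphic
                "N", "N", "A"),   # occupancy fail + invariant
              nrow = 3, byrow = TRUE,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  snps <- extract_snps(consensus_from_sites(m))
  expect_equal(nrow(snps$sites), 1)
  expect_equal(unname(snps$alignment[, 1]), c("A", "C", "A"))
  expect_error(extract_snps(list(s1 = "ACGT")), "at least 2")
})

test_that("the occupancy filter is idempotent and monotone", {
  cfg <- tiny_config(81, n_strains = 6, consensus_mask_rate = 0.1,
                     origin_state_probs = c(CC = 0.8, PP = 0.1, CP = 0.1))
  co <- simulate_cohort(cfg)
  cset <- lapply(co$strains, `[[`, "consensus")
  snps <- extract_snps(cset, occupancy = 0.8)
  # re-extracting from the alignment rows returns the same matrix
  realn <- setNames(lapply(seq_along(cset), function(i)
    paste(snps$alignment[i, ], collapse = "")), names(cset))
  snps2 <- extract_snps(realn, occupancy = 0.8)
  expect_equal(unname(snps2$alignment), unname(snps$alignment))
  # raising occupancy never increases the retained-site count
  counts <- vapply(c(0.5, 0.7, 0.85, 1), function(occ)
    nrow(extract_snps(cset, occupancy = occ)$sites), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("mask_foreign blanks heterospecific blocks", {
  cset <- list(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC")
  expect_identical(mask_foreign(cset, list()), cset)
  masked <- mask_foreign(cset, list(s1 = data.frame(chrom = "chrI",
                                                    start = 0, end = 10)))
  expect_equal(masked$s1, strrep("N", 10))
  expect_equal(masked$s2, cset$s2)
  expect_error(extract_snps(list(s1 = strrep("N", 10),
                                 s2 = strrep("N", 10))), NA)
  expect_equal(nrow(extract_snps(list(s1 = strrep("N", 10),
                                      s2 = "ACGTACGTAC"))$sites), 0)
  expect_error(mask_foreign(cset, list(s1 = data.frame(chrom = "chrI",
                                                       start = 5, end = 2))),
               "malformed")
  # label-aware masking only removes HETEROSPECIFIC rows
  lab <- mask_foreign(cset, list(s1 = data.frame(
    chrom = "chrI", start = c(0, 5), end = c(5, 10),
    label = c("CONSPECIFIC", "HETEROSPECIFIC"))))
  expect_equal(lab$s1, "ACGTANNNNN")
})

test_that("masking foreign blocks shrinks distances to the reference side", {
  # hybrids sharing one hybrid ancestor (the real cohort's situation):
  # their common foreign blocks dominate the unmasked mismatch fraction
  cfg <- sim_config(genome_length = 2e5, n_groups = 40,
                    origin_state_probs = c(CC = 0.75, PP = 0.25, CP = 0),
                    foreign_block_mode = "contiguous",
                    consensus_mask_rate = 0.02, seed = 91)
  co <- simulate_hybrid(simulate_parents(cfg), cfg)
  expect_gt(unname(co$truth$foreign_fraction["S01"]), 0)
  anc <- co$strains$S01$consensus
  set.seed(1)
  cset <- list(hyb1 = mutate_seq(anc, 0.002), hyb2 = mutate_seq(anc, 0.002),
               hyb3 = mutate_seq(anc, 0.002),
               refA1 = mutate_seq(co$parents$genomes$cer, 0.004),
               refA2 = mutate_seq(co$parents$genomes$cer, 0.004))
  d_raw <- distance_tree(extract_snps(cset, occupancy = 0.8))$dist
  b <- co$truth$blocks[co$truth$blocks$strain == "S01", ]
  shared <- data.frame(chrom = b$chrom, start = b$start, end = b$end,
                       label = ifelse(b$origin == "PP", "HETEROSPECIFIC",
                                      "CONSPECIFIC"))
  blocks <- list(hyb1 = shared, hyb2 = shared, hyb3 = shared)
  d_masked <- distance_tree(extract_snps(mask_foreign(cset, blocks),
                                         occupancy = 0.8))$dist
  for (s in c("hyb1", "hyb2", "hyb3"))
    expect_lt(d_masked[s, "refA1"], d_raw[s, "refA1"])
})

test_that("NJ recovers exact branch lengths on a 3-taxon additive matrix", {
  set.seed(17)
  aln <- matrix(sample(c("A", "C", "G", "T"), 300, TRUE), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
  snps <- structure(list(strains = c("a", "b", "c"),
                         sites = data.frame(chrom = "chrI",
                                            pos = 0:(ncol(aln) - 1)),
                         alignment = aln, occupancy = 1),
                    class = "snp_matrix")
  res <- distance_tree(snps)
  d <- res$dist
  # closed-form three-point decomposition
  want <- c(a = (d["a", "b"] + d["a", "c"] - d["b", "c"]) / 2,
            b = (d["a", "b"] + d["b", "c"] - d["a", "c"]) / 2,
            c = (d["a", "c"] + d["b", "c"] - d["a", "b"]) / 2)
  tree <- res$tree
  got <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(got[c("a", "b", "c")], want, tolerance = 1e-12)
  # distance properties
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("degenerate distance inputs are handled", {
  aln <- matrix("A", nrow = 3, ncol = 5,
                dimnames = list(c("a", "b", "c"), NULL))
  snps <- structure(list(strains = c("a", "b", "c"),
                         sites = data.frame(chrom = "chrI", pos = 0:4),
                         alignment = aln, occupancy = 1),
                    class = "snp_matrix")
  res <- distance_tree(snps)
  expect_true(all(res$dist == 0))
  expect_true(all(abs(res$tree$edge.length) < 1e-12))

  aln2 <- aln
  aln2["a", ] <- "N"
  snps$alignment <- aln2
  expect_error(distance_tree(snps), "no jointly called site")
})

test_that("hybrid descendants come out monophyletic on masked matrices", {
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(genome_length = 15e4, n_groups = 30,
                      origin_state_probs = c(CC = 0.9, PP = 0.1, CP = 0),
                      foreign_block_mode = "contiguous",
                      consensus_mask_rate = 0.02, seed = 700 + s)
    co <- simulate_hybrid(simulate_parents(cfg), cfg)
    set.seed(700 + s)
    ancestor <- mutate_seq(co$strains$S01$consensus, 0.005)
    cset <- c(
      setNames(lapply(1:6, function(i) mutate_seq(ancestor, 0.002)),
               sprintf("hyb%d", 1:6)),
      setNames(lapply(1:6, function(i)
        mutate_seq(co$parents$genomes$cer, 0.007)),
        sprintf("bg%d", 1:6)))
    # segment every strain and mask its heterospecific blocks
    blocks <- lapply(cset, function(cons) {
      prof <- label_windows(window_divergence(cons, co$parents$genomes$cer))
      prof$blocks
    })
    snps <- extract_snps(mask_foreign(cset, blocks), occupancy = 0.85)
    tr <- distance_tree(snps)
    if (is_clade(tr, sprintf("hyb%d", 1:6))) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
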