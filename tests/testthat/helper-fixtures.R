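# Shared fixtures and tiny oracles used across test files.

# small, fast default config for unit tests
tiny_config <- function(seed, ...) {
  args <- list(...)
  defaults <- list(genome_length = 50000, n_groups = 20,
                   orf_length_range = c(400, 800), depth = 20,
                   n_strains = 1, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# mutate a sequence string at non-N sites with probability rate (test-local
# re-implementation, independent of the package's internal substitution code)
mutate_seq <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  idx <- which(x != "N" & runif(length(x)) < rate)
  for (i in idx) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

# brute-force per-base mean depth over an ORF for reads fully inside it
brute_force_mean_depth <- function(orf_length, read_starts, read_length) {
  depth <- numeric(orf_length)
  for (s in read_starts) {
    depth[s:(s + read_length - 1L)] <- depth[s:(s + read_length - 1L)] + 1
  }
  mean(depth)
}

# brute-force window mismatch recount (independent of cumsum implementation)
brute_force_divergence <- function(cons, ref, window, step) {
  cc <- strsplit(cons, "")[[1]]
  rr <- strsplit(ref, "")[[1]]
  starts <- seq(0, length(cc) - 1, by = step)
  do.call(rbind, lapply(starts, function(s) {
    e <- min(s + window, length(cc))
    i <- (s + 1):e
    ok <- cc[i] != "N" & rr[i] != "N"
    data.frame(start = s, end = e, compared = sum(ok),
               mismatches = sum(ok & cc[i] != rr[i]))
  }))
}

# naive re-statement of the two origin-call rules, used as an oracle
naive_call <- function(counts, lengths, read_length, median_depth,
                       ref = "cer", presence = 0.25, group_frac = 0.25) {
  mx <- max(counts)
  retained <- if (mx == 0) character(0)
              else names(counts)[counts >= group_frac * mx]
  cov <- counts * read_length / lengths
  pass <- names(counts)[names(counts) %in% retained &
                          cov >= presence * median_depth]
  ref_pass <- ref %in% pass
  foreign_pass <- length(setdiff(pass, ref)) > 0
  if (ref_pass && foreign_pass) "HETEROZYGOUS"
  else if (ref_pass) "REF_ONLY"
  else if (foreign_pass) "FOREIGN"
  else "ABSENT"
}

# map simulator truth states to expected origin calls
state_to_call <- c(CC = "REF_ONLY", PP = "FOREIGN", CP = "HETEROZYGOUS")

# pooled confusion-based precision/recall per class
precision_recall <- function(truth, called, classes) {
  sapply(classes, function(cl) {
    tp <- sum(truth == cl & called == cl)
    c(precision = tp / max(1, sum(called == cl)),
      recall = tp / max(1, sum(truth == cl)))
  })
}
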