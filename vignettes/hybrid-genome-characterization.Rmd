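---
title: "Characterizing hybridization-then-LOH mosaic genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing hybridization-then-LOH mosaic genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridmosaic)
```

## The model

The package targets a specific genomic situation: a homoploid interspecies
hybrid — a diploid formed by fusion of gametes from two species whose
genomes differ at roughly 10% of sites — that subsequently undergoes
massive loss of heterozygosity (LOH), replacing most of the foreign
sub-genome with the reference species' alleles. The surviving genome is a
mosaic with three kinds of territory:

* **CC** — homozygous for the reference species (the bulk of the genome),
* **PP** — homozygous for the foreign species (a few percent, in blocks),
* **CP** — still heterozygous, one allele from each species (rare).

Everything the package computes is a way of reading this mosaic out of
sequencing summaries: competitive per-ORF read counts reveal which allele a
gene carries; windowed consensus divergence reveals the block structure;
depth ratios reveal tandem amplifications (sodium-pump *ENA* arrays,
copper-resistance *CUP1*) that matter for fitness in high-salt niches.

## The foreign-ORF caller

For each ortholog group (the set of corresponding ORFs across the species
panel, sharing coordinates by construction in the simulator), two written
rules are applied to the competitive read counts:

1. *Intra-group read filter.* Within a group, a species' ORF is considered
   only if its read count is at least 25% of the group maximum. This
   controls spurious cross-species alignments: a handful of misassigned
   reads on a diverged ortholog should not create a call.
2. *Presence threshold.* A retained ORF is present when its fold-coverage,
   `count × read_length / orf_length`, is at least one-fourth of the
   strain's median genome coverage. The slack tolerates count heterogeneity
   and, crucially, lets both alleles of a heterozygous ORF (each at ~half
   depth) pass.

Both boundaries are inclusive (`≥`), pinned by boundary tests: counts of
`{100, 25}` retain both species, `{100, 24}` does not; coverage exactly
`median/4` is present. The coverage statistic is normalized per ORF — the
only normalization that yields a number commensurable with median genome
coverage — and equals the base-wise mean depth when reads lie inside the
ORF, which the test suite verifies against a brute-force per-base oracle.

Classification is then mechanical: reference-only → `REF_ONLY`, foreign
only → `FOREIGN`, both → `HETEROZYGOUS`, neither → `ABSENT`. With more than
one foreign species, the best-covered passing foreign species is recorded.
Cohort summaries count a group as foreign content when it is `FOREIGN` *or*
`HETEROZYGOUS` (a heterozygous ORF carries a foreign allele); the
heterozygous percentage is taken over this union.

## Divergence windows and segmentation

The strain consensus (aligned to the reference coordinate system,
low-confidence and heterozygous calls masked to `N`) is compared to the
reference in 10 kb windows with 10 kb steps; mismatches are counted only
where both sequences are non-N (pairwise deletion), and the trailing
partial window keeps its true size. Windows with fewer comparable sites
than `min_sites_fraction` (default 0.5) of their span are `NO_DATA`.

**The decision boundary.** The average divergence between the parental
species (~10%) is the natural reference line to draw on a divergence plot,
but it cannot serve as the classification boundary: a window of purely
foreign origin has divergence fluctuating symmetrically *around* 10%
(binomial SD ≈ 0.3% at 10 kb), so a strict `> 0.10` rule would label only
about half of truly foreign windows heterospecific and halve the estimated
foreign fraction. The default boundary is therefore `threshold = 0.05` —
the midpoint between the conspecific (~0) and heterospecific (~0.10)
divergence modes, where misclassification probability is negligible for
pure windows. The comparison stays strictly `>`, so a window at exactly the
boundary is conspecific (pinned by a test). Mixed windows (an LOH
breakpoint mid-window) go to whichever side holds the majority of the
window, which bounds breakpoint error by one window width — verified
against simulated truth blocks.

The foreign fraction is the heterospecific share of the data-bearing
genome; with everything masked it is reported as missing rather than 0.

## SNP matrix and tree

Sites enter the matrix iff they have unambiguous (non-N) calls in at least
85% of strains — inclusive, so 17/20 qualifies — and at least two distinct
non-N alleles. "Unambiguous high confidence" is operationalized as non-N
because the Q40-style masking upstream is the only confidence signal the
consensus alphabet carries. Invariant sites are excluded; distances
(pairwise mismatch fraction over jointly called sites) are therefore
*polymorphic-site* distances, which rescales but does not reorder
relationships within a fixed matrix. Foreign regions can be masked first
(`mask_foreign()`, driven by the segmentation BED), the standard
preparation for a host-species phylogeny of hybrid strains. The tree is
neighbor joining on those distances with lexicographic strain ordering for
deterministic ties; it is meant for monophyly checks, not branch-support
inference.

One subtlety the tests document: masking foreign blocks provably shrinks a
hybrid's distance to reference-side strains when the hybrids share their
foreign blocks (descendants of one hybridization — the motivating cohort is
monophyletic). For *independent* mosaics the polymorphic-site
renormalization can push the masked distance either way; the test fixture
therefore models shared ancestry.

## Copy-number estimation

For a target gene, `raw_ratio = mean gene depth / median genome depth`, and
the calibrated copy number divides by the same ratio for a single-copy
control gene (an *ACT1* analog): `cn = raw_ratio / control_ratio`. The
control calibration cancels strain-level artifacts and makes the estimate
exactly invariant to rescaling the whole profile (tested to machine
precision). The gene statistic is a mean because short genes make medians
jumpy; the genome statistic is a median (over covered positions) for
robustness. `pass_control` flags strains whose control ratio strays more
than 25% from 1; flank ratios for the neighboring genes distinguish tandem
amplification (flanks ≈ 1) from segmental duplication (flanks elevated).
There is no GC or mappability correction — the simulator has neither bias,
and real-data use would need them. Group comparisons use Kruskal–Wallis
followed by Dunn's rank-sum post hoc with Bonferroni correction; p-values
are reported, never thresholded into verdicts.

## The synthetic world

`sim_config()` fixes the generative model; defaults are the stated
conditions of the motivating system, chosen once:

| parameter | default | why |
|---|---|---|
| `divergence` | 0.10 | average divergence between the parental species |
| `read_length` | 250 bp | MiSeq-style reads |
| `depth` | 20× | typical screening depth; recovery is tested at 5–30× |
| `origin_state_probs` | CC 0.95 / PP 0.04 / CP 0.01 | a genome ~4% foreign with rare heterozygous ORFs, as observed in olive-brine hybrids |
| `mean_block_length` | 10 kb | LOH/introgression blocks at the scale the 10 kb windows are meant to resolve |
| `misassign_rate` | 0.02 | small cross-species mapping bleed-through |
| `seq_error` | 0.005 | post-filter Illumina substitution error |
| `consensus_mask_rate` | 0.02 | sub-Q40 positions masked to N |

Substitutions are uniform over the three alternative bases (a
Jukes–Cantor-style choice; at d = 0.10 the base composition of mismatches
is immaterial to every downstream statistic). Genomes are single-chromosome
because all downstream logic is coordinate-local. Reads are single-end:
counts, not pairing, are what the callers consume. Heterozygous dosage is
fixed at 0.5/0.5 per the homoploid model. In per-ORF mode intergenic
sequence stays parent A (so the foreign fraction tops out at the genic
fraction); contiguous mode lets intergenic sequence follow its block and is
the mode in which whole-genome statements (e.g. "foreign fraction 1") hold.
The truth table's foreign fraction counts homozygous-foreign (PP) bases
only: CP tracts retain a reference allele, and their diverged sites are
N-masked in the consensus, so both the definition and the estimator see the
same quantity.

What the generator does *not* emulate: indels and structural variants
(other than tandem CNV), GC/mappability bias, paired-end artifacts, quality
scores, within-species polymorphism of the parents. A green recovery test
therefore establishes correctness of the statistics under the stated
sampling model — not robustness to alignment artifacts in real data.

## The k-mer assigner

`assign_reads()` stands in for competitive mapping: each read votes with
its diagnostic 21-mers (k-mers unique to one species × group ORF; at d =
0.10 a fraction ≈ 0.9²¹ ≈ 0.11 of ORF k-mers are shared and vote for
nobody). A read is counted for the winner only if it wins strictly and
holds at least half of its *votable* k-mers, `0.5 × n_kmers × (1 − shared
fraction)` — the shared fraction is read off the index, not tuned. The
floor makes a boundary-brushing read count for nothing, so k-mer counts
agree with the direct Poisson counts (which model reads centred on the
ORF) to within a few percent (asserted at ≤5% by the agreement test); a
plain `0.5 × n_kmers` floor systematically undershoots, because shared
k-mers and error-hit k-mers can never vote. Ties go to "unassigned", mirroring
disabled random assignment in real mappers. Depth profiles are rebuilt
from coordinate metadata in the simulated read names — the stand-in for an
aligner's positions, since gapped alignment is deliberately out of scope.

## Numerical conventions

* Coordinates are 0-based half-open throughout; BED on disk, TSV for
  tables, FASTA wrapped at 80 columns.
* Printed percentages round half-up at printed precision (`round_half_up`),
  not banker's rounding: 6.25% → 6.3.
* All randomness flows from the config seed through fixed per-stage
  offsets; identical config + seed reproduces byte-identical FASTA, counts
  and calls (tested), and simulator calls restore the caller's RNG state.
* Degenerate inputs fail loudly: zero median depth, zero-length intervals,
  unknown group ids, strain pairs with no jointly called site.

## Known limitations

* The ORF-coverage normalization ("per ORF") is one reading of an
  ambiguous description of the original pipeline; it is the only reading
  that produces a quantity comparable to median genome coverage.
* Per-paralog resolution inside a tandem array is out of scope; overlapping
  array members are reported as an aggregate.
* The NJ tree is a determinism-friendly internal check, not a substitute
  for likelihood-based phylogenetics.
* Real-data ingestion is via count/depth/consensus tables; BAM/pileup
  parsing is intentionally not built in.
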