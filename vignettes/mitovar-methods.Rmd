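---
title: "Methods: extracting mitochondrial variation from aligned RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting mitochondrial variation from aligned RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovar)
```

## The problem

Mitochondria carry their own genome in hundreds to thousands of copies per
cell, so a cell can harbour a mixture of alleles at one position
(heteroplasmy), quantified as the fraction of reads carrying the
alternative allele. Standard germline variant callers assume a diploid
genotype model and are the wrong tool for this continuous quantity.
Because the mitochondrial contig is transcribed at high levels, ordinary
bulk and single-cell RNA-seq alignments cover it deeply enough to read
allele frequencies (AFs) directly per cell — deeply enough, in fact, that
mtDNA AF profiles can assign cells to their donor of origin and reveal
donor-specific heteroplasmies without any DNA sequencing.

`mitovar` implements this end to end: a pileup engine over BAM files, two
sparse count matrices, per-cell AFs, and the statistical layer on top.

## Pileup model

For every read passing the read-level filters, the engine walks the CIGAR
string and counts only **aligned-match** base calls (`M`/`=`/`X`).
Insertions, deletions, reference skips and soft clips contribute nothing;
a deletion spanning a position adds nothing to its coverage. Base calls of
`N` are never counted. A direct consequence used throughout is that
coverage at a position equals the sum of the four base counts there, so
`alt ≤ coverage` holds exactly and AFs cannot exceed 1.

Filter defaults (all changeable via `pileup_filters()`):

| parameter             | default | rationale |
|-----------------------|---------|-----------|
| `min_base_quality`    | 13      | the samtools-family pileup default |
| `min_mapping_quality` | 0       | mitochondrial reads map uniquely in practice; MAPQ 255 ("unavailable") passes any threshold, as in samtools |
| `exclude_flags`       | secondary, supplementary, duplicate, qc_fail, unmapped | count each fragment once, from its primary alignment |
| `max_depth`           | unlimited | mito depth is the signal here, not a nuisance |
| `dedup_overlaps`      | off     | overlapping mate pairs count twice by default, matching plain pileup semantics; the flag keeps the higher-quality mate call instead |

Two layouts share this code path. **Well** mode takes one BAM per cell
(file stem = cell id; input order = column order). **Droplet** mode
streams a single barcoded BAM and splits calls by a tag (default `CB`);
because most observed barcodes are empty droplets, a whitelist and/or a
minimum mitochondrial read count must be supplied. An optional UMI mode
collapses reads sharing (barcode, UMI) to one vote per position — majority
base, ties broken by summed base quality then alphabetically — but the
default counts reads, not molecules. The contig is matched to the BAM
header by name, falling back to the common aliases chrM/MT/chrMT/M when
the length agrees, since reference-dialect mismatches are the most common
failure mode in practice.

Two decisions worth making explicit: reads spanning the circular origin
are used exactly as the aligner reported them (no circular re-pileup), and
coordinates are 1-based everywhere a user sees them — `3243A>G` means the
3243rd base — except bedGraph output, which is 0-based half-open per that
format's standard.

## Matrices and allele frequencies

`build_matrices()` emits the coverage matrix (positions × cells) and the
alt-count matrix (variants × cells). All three alternative alleles are
materialised (sparsely) for every position whose reference base is
A/C/G/T, ordered by position then alt base, so the row universe depends
only on the reference and matrices from different runs align row-for-row.
Positions with reference base `N` (rCRS 3107) have no alt rows but keep
their coverage.

`calc_allele_frequency()` divides alt counts by the **counted-base
coverage** at the variant's position. Where coverage is below
`min_coverage` (default 1) the AF is *missing*, never zero: in
dropout-heavy single-cell data, imputing 0 would fabricate evidence of
reference homoplasmy at every uncovered site. Every downstream statistic
drops missing values rather than imputing.

Matrices serialise to MatrixMarket with TSV sidecars and a JSON manifest;
the round trip is lossless including row and column order, and the
manifest guards against mixing references of different lengths.

## The statistical layer

**Variable sites.** Variants are ranked by the unbiased sample variance of
their non-missing AFs; sites observed in fewer than `min_covered_cells`
(default 10) cells are excluded, and the top `n` (default 500) are kept.

**Per-site ANOVA.** The model "AF explained by donor identity" is a linear
regression on a single categorical predictor, which is exactly one-way
fixed-effects ANOVA; one code path serves both framings. It is computed
from per-donor sufficient statistics (n, sum, sum of squares), vectorised
across the whole variant universe, with sums of squares in centered form
(group means against the grand mean) to avoid catastrophic cancellation
when between-donor differences are tiny. Donors with fewer than
`min_cells_per_group` (default 2) non-missing cells drop out of a site's
test. Degenerate cases follow the natural conventions: zero within-group
variance with distinct means gives `F = Inf, p = 0`; all values identical
gives `F = 0, p = 1`.

p-values are evaluated in log space (`stats::pf(log.p = TRUE)`, i.e. a
regularised-incomplete-beta tail) because the informative-variant
threshold of `1e-100` sits far below where a naive survival function
underflows; thresholds are compared on log10 p. Raw-p thresholds are used
where the analysis conventions specify them (the `1e-100` informative set,
the AF > 0.9 germline rule); the heteroplasmy scan, which has no
conventional cutoff, defaults to a Bonferroni-adjusted 0.05 over the
candidates it actually tests — conservative where the convention is
silent.

**Discriminative germline variants** are those whose per-donor mean AF
exceeds 0.9 in exactly one donor with every other donor at or below 0.9.
Variants fixed in several donors (shared haplogroup markers) or in all
donors (reference-dialect differences) are deliberately excluded: they
carry no discriminative information. The donor mean is the unweighted mean
over cells with non-missing AF — the literal reading of "average AF per
individual" — with a pooled pseudobulk alternative
(`af_mean = "pooled"`, Σalt/Σcov) available because it is more robust to
uneven per-cell depth.

**Heteroplasmy scan**: (1) compute and exclude the discriminative germline
set (an option excludes the full ANOVA-informative set instead; the
germline set is the default because the scan should not silence genuinely
heteroplasmic sites merely for being statistically loud); (2) keep
variants with at least one donor mean strictly inside (`het_lo`,
`het_hi`) = (1%, 25%); (3) ANOVA across donors with the Bonferroni rule
above. Carriers are the donors whose mean sits in the band.

## Cell-level analyses

Distances are `1 − |Pearson r|` over the sites where both cells are
observed. Taking the absolute value means perfect anti-correlation maps to
distance 0; that is a documented property of this distance, kept for
fidelity to the established formulation. Pairs sharing fewer than
`min_shared_sites` (default 20) sites, or with a constant profile over the
shared sites (r undefined), get the maximal distance 1 and are counted in
an attribute rather than silently imputed. Embedding delegates to Rtsne on
the precomputed distance matrix (perplexity 10, duplicate checking off —
distinct cells can legitimately share a profile); classification delegates
to randomForest on AF features. Missing AFs are encoded as −1, a sentinel
outside [0, 1], so trees can separate "uncovered" from any real frequency
instead of an imputation equating missing with reference. Published
accuracy figures for this kind of classifier do not name a validation
protocol; the default here is out-of-bag accuracy, with k-fold
cross-validation as an option, and both are seeded.

## The simulator

`simulate_study()` generates: a uniform-random reference (`chrM`); donors
with donor-exclusive germline variants (on every covering read) and
heteroplasmies; per-cell reads (Poisson count, uniform starts, fixed
length, default Q30, MAPQ 60, full-match alignments); independent per-base
errors substituting a uniform different base (default 1e-3); and
coordinate-sorted indexed BAMs in either layout, with truth tables, labels
and whitelist. Per-cell heteroplasmy AF is Beta-distributed around the
donor mean μ with dispersion ρ (`sd = sqrt(μ(1−μ)ρ)`), then each covering
read carries the alt with the cell's own AF. The default ρ = 0.05 gives a
per-cell spread of ±0.07 around μ = 0.10, the kind of cell-to-cell
variation reported for genuine donor-specific heteroplasmies. Every draw
flows from the single mandatory seed.

What the simulator deliberately does **not** model — and hence what
passing tests do not demonstrate about real data: 3′ coverage bias and
UMI/PCR duplication of droplet chemistry, alignment artefacts around the
circular origin, nuclear-encoded mitochondrial pseudogenes (NUMTs),
RNA editing, strand-biased damage, or quality-score miscalibration. The
simulator validates the counting and the statistics, not the upstream
alignment.

## Validation sizes and numerical choices

The test suite validates the pileup engine against an independent naive
per-read CIGAR-walking tally (exact equality on randomized BAMs with soft
clips, indels, skips, hard clips, flag combinations and mixed qualities),
and checks well/droplet equivalence by splitting a barcoded BAM per
barcode and re-running the well path (bit-identical matrices). The ANOVA
is checked against `stats::aov()`/`lm()` on 1000 random datasets (relative
agreement ~1e-12) and against the pooled-variance t² identity for two
groups.

Recovery studies use a 3,000 bp synthetic mitochondrial contig — per-site
statistical behaviour depends on per-cell coverage, cells per donor and
donor count, not contig length — at ~50× per-cell coverage and error rate
1e-3: a 4-donor × 50-cell study with 10 donor-exclusive fixed variants per
donor (germline recovery, donor classification across 5 seeds) and an
8-donor × 100-cell droplet study with one μ = 0.10 heteroplasmy per donor
(band recovery and donor-mean accuracy). `scripts/acceptance.R` re-runs
all of this from scratch from a single command-line seed.

Remaining numerical conventions: within/between sums of squares are
clamped at zero and treated as exactly zero below `1e-12 ×` the total sum
of squares (guarding float residue in constructed constant data);
variance ties in site selection break by position then alt base; every
ordering in the package is deterministic for fixed inputs.

## Known limitations

- SNVs only; indels are not called (their CIGAR evidence is ignored).
- No circular-origin handling; positions near the origin inherit whatever
  the aligner did.
- Read-level counting by default: PCR duplicates beyond the `duplicate`
  flag, and mate overlaps unless `dedup_overlaps` is on, count twice.
- No correction for NUMT contamination or RNA editing; a "heteroplasmy"
  call is a statement about aligned RNA reads, not directly about mtDNA.
- One mitochondrial contig per run; nuclear variation is out of scope.
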