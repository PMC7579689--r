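---
title: "Methods: somatic mutation density profiling and regulatory-region enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mutation density profiling and regulatory-region enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and conventions behind each analysis, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices that were genuinely open.

## Coordinates, variant classes, and cohort hygiene

All internal coordinates are 0-based half-open; MAF-like and VCF inputs
(1-based) are converted once at the reading boundary, which keeps every
downstream overlap computation on a single convention. Multi-allelic VCF
rows are split into one record per alternate allele, and anchored indels
are normalised to an explicit `"-"` empty-allele form.

Substitutions are stratified by **reference allele**: pyrimidine
reference (C/T) versus purine reference (G/A), plus indels; the union of
the three is the "all" stratum shown in every profile. This partition
reading is the default because the three classes must cover all SNVs for
the per-class profile counts to conserve totals. The alternative literal
reading — requiring specific ref→alt pairs (C/T→G/A and G/A→C/T) — does
not partition SNVs; it is available as `classify_substitution(...,
mode = "literal")`, which labels the remainder `other`. Multi-base
equal-length variants are rare in exome-style call sets and are
classified by their first base.

Hypermutator samples are excluded by default with Tukey's outer fence on
per-sample burden, count > Q3 + 3·IQR. No published threshold exists for
this step, so the rule and its multiplier are explicit arguments and the
removed samples are reported, never silently dropped. Cohort subsampling
(e.g. to 10 samples) is a pure function of `(cohort, n, seed)`;
`subsample_stability()` repeats an enrichment test over many independent
draws and reports the fold's median/IQR and the fraction of significant
draws, which is how the package operationalises a subsample-based
"permutation" robustness check.

## Scaled profiles

A profile covers `flank_bp` upstream, the feature body, and `flank_bp`
downstream. Flanks use fixed bins (default 50 bp, so 100 bins per 5 kb
flank); the body is cut into `body_bins` (default 40) equal fractions of
its own length, so bodies of different lengths align on one axis. A
position at offset `d` into a body of length `L` falls in bin
`floor(d·B/L)`; bin `j` therefore owns offsets
`[ceil(jL/B), ceil((j+1)L/B))`, and the per-bin aggregate bp used for
frequency normalisation sums these exact widths over features. Features
shorter than `B` pass through the same map (some bins then receive no
bases); a note is emitted. Minus-strand features are mirrored by
measuring offsets from the 3' end, so bin 0 is always biologically
upstream — mirroring the genome *and* flipping all strands describes the
same biology and leaves the profile bin-for-bin identical, a property the
tests check exactly.

Frequency is reported as mutations per Mb per sample,
`count / (bin bp × n_samples) × 1e6`; the y-axis unit is this package's
choice, made explicit because composite-profile figures in the literature
rarely define theirs. A mutation overlapping the windows of two features
counts once per feature window, the natural convention for per-feature
composites; count-conservation tests are stated against that definition.
Indels are located by their first reference base.

`oscillation_score()` is purely descriptive: after a centred moving
average (default 3 bins) it counts sign changes of the first difference
across flank bins and reports the relative amplitude
`(max − min)/mean`, quantifying the alternating high/low mutation
frequency visible around open-chromatin peaks.

## Enrichment tests and their nulls

Per-region rates are pooled event counts divided by region length. Three
nulls are provided:

* **flank** (default): each region's two flanks, pooled per region, give
  one null rate per region; body vs flank rates are compared with an
  unpaired Mann–Whitney *U*.
* **random**: `n_random` chromosome- and length-matched random region
  sets; matching is deliberately *not* GC- or covariate-aware (a stated
  limitation, not an oversight). Candidate placements whose N-run
  reaches half the region length are rejected, with a bounded retry.
* **paired_flank**: Wilcoxon signed-rank on per-region body − flank
  differences (delegated to `stats::wilcox.test`; the unpaired U
  statistic is implemented in this package and cross-checked against
  enumeration and `stats::wilcox.test` in the tests).

Published analyses of this kind name both "Wilcoxon" and "Mann–Whitney"
without stating pairing; both forms are therefore exposed and every
result records which was used.

**Flank width.** The default is length-matched: the two flanks together
cover exactly the region's own length (`L%/%2` left, the remainder
right). This choice is load-bearing. If flanks are much longer than the
body — e.g. 5 kb flanks around a 115 bp miRNA — the body's rate support
is a coarse lattice (`0, 1/L, 2/L, …`) full of zeros while the flank's is
fine-grained, and the rank test loses essentially all power; conversely
if the pooled flank bp differs from the body bp at all, two equal-mean
Poisson rates live on different lattices and the U statistic is no
longer symmetric under the null (its mean shifts visibly below `nm/2`),
so a "null" comparison over-rejects. Equal pooled support makes body and
flank rates exchangeable under a homogeneous rate, giving both power and
calibration. Fixed widths remain available and are used where a window
is conventional: ±300 bp for CTCF binding sites, ±4 kb for histone-mark
peaks, ±5 kb for DNase and gene bodies.

The fold change is computed from pooled counts, not the mean of
per-region ratios, and is `NA` (never a pseudocount) when the null has
zero events. One Benjamini–Hochberg family is applied per reporting run
across all region sets; raw p and q are both written.

**Mann–Whitney implementation.** Average ranks for ties. When both
samples have ≤ 8 observations the p-value is an exhaustive permutation
enumeration over all `choose(n+m, n)` group assignments — valid with
ties and identical to the classical exact distribution without them —
with the two-sided p doubling the smaller tail, capped at 1. Larger
samples use the normal approximation with tie correction and a 0.5
continuity correction. Tail comparisons in the enumeration use an
epsilon of 1e-9 to absorb floating-point rank sums.

## CpG metrics, occurrence, and methylation

The window O/E statistic is `n_CpG/(n_C·n_G) · N²/(N−1)` with N the
window size (default 400 bp, 1 bp step). This normalisation — carrying
`N²/(N−1)` rather than the textbook `N` — is the form this pipeline
standardises on (`convention = "window"`); the classic form is one
argument away, and the two differ by the constant factor `N/(N−1)`.
O/E is `NA` when a window has no C or no G; windows truncated by a
chromosome end are dropped, not padded. The sliding track is computed by
cumulative sums, which is exactly (to machine precision) the per-window
recount, and O/E is invariant under reverse complement, both property-
tested.

**Mutation occurrence** has no standard definition; here it is the
number of mutation events (across samples) within the metric window
centred on a mutated site, inclusive of the site's own event. Every
table that uses the quantity states this definition.

`occurrence_vs_metric()` correlates occurrence with O/E, CpG or GC
content by Spearman rank over mutated sites. Sites are first thinned
greedily (left to right) to at least one window width apart. Without
thinning, neighbouring sites share most of their 400 bp windows, so both
the occurrence and the metric series are strongly autocorrelated and the
rank test's independent-pairs assumption fails badly — null p-values
come out far from uniform. With disjoint windows the retained sites are
independent under sequence-independent mutation placement, and the null
p distribution is uniform (checked by a KS test over replicate
simulations). Occurrence itself still counts all events, including those
at thinned-away sites. The correlation is reported `NA`, with a note,
when there are fewer than three distinct occurrence values or the metric
is constant.

`methylation_around_mutations()` averages CpG methylation levels within
±500 bp of each mutated site (sites with no nearby record are excluded
from bin means, not imputed). `methylation_ct_ratio()` verifies each
methylation record against the reference genome (a record must sit on a
plus-strand C followed by G; the methylation file is never trusted for
CpG-ness), then counts C→T at the cytosine plus G→A at the adjacent
guanine — the same dinucleotide seen from the minus strand — per
methylation stratum (level ≥ 0.5 by default). The ratio of per-CpG rates
is `NA` when a stratum is empty or the unmethylated stratum has no
events. Because per-sample exposure is identical in both strata, the
ratio is scale-free and can be computed on unfiltered cohorts; a
hypermutator inflates numerator and denominator alike.

## The synthetic study

The generator emulates the statistical skeleton of a somatic-mutation
regulatory analysis at desk scale, with every artifact a pure function
of `(config, seed)`:

* **Genome** (default 2 × 1 Mb): i.i.d. bases at GC 0.41, then 80% of
  background CpG dinucleotides rewritten to TpG/CpA (choosing a strand
  at random) to emulate historical methylation-driven CpG depletion —
  without this step an i.i.d. background sits at O/E ≈ 1 and islands
  cannot stand out. Base probabilities are pre-compensated so realized
  GC still lands on the target. CpG islands (25 per chromosome, 1200 bp,
  token mixture tuned to O/E ≈ 1) are planted away from chromosome ends.
* **Annotation**: 120 genes (5'UTR, three CDS exons, two introns,
  3'UTR; random strand) spaced to leave promoter/TTS room; 300 miRNAs of
  80–150 bp split ≈ 55/6.5/38.5% across intron/CDS/intergenic host
  contexts, the proportions reported for the human miRNA complement;
  non-overlapping-within-class peak sets (CTCF 400 × ~300 bp, three
  histone marks 300 × ~1150 bp, DNase 400 × ~600 bp).
* **Methylation**: one record per CpG; island CpGs ~Beta(2, 8)
  (hypomethylated), background ~Beta(8, 2) (mean 0.8, matching the
  bulk-methylated mammalian genome); an optional tumour track scales all
  levels down globally.
* **Mutations**: per sample and base, SNV probability
  `mu0 × ∏ (fold of each covering class)`, folds defaulting to miRNA 3,
  CTCF 2, H3K27me3 1.5, promoter 0.5, others 1. Multiplicative
  composition is the simplest identifiable model for recovery tests; it
  also means realized per-class rate ratios sit slightly off the planted
  folds wherever classes overlap, which the recovery tolerances absorb.
  At methylated CpGs the C→T channel is multiplied by 10 (both strands,
  emitted as G→A on the minus strand), the literature's order of
  magnitude for deamination at methylated cytosines. Indels are added at
  8% of each sample's SNV count — the proportion reported for somatic
  call sets — placed on the fold landscape without the methylation
  boost. Two of the 40 samples mutate at 20× and exist to be caught by
  the hypermutator filter. Events are independent across samples and
  positions: recurrent-site structure arises only from rate
  heterogeneity, and there are no trinucleotide signatures, replication-
  timing covariates, or clustered mutational processes. Passing recovery
  tests on these data therefore demonstrates that the estimators are
  calibrated for rate-heterogeneity structure, not that real tumours
  lack further structure the generator omits.

A guard refuses configurations whose expected event count exceeds 10⁷.

## Numerical and testing choices

Degenerate inputs are handled explicitly rather than by convention:
empty cohorts produce zero profiles; all-tied rank tests return p = 1;
zero-denominator folds and ratios are `NA`; an all-removing hypermutator
threshold is an error, not an empty cohort. Oracle comparisons in the
test suite run at 1e-12 for the sliding metrics and exactly (integer
equality) for profile bin counts.

Problem sizes in the test suite are chosen to finish comfortably on one
CPU: unit fixtures use a 250 kb single-chromosome study; the calibrated
recovery checks sweep 20 default-scale (2 Mb, 40-sample) simulations and
pool the methylation-ratio counts across them, since a single cohort
yields only ~10–20 C→T events at unmethylated CpGs and the per-seed
ratio is correspondingly noisy; the rank-test calibration uses 1000 null
replicates at n = 50/50; the occurrence-correlation calibration uses 200
replicate placements on a 100 kb genome.

## Known limitations

Random-region nulls match chromosome and length only, not GC or
chromatin context. The annotation model imposes a priority order
(miRNA > exonic > 5'UTR > 3'UTR > promoter > TTS > ncRNA > pseudogene >
intronic > intergenic) and promoter/TTS windows (TSS −1000/+100,
TES −100/+1000, strand-aware) that follow common annotation-tool
conventions but are not canonical; all are configurable. The GTF/GFF
ecosystem is out of scope — annotations arrive as BED. The Mann–Whitney
enumeration is exact only up to n = m = 8; beyond that the normal
approximation's accuracy is the usual large-sample one. The generator's
islands are hypomethylated as a class; partially methylated domains,
allele-specific methylation and sample-to-sample methylation variation
are not modelled.
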