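# mutprofiler

Where do somatic mutations concentrate in a tumour genome? `mutprofiler`
is an R package for answering that question the way regulatory-genomics
studies of colorectal and other cancers do: by profiling mutation density
around annotated elements and testing enrichment against explicit nulls.
It is aimed at analysts who have per-sample somatic variant calls (MAF-like
TSV or VCF), a reference FASTA, element annotations in BED, and optionally
per-CpG methylation in bedGraph — and who want calibrated, reproducible
versions of the standard analyses:

- **Scaled metagene profiles.** Each feature body is rescaled to a common
  axis (TSS→TES, or PSS→PES for peaks) with fixed flanks; per-bin mutation
  frequency is reported as mutations/Mb/sample, stratified into Ref-CT
  (pyrimidine reference), Ref-GA (purine reference), indel, and all.
- **Enrichment statistics.** For a region set R with per-region rates
  `r_i = k_i / L_i` (pooled mutation events over region length), the
  package compares `{r_i}` against flanking-region or length/chromosome-
  matched random-region nulls with a Mann-Whitney *U* test (average ranks
  for ties; exhaustive-enumeration p for small samples, tie- and
  continuity-corrected normal approximation otherwise), reports the
  pooled-count fold change
  `fold = (Σk_body / Σbp_body) / (Σk_null / Σbp_null)`,
  and applies one Benjamini–Hochberg family per run.
- **CpG dinucleotide metrics.** Sliding-window (default N = 400 bp, 1 bp
  step) CpG observed/expected ratio
  `OE = n_CpG / (n_C · n_G) · N² / (N − 1)`,
  CpG density `CG = n_CpG/(N−1)` and GC fraction, plus the Spearman
  correlation between a site's *mutation occurrence* (events within the
  window centred on it) and each metric.
- **Methylation coupling.** Mean CpG methylation in 1 kb windows around
  mutated sites, and the C→T rate ratio at methylated vs unmethylated
  CpGs (counting both strands of the dinucleotide, so the minus-strand
  event appears as G→A).
- **Cohort hygiene.** Hypermutator exclusion (Tukey Q3 + 3·IQR on
  per-sample burden, or an absolute cutoff) and seeded subsampling with a
  subsample-stability summary.
- **A synthetic-data generator.** A fully specified toy study — genome
  with CpG islands, genes with sub-elements, miRNAs in intron/CDS/
  intergenic contexts, peak sets (CTCF, H3K27me3, H3K4me3, H3K27ac,
  DNase), a methylation landscape, and a mutation cohort with planted
  per-class fold enrichments, a 10× C→T multiplier at methylated CpGs,
  8% indels and two 20× hypermutators — so every analysis can be
  validated against known ground truth.

## Worked example

Simulate the default study (2 × 1 Mb genome, 40 samples, base rate
mu0 = 5 × 10⁻⁵ per bp per sample) and run the core analyses:

```r
library(mutprofiler)

sim <- simulate_dataset(sim_config(seed = 1))
sim$cohort
#> mutation_cohort: 10294 mutations across 40 samples
#>   classes: indel=784, ref_CT=4767, ref_GA=4743

filt <- filter_hypermutators(sim$cohort)
names(filt$removed_samples)
#> [1] "S003" "S011"            # exactly the two planted hypermutators

cohort <- filt$cohort
enrichment_test(cohort, sim$features$mirnas, "flank",
                region_set_name = "miRNA")
#> enrichment_result 'miRNA': n=300 fold=4.312 p=3.66e-23 (flank null, mann_whitney_normal)

enrichment_test(cohort, sim$features$CTCF, "flank", flank_bp = 300,
                region_set_name = "CTCF")
#> enrichment_result 'CTCF': n=400 fold=1.859 p=8.33e-12 (flank null, mann_whitney_normal)

ct <- methylation_ct_ratio(sim$cohort, sim$methylation, sim$genome)
sprintf("methylated C>T rate ratio: %.2f (%d vs %d events)",
        ct$ratio, ct$events[1], ct$events[2])
#> "methylated C>T rate ratio: 10.97 (578 vs 11 events)"
```

Reading the numbers: the miRNA set carries a strongly elevated pooled
mutation rate relative to its flanks (planted fold 3; single-seed
estimates scatter around ~3.2 because overlapping peak classes compose
multiplicatively), CTCF sites land near their planted 2-fold with the
±300 bp flank window, and the C→T rate at methylated CpGs recovers the
planted 10× multiplier. The unmethylated-CpG event count is small in a
single cohort, so the ratio is noisy per seed; pool counts over seeds for
a tight estimate.

For file-based pipelines, `simulate_dataset(cfg, outdir = ...)` writes
FASTA/BED/bedGraph/MAF inputs, `run_report(data_dir, outdir = ...)`
executes every stage and writes `#`-commented TSV tables, and
`inst/cli/mutprofiler.R` exposes `simulate`/`annotate`/`report`
subcommands for shell use.

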