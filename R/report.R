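# Atomic TSV writer: body written to a temp file, then renamed in place.
write_tsv_atomic <- function(df, path, header_lines = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

read_dir_features <- function(data_dir) {
  bed <- function(nm) {
    p <- file.path(data_dir, paste0(nm, ".bed"))
    if (file.exists(p)) read_bed(p) else NULL
  }
  feats <- list(genes = bed("genes"), cds = bed("cds"),
                utr5 = bed("utr5"), utr3 = bed("utr3"),
                mirnas = bed("mirnas"))
  for (cl in c("CTCF", "H3K27me3", "H3K4me3", "H3K27ac", "DNase"))
    feats[[cl]] <- bed(cl)
  feats
}

#' Run the full analysis over a data directory and write a report
#'
#' Expects the file layout produced by [simulate_dataset()] (or
#' user-supplied equivalents): `genome.fa`, `mutations.maf`, optional
#' `genes.bed`/`cds.bed`/`utr5.bed`/`utr3.bed`/`mirnas.bed`, optional
#' per-class peak BEDs (`CTCF.bed`, `H3K27me3.bed`, `H3K4me3.bed`,
#' `H3K27ac.bed`, `DNase.bed`) and optional `methylation.bedGraph`.
#'
#' Stages: hypermutator filtering; per-category mutation counts; scaled
#' gene and miRNA profiles plus peak-centered profiles with oscillation
#' scores; enrichment of every available region set against its null
#' (CTCF at 300 bp flanks, histone marks at 4 kb, DNase at 5 kb, miRNA
#' and promoters at length-matched flanks, plus a random-region control
#' matched to the miRNAs) with one Benjamini-Hochberg family across the
#' whole run; highly mutated genes and the key-gene split; occurrence vs
#' OE/CG/GC correlations; methylation around mutations and the
#' methylated/unmethylated C-to-T rate ratio; subsample stability of the
#' miRNA enrichment. Raw p and BH q are both reported.
#'
#' @param data_dir input directory.
#' @param outdir output directory for the report TSVs (created; atomic
#'   writes); NULL to skip writing.
#' @param seed seed for every random component (random regions,
#'   subsampling).
#' @param n_subsample,n_draws subsample-stability settings (10 samples,
#'   20 draws by default; `n_draws = 0` skips the stage).
#' @return list of result objects (invisibly when writing).
#' @export
run_report <- function(data_dir, outdir = NULL, seed = 1L,
                       n_subsample = 10L, n_draws = 20L) {
  maf <- file.path(data_dir, "mutations.maf")
  fa <- file.path(data_dir, "genome.fa")
  if (!file.exists(maf) || !file.exists(fa)) {
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_atomic(data.frame(note = "no stage outputs found"),
                       file.path(outdir, "report.tsv"),
                       "# empty report")
    }
    return(invisible(list(note = "no stage outputs found")))
  }
  genome <- read_fasta(fa)
  cohort_raw <- read_mutations(maf, "maf_min")
  filt <- filter_hypermutators(cohort_raw)
  cohort <- filt$cohort
  feats <- read_dir_features(data_dir)
  meth_path <- file.path(data_dir, "methylation.bedGraph")
  meth <- if (file.exists(meth_path))
    read_bedgraph_methylation(meth_path) else NULL

  out <- list(seed = seed,
              removed_hypermutators = filt$removed_samples,
              n_samples = length(cohort$sample_ids),
              n_mutations = n_mutations(cohort))

  model <- NULL
  if (!is.null(feats$genes)) {
    model <- annotation_model(feats$genes, cds = feats$cds,
                              utr5 = feats$utr5, utr3 = feats$utr3,
                              mirnas = feats$mirnas)
    out$category_counts <- count_by_category(cohort, model)
    gf <- gene_mutation_frequency(cohort, feats$genes)
    out$gene_frequency <- gf
    out$top_genes <- top_genes(gf)
    if (length(out$top_genes)) {
      sp <- split_by_genes(cohort, out$top_genes, feats$genes)
      out$key_gene_split <- c(with_key = n_mutations(sp$cohort_in),
                              without_key = n_mutations(sp$cohort_out))
    }
    if (!is.null(feats$mirnas))
      out$mirna_classes <- table(classify_mirnas(feats$mirnas, model))
    out$gene_profile <- scaled_profile(cohort, feats$genes,
                                       profile_spec(flank_bp = 5000L))
  }
  if (!is.null(feats$mirnas))
    out$mirna_profile <- scaled_profile(
      cohort, feats$mirnas, profile_spec(flank_bp = 1000L),
      body_labels = c("TSS", "TES"))

  peak_flanks <- c(CTCF = 300L, H3K27me3 = 4000L, H3K4me3 = 4000L,
                   H3K27ac = 4000L, DNase = 5000L)
  out$peak_profiles <- list(); out$oscillation <- list()
  for (cl in names(peak_flanks)) {
    if (is.null(feats[[cl]])) next
    pr <- peak_profile(cohort, feats[[cl]], flank_bp = peak_flanks[[cl]])
    out$peak_profiles[[cl]] <- pr
    out$oscillation[[cl]] <- oscillation_score(pr)
  }

  results <- list()
  if (!is.null(feats$mirnas)) {
    results <- c(results, list(
      enrichment_test(cohort, feats$mirnas, "flank", seed = seed,
                      region_set_name = "miRNA"),
      enrichment_test(cohort,
                      sample_random_regions(feats$mirnas, genome,
                                            seed = seed),
                      "flank", seed = seed,
                      region_set_name = "random_control")))
  }
  for (cl in names(peak_flanks)) {
    if (is.null(feats[[cl]])) next
    results <- c(results, list(
      enrichment_test(cohort, feats[[cl]], "flank",
                      flank_bp = peak_flanks[[cl]], seed = seed,
                      region_set_name = cl)))
  }
  if (!is.null(model)) {
    g <- feats$genes
    plus <- g$strand != "-"
    prom <- data.frame(chrom = g$chrom,
                       start = ifelse(plus, g$start - 1000L,
                                      g$end - 100L),
                       end = ifelse(plus, g$start + 100L, g$end + 1000L))
    results <- c(results, list(
      enrichment_test(cohort, prom, "flank", seed = seed,
                      region_set_name = "promoter")))
  }
  if (length(results)) {
    results <- bh_adjust(results)
    out$enrichment <- enrichment_table(results)
  }
  if (!is.null(feats$mirnas) && n_draws > 0 &&
      length(cohort$sample_ids) >= n_subsample)
    out$mirna_stability <- subsample_stability(cohort, feats$mirnas,
                                               n_samples = n_subsample,
                                               n_draws = n_draws,
                                               seed = seed)

  out$occurrence_metric <- lapply(
    stats::setNames(c("OE", "CG", "GC"), c("OE", "CG", "GC")),
    function(mt) occurrence_vs_metric(cohort, genome, metric = mt))
  if (!is.null(meth)) {
    out$methylation_bins <- methylation_around_mutations(cohort, meth)
    out$ct_ratio <- methylation_ct_ratio(cohort, meth, genome)
  }
  if (!is.null(outdir)) write_report_files(out, outdir)
  invisible(out)
}

write_report_files <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(paste0("# mutprofiler report, seed=", out$seed),
           paste0("# samples=", out$n_samples, " mutations=",
                  out$n_mutations),
           paste0("# removed_hypermutators=",
                  paste(names(out$removed_hypermutators),
                        collapse = ",")))
  if (!is.null(out$category_counts))
    write_tsv_atomic(data.frame(category = names(out$category_counts),
                                count = as.integer(out$category_counts)),
                     file.path(outdir, "category_counts.tsv"), hdr)
  if (!is.null(out$enrichment))
    write_tsv_atomic(out$enrichment,
                     file.path(outdir, "enrichment.tsv"),
                     c(hdr, "# BH family: all region sets of this run"))
  if (!is.null(out$gene_frequency))
    write_tsv_atomic(out$gene_frequency,
                     file.path(outdir, "gene_frequency.tsv"), hdr)
  for (cl in names(out$peak_profiles))
    write_profile_tsv(out$peak_profiles[[cl]],
                      file.path(outdir, paste0("profile_", cl, ".tsv")))
  if (!is.null(out$gene_profile))
    write_profile_tsv(out$gene_profile,
                      file.path(outdir, "profile_genes.tsv"))
  if (!is.null(out$mirna_profile))
    write_profile_tsv(out$mirna_profile,
                      file.path(outdir, "profile_mirnas.tsv"))
  if (length(out$oscillation)) {
    osc <- do.call(rbind, lapply(names(out$oscillation), function(cl)
      data.frame(peak_class = cl,
                 n_extrema = out$oscillation[[cl]]$n_extrema,
                 amplitude = out$oscillation[[cl]]$amplitude)))
    write_tsv_atomic(osc, file.path(outdir, "oscillation.tsv"), hdr)
  }
  if (!is.null(out$occurrence_metric)) {
    cor_tab <- do.call(rbind, lapply(out$occurrence_metric, function(r)
      data.frame(metric = r$metric, rho = r$rho, p = r$p,
                 n_sites = r$n_sites)))
    write_tsv_atomic(cor_tab,
                     file.path(outdir, "occurrence_correlation.tsv"),
                     c(hdr, paste0("# occurrence = events within the ",
                                   "metric window centred on a mutated",
                                   " site")))
  }
  if (!is.null(out$methylation_bins))
    write_tsv_atomic(out$methylation_bins$bins,
                     file.path(outdir, "methylation_bins.tsv"), hdr)
  if (!is.null(out$ct_ratio))
    write_tsv_atomic(
      data.frame(stratum = c("methylated", "unmethylated"),
                 sites = out$ct_ratio$sites,
                 events = out$ct_ratio$events,
                 rate = out$ct_ratio$rate,
                 ratio = c(out$ct_ratio$ratio, NA)),
      file.path(outdir, "ct_ratio.tsv"), hdr)
  if (!is.null(out$mirna_stability))
    write_tsv_atomic(out$mirna_stability$draws,
                     file.path(outdir, "mirna_stability.tsv"),
                     c(hdr, sprintf(
                       "# fold_median=%.4f fold_iqr=%.4f frac_p<0.05=%.2f",
                       out$mirna_stability$fold_median,
                       out$mirna_stability$fold_iqr,
                       out$mirna_stability$frac_significant)))
  invisible(outdir)
}
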