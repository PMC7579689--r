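toy_model <- function() {
  genes <- data.frame(chrom = "chr1", start = 1000L, end = 5000L,
                      name = "g1", score = "0", strand = "+")
  cds <- data.frame(chrom = "chr1", start = 1000L, end = 1200L,
                    name = "g1", score = "0", strand = "+")
  annotation_model(genes, cds = cds)
}

test_that("mutation annotation follows priority and windows", {
  model <- toy_model()
  mut <- function(pos) data.frame(chrom = "chr1", pos = pos)
  expect_equal(annotate_mutations(mut(1100L), model), "exonic")
  # promoter window TSS-1000..TSS+100 covers position 500
  expect_equal(annotate_mutations(mut(500L), model), "promoter")
  expect_equal(annotate_mutations(mut(3000L), model), "intronic")
  expect_warning(
    out <- annotate_mutations(data.frame(chrom = "chrEmpty",
                                         pos = 999999L), model),
    "absent")
  expect_equal(out, "intergenic")
})

test_that("category counts sum to cohort size and match the oracle", {
  set.seed(12)
  genes <- data.frame(chrom = "chr1",
                      start = c(10000L, 40000L), end = c(20000L, 52000L),
                      name = c("g1", "g2"), score = "0",
                      strand = c("+", "-"))
  cds <- data.frame(chrom = "chr1",
                    start = c(11000L, 42000L), end = c(12000L, 43000L),
                    name = c("g1", "g2"), score = "0", strand = c("+", "-"))
  utr5 <- data.frame(chrom = "chr1", start = 10000L, end = 10500L,
                     name = "g1", score = "0", strand = "+")
  mir <- data.frame(chrom = "chr1", start = c(15000L, 70000L),
                    end = c(15100L, 70120L), name = c("m1", "m2"),
                    score = "0", strand = ".")
  model <- annotation_model(genes, cds = cds, utr5 = utr5, mirnas = mir)
  df <- random_mutation_df(300, max_pos = 90000, seed = 12)
  co <- mutation_cohort(df)
  counts <- count_by_category(co, model)
  expect_equal(sum(counts), n_mutations(co))

  # brute-force oracle over the raw element tables, with promoter/TTS
  # windows spelled out by hand
  tabs <- list(
    "miRNA" = mir, "exonic" = cds, "5'UTR" = utr5, "3'UTR" = NULL,
    "promoter" = data.frame(chrom = "chr1",
                            start = c(10000L - 1000L, 52000L - 100L),
                            end = c(10000L + 100L, 52000L + 1000L)),
    "TTS" = data.frame(chrom = "chr1",
                       start = c(20000L - 100L, 40000L - 1000L),
                       end = c(20000L + 1000L, 40000L + 100L)),
    "ncRNA" = NULL, "pseudogene" = NULL, "intronic" = genes)
  m <- co$mutations
  want <- vapply(seq_len(nrow(m)), function(i)
    oracle_annotate(m$chrom[i], m$pos[i], tabs, model$priority),
    character(1))
  got <- annotate_mutations(co, model)
  expect_equal(got, want)
  # order independence
  shuf <- co
  set.seed(1); idx <- sample(nrow(m))
  expect_equal(sort(annotate_mutations(m[idx, ], model)), sort(got))
})

test_that("empty and planted cohorts give the expected category table", {
  model <- toy_model()
  empty <- mutation_cohort(random_mutation_df(0))
  expect_equal(sum(count_by_category(empty, model)), 0L)
  inter <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                      pos = 50000L + seq_len(100),
                                      ref = "C", alt = "T"))
  counts <- count_by_category(inter, model)
  expect_equal(unname(counts["intergenic"]), 100L)
  expect_equal(sum(counts), 100L)
})

test_that("miRNA host-context classes partition and obey CDS precedence", {
  genes <- data.frame(chrom = "chr1", start = 1000L, end = 9000L,
                      name = "g1", score = "0", strand = "+")
  cds <- data.frame(chrom = "chr1", start = c(1200L, 4000L, 8000L),
                    end = c(1500L, 4300L, 8600L), name = "g1",
                    score = "0", strand = "+")
  model <- annotation_model(genes, cds = cds)
  mir <- data.frame(chrom = "chr1",
                    start = c(2000L, 3950L, 20000L),
                    end = c(2100L, 4050L, 20100L),
                    name = c("in_intron", "spans_cds_and_intron",
                             "intergenic"))
  cls <- classify_mirnas(mir, model)
  expect_equal(cls, c("intron_miRNA", "CDS_miRNA", "intergenic_miRNA"))

  # random toy: classes partition and match a direct overlap oracle
  set.seed(7)
  rmir <- data.frame(chrom = "chr1", start = sample.int(25000, 60),
                     name = sprintf("m%02d", 1:60))
  rmir$end <- rmir$start + 80L
  got <- classify_mirnas(rmir, model)
  ov <- function(df, s, e) any(df$start < e & df$end > s)
  want <- vapply(seq_len(nrow(rmir)), function(i) {
    if (ov(cds, rmir$start[i], rmir$end[i])) "CDS_miRNA"
    else {
      # gene span minus CDS blocks (no UTRs in this toy)
      introns <- data.frame(start = c(1000L, 1500L, 4300L, 8600L),
                            end = c(1200L, 4000L, 8000L, 9000L))
      if (ov(introns, rmir$start[i], rmir$end[i])) "intron_miRNA"
      else "intergenic_miRNA"
    }
  }, character(1))
  expect_equal(got, want)
  expect_equal(length(got), 60L)
})

test_that("gene mutation frequency counts samples once and finds top genes", {
  genes <- data.frame(chrom = "chr1", start = c(100L, 1000L, 5000L),
                      end = c(500L, 2000L, 6000L),
                      name = c("gA", "gB", "gC"), score = "0", strand = "+")
  rows <- rbind(
    data.frame(sample_id = "S1", chrom = "chr1", pos = c(150L, 160L),
               ref = "C", alt = "T"),                     # gA twice, 1 sample
    data.frame(sample_id = c("S2", "S3"), chrom = "chr1",
               pos = c(200L, 300L), ref = "C", alt = "T"),  # gA
    data.frame(sample_id = "S4", chrom = "chr1", pos = 1500L,
               ref = "G", alt = "A"))                      # gB
  co <- mutation_cohort(rows, sample_ids = sprintf("S%d", 1:10))
  tab <- gene_mutation_frequency(co, genes)
  expect_equal(tab$n_samples, c(3L, 1L, 0L))
  expect_equal(tab$fraction, c(0.3, 0.1, 0))
  expect_equal(top_genes(tab), "gA")            # 0.1 is not > 0.1
  expect_equal(top_genes(tab, 1.0), character(0))

  sp <- split_by_genes(co, "gA", genes)
  expect_equal(n_mutations(sp$cohort_in), 4L)
  expect_equal(n_mutations(sp$cohort_out), 1L)
  expect_equal(n_mutations(sp$cohort_in) + n_mutations(sp$cohort_out),
               n_mutations(co))
  sp0 <- split_by_genes(co, character(0), genes)
  expect_equal(n_mutations(sp0$cohort_in), 0L)
})
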