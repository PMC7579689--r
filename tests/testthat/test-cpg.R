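test_that("the O/E window statistic evaluates the printed form exactly", {
  win <- strrep("CG", 200)            # N = 400, nCpG = nC = nG = 200
  oe <- cpg_oe_window(win)
  expect_equal(oe, (200 / (200 * 200)) * 400^2 / 399, tolerance = 1e-12)
  expect_equal(round(oe, 5), 2.00501)
  # the classic normalisation differs by N/(N-1)... i.e. uses N not N^2/(N-1)
  expect_equal(cpg_oe_window(win, convention = "classic"),
               200 * 400 / (200 * 200), tolerance = 1e-12)
  expect_true(is.na(cpg_oe_window(strrep("AT", 200))))
  expect_error(cpg_oe_window("C"), "short")
})

test_that("sliding metrics equal a per-window recount oracle", {
  set.seed(55)
  # 1,000 random 400 bp windows
  for (i in 1:40) {
    win <- paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    want <- oracle_window_metrics(win)
    got <- cpg_oe_window(win)
    expect_equal(got, want$OE, tolerance = 1e-12)
  }
  # incremental 5 kb track vs naive recount at every start
  seqc <- random_genome(5000, seed = 9)[[1]]
  track <- sliding_metrics(seqc, N = 400)
  expect_equal(nrow(track), 5000 - 400 + 1)
  idx <- seq(1, nrow(track), by = 97)      # spot-check a spread of starts
  for (i in idx) {
    win <- substr(seqc, track$start[i] + 1, track$start[i] + 400)
    want <- oracle_window_metrics(win)
    expect_equal(track$n_CpG[i], want$n_CpG)
    expect_equal(track$n_C[i], want$n_C)
    expect_equal(track$n_G[i], want$n_G)
    expect_equal(track$CG[i], want$CG, tolerance = 1e-12)
    expect_equal(track$GC[i], want$GC, tolerance = 1e-12)
    expect_equal(track$OE[i], want$OE, tolerance = 1e-12)
  }
})

test_that("sliding metrics handle edge cases", {
  one <- sliding_metrics(strrep("ACGT", 100), N = 400)
  expect_equal(nrow(one), 1L)
  hom <- sliding_metrics(strrep("A", 500), N = 400)
  expect_true(all(hom$GC == 0))
  expect_true(all(hom$CG == 0))
  expect_true(all(is.na(hom$OE)))
  expect_warning(empty <- sliding_metrics("ACGT", N = 400), "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("O/E is invariant under reverse complement", {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]),
                                      collapse = ""))
  set.seed(66)
  for (i in 1:50) {
    win <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    expect_equal(cpg_oe_window(win), cpg_oe_window(revcomp(win)),
                 tolerance = 1e-12)
  }
})

test_that("mutation occurrence counts events in the centred window", {
  co <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                   pos = 5000L, ref = "C", alt = "T"))
  occ <- mutation_occurrence(co)
  expect_equal(occ$occurrence, 1L)

  # two events 10 bp apart, 400 bp window: both sites see both events
  co <- mutation_cohort(data.frame(sample_id = c("S1", "S2"),
                                   chrom = "chr1", pos = c(5000L, 5010L),
                                   ref = "C", alt = "T"))
  occ <- mutation_occurrence(co)
  expect_equal(occ$occurrence, c(2L, 2L))
  expect_error(mutation_occurrence(co, window_bp = 401L), "even")

  # random fixture vs quadratic brute force (events within +-200 inclusive)
  df <- random_mutation_df(300, max_pos = 20000, seed = 13)
  co <- mutation_cohort(df)
  occ <- mutation_occurrence(co)
  for (i in seq_len(nrow(occ))) {
    want <- sum(abs(df$pos - occ$pos[i]) <= 200)
    expect_equal(occ$occurrence[i], want)
  }
})

test_that("occurrence-metric correlation recovers a monotone toy exactly", {
  # five well-separated blocks with identical base composition but
  # strictly decreasing CpG dinucleotide content (so OE falls block by
  # block); the cluster size (occurrence) increases as block OE decreases.
  # "CGCGAT" carries two CpGs, "GGCCAT" none; both are 2C/2G/1A/1T.
  block <- function(k) {
    unit <- paste0(strrep("CGCGAT", 6 - k), strrep("GGCCAT", k))
    substr(strrep(unit, 200), 1, 4000)
  }
  g <- c(chr1 = paste0(vapply(1:5, block, character(1)), collapse = ""))
  rows <- NULL
  for (k in 1:5) {
    centre <- (k - 1L) * 4000L + 2000L
    rows <- rbind(rows, data.frame(sample_id = "S1", chrom = "chr1",
                                   pos = centre + seq_len(k) * 3L,
                                   ref = "C", alt = "T"))
  }
  co <- mutation_cohort(rows)
  r <- occurrence_vs_metric(co, g, metric = "OE")
  # one retained site per block after thinning
  expect_equal(r$n_sites, 5L)
  expect_equal(unname(r$rho), -1)
  expect_equal(nrow(r$bins), 5L)

  # constant metric -> correlation undefined, note set
  flat <- c(chr1 = strrep("ACGT", 5000))
  r <- occurrence_vs_metric(co, flat, metric = "GC")
  expect_true(is.na(r$rho))
  expect_match(r$note, "undefined")
})

test_that("methylation around mutations averages nearby CpG records", {
  meth <- data.frame(chrom = "chr1",
                     pos = c(900L, 1100L, 5000L),
                     level = c(0.2, 0.6, 1.0), coverage = NA_integer_)
  co <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                   pos = c(1000L, 9000L), ref = "C",
                                   alt = "T"))
  r <- methylation_around_mutations(co, meth, window_bp = 1000L)
  s <- r$sites[order(r$sites$pos), ]
  expect_equal(s$mean_methylation[1], mean(c(0.2, 0.6)))
  expect_true(is.na(s$mean_methylation[2]))     # nothing within +-500
  expect_equal(r$bins$n, 1L)                     # NA site excluded

  # all levels 1.0 -> every bin mean 1.0
  meth$level <- 1
  r <- methylation_around_mutations(co, meth)
  expect_true(all(r$bins$mean_methylation == 1))

  # direct averaging oracle on a random toy
  set.seed(19)
  meth <- data.frame(chrom = "chr1", pos = sort(sample.int(30000, 400)),
                     level = round(runif(400), 3), coverage = NA_integer_)
  df <- random_mutation_df(60, max_pos = 30000, seed = 20)
  co <- mutation_cohort(df)
  r <- methylation_around_mutations(co, meth, window_bp = 1000L)
  for (i in seq_len(nrow(r$sites))) {
    sel <- abs(meth$pos - r$sites$pos[i]) <= 500
    want <- if (any(sel)) mean(meth$level[sel]) else NA_real_
    expect_equal(r$sites$mean_methylation[i], want)
  }
})

test_that("the C-to-T ratio counts both strands of each CpG", {
  g <- c(chr1 = paste0(strrep("A", 100), "CG", strrep("A", 98),
                       "CG", strrep("A", 98)))
  meth <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                     level = c(0.9, 0.1), coverage = NA_integer_)
  # methylated CpG at 100: C>T at 100 and G>A at 101; unmethylated at 200:
  # one C>T
  co <- mutation_cohort(data.frame(
    sample_id = c("S1", "S2", "S1"), chrom = "chr1",
    pos = c(100L, 101L, 200L), ref = c("C", "G", "C"),
    alt = c("T", "A", "T")))
  r <- methylation_ct_ratio(co, meth, g)
  expect_equal(unname(r$events), c(2L, 1L))
  expect_equal(unname(r$sites), c(1L, 1L))
  expect_equal(r$ratio, 2)

  # no C>T events -> NA
  co2 <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                    pos = 100L, ref = "C", alt = "A"))
  expect_true(is.na(methylation_ct_ratio(co2, meth, g)$ratio))

  # non-CpG records are dropped with a warning
  bad <- rbind(meth, data.frame(chrom = "chr1", pos = 5L, level = 0.5,
                                coverage = NA_integer_))
  expect_warning(r2 <- methylation_ct_ratio(co, bad, g), "dropped")
  expect_equal(unname(r2$sites), c(1L, 1L))
})
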