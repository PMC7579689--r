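test_that("region rates equal a direct per-region scan", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L, 500L),
                        end = c(100L, 200L, 600L))
  co <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                   pos = c(10L, 20L, 150L), ref = "C",
                                   alt = "T"))
  expect_equal(region_rates(co, regions), c(0.02, 0.01, 0))
  empty <- mutation_cohort(data.frame(sample_id = character(),
                                      chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           sample_ids = "S1")
  expect_equal(region_rates(empty, regions), c(0, 0, 0))

  set.seed(3)
  regions <- data.frame(chrom = "chr1",
                        start = st <- sample.int(5000, 20) * 10L)
  regions$end <- regions$start + sample.int(300, 20)
  df <- random_mutation_df(500, max_pos = 60000, seed = 6)
  co <- mutation_cohort(df)
  want <- vapply(seq_len(nrow(regions)), function(i)
    sum(df$pos >= regions$start[i] & df$pos < regions$end[i]) /
      (regions$end[i] - regions$start[i]), numeric(1))
  expect_equal(region_rates(co, regions), want)
})

test_that("random regions are matched, deterministic and uniform", {
  genome <- random_genome(100000, seed = 10)
  regions <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                        end = c(200L, 5400L), name = c("a", "b"))
  r1 <- sample_random_regions(regions, genome, seed = 4)
  r2 <- sample_random_regions(regions, genome, seed = 4)
  expect_identical(r1, r2)
  expect_equal(r1$end - r1$start, regions$end - regions$start)
  expect_equal(r1$chrom, regions$chrom)

  # uniform starts: 10,000 draws of a 100 bp region over 100 kb
  many <- data.frame(chrom = "chr1", start = 0L, end = 100L,
                     name = "x")[rep(1, 10000), ]
  draws <- sample_random_regions(many, genome, seed = 8)
  cs <- chisq.test(table(cut(draws$start, breaks = 20)))
  expect_gt(cs$p.value, 0.001)

  # exclusion of the source set
  src <- data.frame(chrom = "chr1", start = 0L, end = 500L,
                    name = "a")[rep(1, 100), ]
  ex <- sample_random_regions(src, genome, seed = 2, exclude_overlap = TRUE)
  expect_true(all(ex$start >= 500L))
  # a source spanning almost the whole chromosome cannot be avoided
  big <- data.frame(chrom = "chr1", start = 0L, end = 99000L, name = "big")
  expect_error(sample_random_regions(big, genome, seed = 2,
                                     exclude_overlap = TRUE), "retries")
})

test_that("random regions avoid N-dominated stretches", {
  g <- c(chr1 = paste0(strrep("N", 9000), strrep("A", 1000)))
  r <- sample_random_regions(data.frame(chrom = "chr1", start = 0L,
                                        end = 500L, name = "q")[rep(1, 50), ],
                             g, seed = 3)
  # accepted placements carry fewer than 250 consecutive Ns
  for (s in r$start) {
    win <- substr(g[[1]], s + 1, s + 500)
    runs <- gregexpr("N+", win)[[1]]
    longest <- if (runs[1] == -1) 0 else max(attr(runs, "match.length"))
    expect_lt(longest, 250)
  }
})

test_that("Mann-Whitney U handles ties, small-sample enumeration and swaps", {
  r <- mann_whitney_u(rep(1, 4), rep(1, 5))
  expect_equal(r$U, 10)              # nm/2 under complete ties
  expect_equal(r$p, 1)

  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.05)            # 1 of choose(6,3)=20 arrangements

  # agreement with the enumeration oracle on random small integer vectors
  set.seed(17)
  for (i in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    x <- sample(0:4, n, replace = TRUE)
    y <- sample(0:4, m, replace = TRUE)
    alt <- sample(c("two_sided", "greater", "less"), 1)
    got <- mann_whitney_u(x, y, alternative = alt)
    want <- oracle_mwu(x, y, alternative = alt)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
    # swapping the samples reflects U and keeps the two-sided p
    sw <- mann_whitney_u(y, x)
    expect_equal(sw$U, n * m - mann_whitney_u(x, y)$U)
    expect_equal(sw$p, mann_whitney_u(x, y)$p)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("large-sample p matches the tie-corrected normal approximation", {
  set.seed(23)
  for (i in 1:10) {
    x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.3), 1)
    got <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("enrichment against flanks detects planted structure", {
  # planted 3x rate inside 200 regions of 200 bp on a 500 kb chromosome
  set.seed(41)
  L <- 500000L
  regions <- data.frame(chrom = "chr1",
                        start = (0:199) * 2500L + 600L)
  regions$end <- regions$start + 200L
  inside <- unlist(mapply(function(s, e) s:(e - 1), regions$start,
                          regions$end))
  lam <- rep(5e-3, L); lam[inside + 1] <- 1.5e-2
  pos <- which(runif(L) < lam) - 1L
  co <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                   pos = pos, ref = "C", alt = "T"))
  r <- enrichment_test(co, regions, "flank", region_set_name = "planted")
  expect_lt(r$p_value, 1e-4)
  expect_gt(r$fold, 2.4)
  expect_lt(r$fold, 3.6)

  # paired flank variant agrees on direction
  rp <- enrichment_test(co, regions, "paired_flank")
  expect_lt(rp$p_value, 1e-3)

  # random-region null with the genome
  genome <- random_genome(L, seed = 2)
  rr <- enrichment_test(co, regions, "random", genome = genome, seed = 9,
                        n_random = 2L)
  expect_lt(rr$p_value, 1e-4)
  expect_gt(rr$fold, 2)
})

test_that("zero-mutation inputs give fold NA and p = 1", {
  regions <- data.frame(chrom = "chr1", start = c(100L, 400L),
                        end = c(200L, 500L))
  empty <- mutation_cohort(data.frame(sample_id = character(),
                                      chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           sample_ids = "S1")
  r <- enrichment_test(empty, regions, "flank")
  expect_true(is.na(r$fold))
  expect_equal(r$p_value, 1)
})

test_that("the pooled fold estimate tightens with sequencing depth", {
  # direct Poisson construction: 200 regions of 100 bp, flanks of 100 bp
  # each side, true fold 2; deep data has 8x the base rate
  fold_err <- function(base_rate, seed) {
    set.seed(seed)
    regions <- data.frame(chrom = "chr1", start = (0:199) * 1000L + 300L)
    regions$end <- regions$start + 100L
    body <- rpois(200, 2 * base_rate * 100)
    flank <- rpois(200, base_rate * 200)
    pos <- c(unlist(mapply(function(s, k) if (k) s + seq_len(k) else NULL,
                           regions$start, body)),
             unlist(mapply(function(s, k) if (k) s - seq_len(k) else NULL,
                           regions$start, flank)))
    co <- mutation_cohort(data.frame(sample_id = "S1", chrom = "chr1",
                                     pos = as.integer(pos), ref = "C",
                                     alt = "T"))
    abs(enrichment_test(co, regions, "flank")$fold - 2)
  }
  shallow <- mean(vapply(1:5, function(s) fold_err(0.02, s), numeric(1)))
  deep <- mean(vapply(1:5, function(s) fold_err(0.16, s + 50), numeric(1)))
  expect_lt(deep, shallow + 0.02)
})

test_that("BH q-values form one monotone family over the run", {
  ps <- c(0.001, 0.2, 0.04, 0.9, 0.0005)
  results <- lapply(seq_along(ps), function(i)
    structure(list(region_set_name = paste0("set", i), n_regions = 10,
                   fold = 1, U = 1, p_value = ps[i], q_value = NA,
                   null_kind = "flank", seed = 1, method = "x",
                   body_events = 0, body_bp = 1, null_events = 0,
                   null_bp = 1), class = "enrichment_result"))
  adj <- bh_adjust(results)
  tab <- enrichment_table(adj)
  expect_equal(tab$q, p.adjust(ps, "BH"))
  o <- order(tab$p)
  expect_true(all(diff(tab$q[o]) >= -1e-12))
})

test_that("subsample stability composes subsampling with the test", {
  sim <- small_sim(1)
  cohort <- filter_hypermutators(sim$cohort)$cohort
  st <- subsample_stability(cohort, sim$features$mirnas, n_samples = 8L,
                            n_draws = 1L, seed = 30L)
  manual <- enrichment_test(subsample_cohort(cohort, 8L, seed = 31L),
                            sim$features$mirnas, seed = 31L)
  expect_equal(st$draws$fold, manual$fold)
  expect_equal(st$draws$p, manual$p_value)
  expect_error(subsample_stability(cohort, sim$features$mirnas,
                                   n_samples = 100L), "fewer")
})
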