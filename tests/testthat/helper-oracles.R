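# Independent brute-force oracles and shared fixtures for the test suite.

# ---- cached simulations (computed once per test run) -----------------------
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_dataset(config)
  .sim_cache[[key]]
}

default_sim <- function(seed) {
  cached_sim(paste0("default_", seed), sim_config(seed = seed))
}

# A small, fast study used by unit tests: one 250 kb chromosome.
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chroms = 1L, chrom_len = 250000L,
             n_genes = 10L, n_mirnas = 24L,
             n_peaks = c(CTCF = 30L, H3K27me3 = 20L, H3K4me3 = 20L,
                         H3K27ac = 20L, DNase = 30L),
             cpg_island_params = list(count_per_chrom = 6L, length = 800L,
                                      oe_target = 1.0),
             mu0 = 2e-4, n_samples = 12L, n_hypermutators = 1L, ...)
}

small_sim <- function(seed = 1L) {
  cached_sim(paste0("small_", seed), small_sim_config(seed = seed))
}

# ---- random fixture builders ----------------------------------------------
random_genome <- function(len, seed, gc = 0.5, nchrom = 1L) {
  set.seed(seed)
  g <- vapply(seq_len(nchrom), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), character(1))
  names(g) <- paste0("chr", seq_len(nchrom))
  g
}

random_mutation_df <- function(n, chrom = "chr1", max_pos = 1e5,
                               n_samples = 5, seed = 1) {
  if (n == 0)
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  data.frame(sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n,
                                replace = TRUE),
             chrom = chrom, pos = sample.int(max_pos, n, replace = TRUE) - 1L,
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# ---- Mann-Whitney enumeration oracle --------------------------------------
# U by direct pair counting; p by enumerating all C(n+m, n) assignments of
# the pooled values to the x-group.
oracle_mwu <- function(x, y, alternative = "two_sided") {
  u_of <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_of(x, y)
  pool <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pool), n)
  us <- apply(combs, 2, function(ix) u_of(pool[ix], pool[-ix]))
  eps <- 1e-9
  p_ge <- mean(us >= u_obs - eps)
  p_le <- mean(us <= u_obs + eps)
  p <- switch(alternative, greater = p_ge, less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  list(U = u_obs, p = p)
}

# ---- per-window CpG metric recount oracle ---------------------------------
oracle_window_metrics <- function(win) {
  N <- nchar(win)
  chars <- strsplit(win, "")[[1]]
  nC <- sum(chars == "C"); nG <- sum(chars == "G")
  starts <- gregexpr("CG", win, fixed = TRUE)[[1]]
  nCpG <- if (starts[1] == -1) 0L else length(starts)
  oe <- if (nC == 0 || nG == 0) NA_real_ else nCpG / (nC * nG) * N^2 / (N - 1)
  list(n_CpG = nCpG, n_C = nC, n_G = nG, CG = nCpG / (N - 1),
       GC = (nC + nG) / N, OE = oe)
}

# ---- brute-force profile oracle -------------------------------------------
# Per-mutation, per-feature direct assignment following the documented
# window/bin definitions, written as plain conditionals.
oracle_profile_counts <- function(mut_df, features, flank_bp, body_bins,
                                  flank_bin_bp, strand_aware = TRUE) {
  nf <- flank_bp / flank_bin_bp
  nbins <- 2 * nf + body_bins
  classes <- c("all", "ref_CT", "ref_GA", "indel")
  counts <- matrix(0L, nbins, length(classes),
                   dimnames = list(NULL, classes))
  for (fi in seq_len(nrow(features))) {
    s <- features$start[fi]; e <- features$end[fi]
    L <- e - s
    str <- if (is.null(features$strand)) "." else features$strand[fi]
    minus <- strand_aware && str == "-"
    for (mi in seq_len(nrow(mut_df))) {
      if (mut_df$chrom[mi] != features$chrom[fi]) next
      p <- mut_df$pos[mi]
      bin <- NA
      if (!minus) {
        if (p >= s - flank_bp && p < s) {
          bin <- floor((p - (s - flank_bp)) / flank_bin_bp)
        } else if (p >= s && p < e) {
          bin <- nf + floor((p - s) * body_bins / L)
        } else if (p >= e && p < e + flank_bp) {
          bin <- nf + body_bins + floor((p - e) / flank_bin_bp)
        }
      } else {
        if (p >= e && p < e + flank_bp) {
          bin <- floor((e + flank_bp - 1 - p) / flank_bin_bp)
        } else if (p >= s && p < e) {
          bin <- nf + floor((e - 1 - p) * body_bins / L)
        } else if (p >= s - flank_bp && p < s) {
          bin <- nf + body_bins + floor((s - 1 - p) / flank_bin_bp)
        }
      }
      if (is.na(bin)) next
      cls <- mut_df$var_class[mi]
      counts[bin + 1, "all"] <- counts[bin + 1, "all"] + 1L
      counts[bin + 1, cls] <- counts[bin + 1, cls] + 1L
    }
  }
  counts
}

# ---- brute-force annotation oracle ----------------------------------------
# category per position by scanning raw element tables in priority order.
oracle_annotate <- function(chrom, pos, element_tables, priority) {
  for (cat in priority) {
    df <- element_tables[[cat]]
    if (is.null(df) || !nrow(df)) next
    hit <- any(df$chrom == chrom & df$start <= pos & pos < df$end)
    if (hit) return(cat)
  }
  "intergenic"
}

expect_no_warning_reparse <- function(path, reader, ...) {
  expect_silent(suppressMessages(reader(path, ...)))
}
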