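# Raw-byte indicator helpers over an {A,C,G,T,N} sequence string.
seq_indicators <- function(seq) {
  b <- charToRaw(seq)
  isC <- b == as.raw(67L); isG <- b == as.raw(71L)
  n <- length(b)
  cg <- if (n >= 2) isC[-n] & isG[-1] else logical(0)
  list(isC = isC, isG = isG, cg_start = cg, n = n)
}

#' CpG observed/expected ratio of one window
#'
#' The O/E statistic used here is
#' `OE = (n_CpG / (n_C * n_G)) * N^2 / (N - 1)` with `N` the window size
#' (`convention = "window"`, the default); the textbook normalisation
#' `OE = n_CpG * N / (n_C * n_G)` is available as
#' `convention = "classic"`. CpG is counted as literal `CG` dinucleotides
#' scanned over all `N - 1` starts. The value is NA when the window has no
#' C or no G.
#'
#' @param seq window sequence over `{A,C,G,T,N}`.
#' @param convention `"window"` (N^2/(N-1) form) or `"classic"` (N form).
#' @return numeric OE (NA when undefined).
#' @export
cpg_oe_window <- function(seq, convention = c("window", "classic")) {
  convention <- match.arg(convention)
  si <- seq_indicators(toupper(seq))
  N <- si$n
  if (N < 2) stop("window too short")
  nC <- sum(si$isC); nG <- sum(si$isG); nCpG <- sum(si$cg_start)
  if (nC == 0 || nG == 0) return(NA_real_)
  if (convention == "window") nCpG / (nC * nG) * N^2 / (N - 1)
  else nCpG * N / (nC * nG)
}

#' Sliding CpG metrics along a sequence
#'
#' One record per window start (0-based) from 0 to `|seq| - N`, at `step`
#' bp intervals. Per window: `n_CpG`, `n_C`, `n_G`, CpG dinucleotide
#' density `CG = n_CpG / (N - 1)`, GC fraction `GC = (n_C + n_G) / N`, and
#' `OE` as in [cpg_oe_window()]. Computed with cumulative sums, which is
#' exactly equivalent to recounting every window.
#'
#' @param seq sequence string.
#' @param N window size in bp (default 400).
#' @param step window step in bp (default 1).
#' @param convention passed to [cpg_oe_window()].
#' @return data.frame (start, n_CpG, n_C, n_G, CG, GC, OE); empty with a
#'   warning when the sequence is shorter than `N`.
#' @export
sliding_metrics <- function(seq, N = 400L, step = 1L,
                            convention = c("window", "classic")) {
  convention <- match.arg(convention)
  seq <- toupper(seq)
  si <- seq_indicators(seq)
  L <- si$n
  if (L < N) {
    warning("sequence shorter than the window; empty track")
    return(data.frame(start = integer(), n_CpG = integer(), n_C = integer(),
                      n_G = integer(), CG = numeric(), GC = numeric(),
                      OE = numeric()))
  }
  cumC <- c(0L, cumsum(si$isC)); cumG <- c(0L, cumsum(si$isG))
  cumCG <- c(0L, cumsum(si$cg_start))
  start <- seq.int(0L, L - N, by = step)
  nC <- cumC[start + N + 1L] - cumC[start + 1L]
  nG <- cumG[start + N + 1L] - cumG[start + 1L]
  nCpG <- cumCG[start + N] - cumCG[start + 1L]
  oe <- ifelse(nC == 0 | nG == 0, NA_real_,
               if (convention == "window") nCpG / (nC * nG) * N^2 / (N - 1)
               else nCpG * N / (nC * nG))
  data.frame(start = start, n_CpG = nCpG, n_C = nC, n_G = nG,
             CG = nCpG / (N - 1), GC = (nC + nG) / N, OE = oe)
}

#' Mutation occurrence per mutated site
#'
#' For each distinct mutated position, the occurrence is the number of
#' mutation events (over all samples) within `window_bp / 2` bp of it,
#' inclusive of itself. This is the package's operational definition of
#' "mutation occurrence"; it is reported wherever the quantity is used.
#'
#' @param cohort a `mutation_cohort`.
#' @param window_bp even window width (default 400).
#' @return data.frame (chrom, pos, occurrence), one row per distinct site.
#' @export
mutation_occurrence <- function(cohort, window_bp = 400L) {
  if (window_bp %% 2L != 0L) stop("window_bp must be even")
  h <- window_bp %/% 2L
  m <- cohort$mutations
  out <- NULL
  for (ch in unique(m$chrom)) {
    ev <- sort(m$pos[m$chrom == ch])
    site <- unique(ev)
    occ <- findInterval(site + h, ev) - findInterval(site - h - 1L, ev)
    out <- rbind(out, data.frame(chrom = ch, pos = site, occurrence = occ,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      occurrence = integer())
  out
}

# Greedy left-to-right thinning: keep sites at least min_spacing apart.
thin_sites <- function(sites, min_spacing) {
  if (!nrow(sites) || min_spacing <= 0) return(sites)
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    idx <- idx[order(sites$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (sites$pos[i] - last >= min_spacing) { keep[i] <- TRUE
        last <- sites$pos[i] }
    }
  }
  sites[keep, , drop = FALSE]
}

#' Correlate mutation occurrence with a sequence metric
#'
#' For each distinct mutated site, computes the chosen metric (`OE`, `CG`
#' or `GC`) on the `window_bp` window centred on it, and the site's
#' occurrence; reports per-occurrence bins (mean metric, n) and the
#' Spearman rank correlation between occurrence and metric across sites.
#' Windows truncated by a chromosome end and NA-metric windows are
#' dropped. Sites are first thinned to `min_spacing` (default: the window
#' width) so retained sites have non-overlapping windows and the rank
#' test's independence assumption holds; occurrence still counts all
#' events, including those at dropped sites.
#'
#' @param cohort a `mutation_cohort`.
#' @param genome named character vector of sequences.
#' @param metric `"OE"`, `"CG"` or `"GC"`.
#' @param window_bp window width centred on each site (default 400).
#' @param min_spacing minimum distance between retained sites (default
#'   `window_bp`; 0 disables thinning).
#' @param convention passed to [cpg_oe_window()].
#' @return list: `bins` (occurrence, mean_metric, n_windows), `rho`, `p`,
#'   `n_sites`, `metric`, `note` (set when the correlation is undefined).
#' @export
occurrence_vs_metric <- function(cohort, genome,
                                 metric = c("OE", "CG", "GC"),
                                 window_bp = 400L, min_spacing = NULL,
                                 convention = c("window", "classic")) {
  metric <- match.arg(metric)
  convention <- match.arg(convention)
  if (is.null(min_spacing)) min_spacing <- window_bp
  h <- window_bp %/% 2L
  sites <- mutation_occurrence(cohort, window_bp)
  sites <- sites[sites$chrom %in% names(genome), , drop = FALSE]
  sites <- thin_sites(sites, min_spacing)
  vals <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    L <- nchar(genome[[ch]])
    tr <- sliding_metrics(genome[[ch]], N = window_bp, step = 1L,
                          convention = convention)
    st <- sites$pos[idx] - h
    ok <- st >= 0 & st + window_bp <= L
    vals[idx[ok]] <- tr[[metric]][st[ok] + 1L]
  }
  keep <- !is.na(vals)
  sites <- sites[keep, , drop = FALSE]
  vals <- vals[keep]
  agg <- if (nrow(sites))
    stats::aggregate(vals, by = list(occurrence = sites$occurrence),
                     FUN = mean) else
    data.frame(occurrence = integer(), x = numeric())
  nb <- if (nrow(sites))
    as.integer(table(factor(sites$occurrence,
                            levels = agg$occurrence))) else integer()
  bins <- data.frame(occurrence = agg$occurrence, mean_metric = agg$x,
                     n_windows = nb)
  if (length(unique(sites$occurrence)) < 3 || length(unique(vals)) < 2) {
    return(list(bins = bins, rho = NA_real_, p = NA_real_,
                n_sites = nrow(sites), metric = metric,
                note = "correlation undefined: <3 distinct occurrence values or constant metric"))
  }
  ct <- suppressWarnings(stats::cor.test(sites$occurrence, vals,
                                         method = "spearman",
                                         exact = FALSE))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value,
       n_sites = nrow(sites), metric = metric, note = NULL)
}

#' Mean CpG methylation around mutated sites
#'
#' For each distinct mutated site, the mean methylation level of CpG
#' records within `window_bp / 2` bp (NA, and excluded from bin means,
#' when no record is nearby). Sites are binned by their mutation
#' occurrence (computed with `occurrence_window_bp`); each bin reports the
#' mean of the per-site means and the number of contributing sites.
#'
#' @param cohort a `mutation_cohort`.
#' @param methylation data.frame from [read_bedgraph_methylation()].
#' @param window_bp methylation window width (default 1000).
#' @param occurrence_window_bp occurrence window (default 400).
#' @return list: `sites` (chrom, pos, occurrence, mean_methylation),
#'   `bins` (occurrence, mean_methylation, n).
#' @export
methylation_around_mutations <- function(cohort, methylation,
                                         window_bp = 1000L,
                                         occurrence_window_bp = 400L) {
  h <- window_bp %/% 2L
  sites <- mutation_occurrence(cohort, occurrence_window_bp)
  mm <- rep(NA_real_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    sel <- methylation$chrom == ch
    mp <- methylation$pos[sel]; lv <- methylation$level[sel]
    o <- order(mp); mp <- mp[o]; lv <- lv[o]
    idx <- which(sites$chrom == ch)
    if (!length(mp)) next
    cum <- c(0, cumsum(lv))
    lo <- findInterval(sites$pos[idx] - h - 1L, mp)
    hi <- findInterval(sites$pos[idx] + h, mp)
    n <- hi - lo
    mm[idx[n > 0]] <- (cum[hi + 1L] - cum[lo + 1L])[n > 0] / n[n > 0]
  }
  sites$mean_methylation <- mm
  with_m <- sites[!is.na(mm), , drop = FALSE]
  agg <- if (nrow(with_m))
    stats::aggregate(with_m$mean_methylation,
                     by = list(occurrence = with_m$occurrence), FUN = mean)
  else data.frame(occurrence = integer(), x = numeric())
  nb <- if (nrow(with_m))
    as.integer(table(factor(with_m$occurrence,
                            levels = agg$occurrence))) else integer()
  list(sites = sites,
       bins = data.frame(occurrence = agg$occurrence,
                         mean_methylation = agg$x, n = nb))
}

#' C-to-T rate ratio at methylated vs unmethylated CpGs
#'
#' Each methylation record is verified against the reference genome to be
#' a plus-strand CpG cytosine (C followed by G); non-CpG records are
#' dropped with a warning. A CpG dinucleotide's C-to-T events are
#' mutations C>T at the cytosine plus G>A at the following guanine (the
#' minus-strand C of the same CpG). The per-stratum rate is events per
#' CpG site, stratified by `level >= level_threshold`; the returned ratio
#' is methylated rate / unmethylated rate (NA when a stratum is empty or
#' the unmethylated stratum has no events).
#'
#' @param cohort a `mutation_cohort`.
#' @param methylation data.frame from [read_bedgraph_methylation()].
#' @param genome named character vector of sequences.
#' @param level_threshold methylation fraction splitting the strata
#'   (default 0.5).
#' @return list with `ratio`, per-stratum `events`, `sites` and `rate`.
#' @export
methylation_ct_ratio <- function(cohort, methylation, genome,
                                 level_threshold = 0.5) {
  meth <- methylation[methylation$chrom %in% names(genome), , drop = FALSE]
  is_cpg <- logical(nrow(meth))
  for (ch in unique(meth$chrom)) {
    idx <- which(meth$chrom == ch)
    b <- charToRaw(genome[[ch]])
    p <- meth$pos[idx]
    ok <- p >= 0 & p + 2L <= length(b)
    is_cpg[idx[ok]] <- b[p[ok] + 1L] == as.raw(67L) &
      b[p[ok] + 2L] == as.raw(71L)
  }
  if (any(!is_cpg))
    warning(sum(!is_cpg), " methylation record(s) not at a CpG cytosine ",
            "in the reference; dropped")
  meth <- meth[is_cpg, , drop = FALSE]
  m <- cohort$mutations
  ev <- integer(nrow(meth))
  for (ch in unique(meth$chrom)) {
    idx <- which(meth$chrom == ch)
    sel <- m$chrom == ch
    ct <- sort(m$pos[sel & m$ref == "C" & m$alt == "T"])
    ga <- sort(m$pos[sel & m$ref == "G" & m$alt == "A"])
    p <- meth$pos[idx]
    ev[idx] <- (findInterval(p, ct) - findInterval(p - 1L, ct)) +
      (findInterval(p + 1L, ga) - findInterval(p, ga))
  }
  methylated <- meth$level >= level_threshold
  n_m <- sum(methylated); n_u <- sum(!methylated)
  e_m <- sum(ev[methylated]); e_u <- sum(ev[!methylated])
  rate_m <- if (n_m) e_m / n_m else NA_real_
  rate_u <- if (n_u) e_u / n_u else NA_real_
  ratio <- if (is.na(rate_m) || is.na(rate_u) || rate_u == 0) NA_real_
    else rate_m / rate_u
  list(ratio = ratio,
       events = c(methylated = e_m, unmethylated = e_u),
       sites = c(methylated = n_m, unmethylated = n_u),
       rate = c(methylated = rate_m, unmethylated = rate_u),
       level_threshold = level_threshold)
}
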