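#' Configuration for the synthetic dataset generator
#'
#' Defines a toy study: a small genome with planted CpG islands, an
#' annotation (genes with sub-elements, miRNAs in three host contexts,
#' peak sets per chromatin class), a per-CpG methylation landscape
#' (islands hypomethylated, background highly methylated) and a somatic
#' mutation cohort in which per-base mutation probability is
#' `mu0 * prod(folds of covering feature classes)`, with an extra
#' multiplier on the C-to-T channel at methylated CpGs and a small number
#' of hypermutator samples at an elevated global rate. Every artifact is a
#' pure function of (config, seed).
#'
#' @param seed base seed (stage seeds are derived from it).
#' @param n_chroms,chrom_len genome shape (default 2 x 1 Mb).
#' @param gc_background background GC fraction (default 0.41).
#' @param n_genes genes across the genome (default 120), each with 5'UTR,
#'   three CDS exons, two introns and a 3'UTR.
#' @param gene_len gene-span length range in bp.
#' @param n_mirnas miRNAs (default 300), length `mirna_len`, split across
#'   intron/CDS/intergenic host contexts by `mirna_split`.
#' @param mirna_len,mirna_split miRNA length range and context fractions.
#' @param n_peaks named per-class peak counts.
#' @param peak_len named list of per-class length ranges.
#' @param cpg_island_params list(count_per_chrom, length, oe_target).
#' @param cpg_depletion fraction of background CpG dinucleotides rewritten
#'   to TpG/CpA (emulating historical methylation-driven CpG loss), so the
#'   background CpG O/E sits far below the island target; base
#'   probabilities are pre-compensated to keep the realized GC at
#'   `gc_background`.
#' @param meth_island,meth_background Beta(shape1, shape2) parameters of
#'   island / background CpG methylation levels.
#' @param tumour_shift relative reduction of methylation levels in the
#'   optional tumour track.
#' @param mu0 base per-bp per-sample SNV probability (default 5e-5).
#' @param fold_enrichment named per-class rate folds (composition across
#'   overlapping classes is multiplicative).
#' @param meth_ct_multiplier C-to-T rate multiplier at methylated CpGs
#'   (default 10; applied to the C of a CpG on either strand, so the
#'   minus-strand event is emitted as G>A).
#' @param meth_threshold methylation level above which a CpG counts as
#'   methylated in the mutation model.
#' @param indel_fraction indel events as a fraction of SNV events
#'   (default 0.08).
#' @param n_samples cohort size (default 40), of which `n_hypermutators`
#'   (default 2) mutate at `hypermutator_rate` (default 20) times `mu0`.
#' @param n_hypermutators,hypermutator_rate see above.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 1e6L,
                       gc_background = 0.41, n_genes = 120L,
                       gene_len = c(3000L, 8000L), n_mirnas = 300L,
                       mirna_len = c(80L, 150L),
                       mirna_split = c(intron = 0.55, cds = 0.065,
                                       intergenic = 0.385),
                       n_peaks = c(CTCF = 400L, H3K27me3 = 300L,
                                   H3K4me3 = 300L, H3K27ac = 300L,
                                   DNase = 400L),
                       peak_len = list(CTCF = c(200L, 400L),
                                       H3K27me3 = c(800L, 1500L),
                                       H3K4me3 = c(800L, 1500L),
                                       H3K27ac = c(800L, 1500L),
                                       DNase = c(400L, 800L)),
                       cpg_island_params = list(count_per_chrom = 25L,
                                                length = 1200L,
                                                oe_target = 1.0),
                       cpg_depletion = 0.8,
                       meth_island = c(2, 8), meth_background = c(8, 2),
                       tumour_shift = 0.25,
                       mu0 = 5e-5,
                       fold_enrichment = c(miRNA = 3.0, CTCF = 2.0,
                                           H3K27me3 = 1.5, promoter = 0.5,
                                           H3K4me3 = 1.0, H3K27ac = 1.0,
                                           DNase = 1.0),
                       meth_ct_multiplier = 10.0, meth_threshold = 0.5,
                       indel_fraction = 0.08, n_samples = 40L,
                       n_hypermutators = 2L, hypermutator_rate = 20) {
  stopifnot(mu0 >= 0, all(fold_enrichment > 0), meth_ct_multiplier >= 0,
            indel_fraction >= 0, n_samples >= 1,
            n_hypermutators <= n_samples)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "x", x$chrom_len, "bp;", x$n_samples,
      "samples (", x$n_hypermutators, "hypermutators ); mu0 =", x$mu0, "\n")
  cat("  folds:", paste(names(x$fold_enrichment), x$fold_enrichment,
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

# CG-token emission probability giving a target classic O/E inside islands
# (an i.i.d. sequence has O/E ~ 1, so targets <= 1 need no CG tokens).
island_cg_prob <- function(oe_target, g1 = 0.5) {
  oe_of <- function(q) {
    B <- 1 + q
    pC <- (q + (1 - q) * g1 / 2) / B
    ncg <- (q + ((1 - q) * g1 / 2)^2) / B
    ncg / (pC * pC)
  }
  if (oe_target <= oe_of(1e-4)) return(0)
  stats::uniroot(function(q) oe_of(q) - oe_target, c(1e-4, 0.6))$root
}

#' Generate the toy genome and CpG-island annotation
#'
#' Background bases are i.i.d. at `gc_background`; islands are emitted by
#' a CpG-token mixture tuned to the configured island O/E target, so
#' island windows score markedly higher CpG O/E than background.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `genome` (named character vector) and `islands`
#'   (BED-style data.frame).
#' @export
generate_genome <- function(config, seed = config$seed) {
  cp <- config$cpg_island_params
  margin <- 10000L
  need <- cp$count_per_chrom * cp$length + 2L * margin
  if (need > config$chrom_len)
    stop("island demands exceed chromosome space")
  q <- island_cg_prob(cp$oe_target)
  local_seed(seed, {
    genome <- character(config$n_chroms)
    names(genome) <- paste0("chr", seq_len(config$n_chroms))
    isl <- NULL
    # pre-compensate GC so that CpG depletion lands on gc_background:
    # each depleted CpG converts one C or G to T/A, losing d*g^2/4 GC.
    d <- config$cpg_depletion
    g0 <- if (d > 0)
      (1 - sqrt(1 - d * config$gc_background)) / (d / 2)
    else config$gc_background
    bg_p <- c(A = (1 - g0) / 2, C = g0 / 2, G = g0 / 2, T = (1 - g0) / 2)
    for (ci in seq_len(config$n_chroms)) {
      L <- config$chrom_len
      s <- sample(names(bg_p), L, replace = TRUE, prob = bg_p)
      if (d > 0) {
        cg <- which(s[-L] == "C" & s[-1] == "G")
        hit <- cg[stats::runif(length(cg)) < d]
        to_c <- stats::runif(length(hit)) < 0.5
        s[hit[to_c]] <- "T"           # CpG -> TpG
        s[hit[!to_c] + 1L] <- "A"     # CpG -> CpA
      }
      starts <- place_nonoverlapping(cp$count_per_chrom,
                                     rep(cp$length, cp$count_per_chrom),
                                     margin, L - margin)
      for (st in starts) {
        tok_n <- cp$length          # generous token budget
        use_cg <- stats::runif(tok_n) < q
        singles <- sample(c("A", "C", "G", "T"), tok_n, replace = TRUE,
                          prob = c(0.25, 0.25, 0.25, 0.25))
        toks <- ifelse(use_cg, "CG", singles)
        island_seq <- substr(paste(toks, collapse = ""), 1, cp$length)
        s[(st + 1):(st + cp$length)] <- strsplit(island_seq, "")[[1]]
      }
      genome[ci] <- paste(s, collapse = "")
      isl <- rbind(isl, data.frame(chrom = names(genome)[ci],
                                   start = starts,
                                   end = starts + cp$length,
                                   name = sprintf("island_%s_%03d",
                                                  names(genome)[ci],
                                                  seq_along(starts)),
                                   score = "0", strand = ".",
                                   stringsAsFactors = FALSE))
    }
    list(genome = genome, islands = isl)
  })
}

# Deterministically place n non-overlapping intervals of the given lengths
# in [lo, hi): lengths in order, random gaps by broken-stick.
place_nonoverlapping <- function(n, lens, lo, hi) {
  if (n == 0L) return(integer(0))
  slack <- (hi - lo) - sum(lens)
  if (slack < 0) stop("placement failure: intervals exceed available space")
  cuts <- sort(stats::runif(n, 0, slack))
  as.integer(floor(lo + cuts + c(0, cumsum(lens))[seq_len(n)]))
}

#' Generate the toy feature annotation
#'
#' Genes (with 5'UTR, three CDS exons, two introns, 3'UTR; random strand)
#' are placed non-overlapping with spacious gaps; miRNAs are planted in
#' the configured host contexts (inside gene introns, inside CDS exons,
#' or in intergenic space) so that [classify_mirnas()] can recover the
#' planted labels; peak sets are placed independently per class,
#' non-overlapping within each class.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()] (`$genome` element).
#' @param seed integer seed.
#' @return list of BED-style data.frames: genes, cds, utr5, utr3, mirnas
#'   (with a `context` column), and one element per peak class.
#' @export
generate_features <- function(config, genome, seed = config$seed + 1L) {
  local_seed(seed, {
    chroms <- names(genome)
    L <- chrom_lengths(genome)
    margin <- 8000L
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chroms + 1)))
    genes <- cds <- utr5 <- utr3 <- NULL
    for (ci in seq_along(chroms)) {
      ng <- per_chrom[ci]
      lens <- sample(seq(config$gene_len[1], config$gene_len[2]), ng,
                     replace = TRUE)
      # reserve 3 kb around every gene for promoter/TTS windows
      starts <- place_nonoverlapping(ng, lens + 6000L, margin,
                                     L[ci] - margin) + 3000L
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      for (gi in seq_len(ng)) {
        g <- gene_structure(chroms[ci], starts[gi], starts[gi] + lens[gi],
                            strand[gi],
                            sprintf("gene_%s_%03d", chroms[ci], gi))
        genes <- rbind(genes, g$gene); cds <- rbind(cds, g$cds)
        utr5 <- rbind(utr5, g$utr5); utr3 <- rbind(utr3, g$utr3)
      }
    }
    mir <- place_mirnas(config, genes, cds, L)
    out <- list(genes = genes, cds = cds, utr5 = utr5, utr3 = utr3,
                mirnas = mir)
    for (cl in names(config$n_peaks)) {
      n <- config$n_peaks[[cl]]
      rng <- config$peak_len[[cl]]
      per <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
      pk <- NULL
      for (ci in seq_along(chroms)) {
        lens <- sample(seq(rng[1], rng[2]), per[ci], replace = TRUE)
        starts <- place_scattered(per[ci], lens, 2000L, L[ci] - 2000L)
        pk <- rbind(pk, data.frame(chrom = chroms[ci], start = starts,
                                   end = starts + lens,
                                   stringsAsFactors = FALSE))
      }
      o <- order(pk$chrom, pk$start)
      pk <- pk[o, , drop = FALSE]
      pk$name <- sprintf("%s_%04d", cl, seq_len(nrow(pk)))
      pk$score <- "0"; pk$strand <- "."
      rownames(pk) <- NULL
      out[[cl]] <- pk
    }
    out
  })
}

# One gene's sub-element layout (coordinates on the genome axis; the
# element order is reversed on '-' genes).
gene_structure <- function(chrom, start, end, strand, name) {
  len <- end - start
  u5 <- 200L; u3 <- 300L; n_cds <- 3L; cds_len <- 250L
  intron <- (len - u5 - u3 - n_cds * cds_len) %/% 2L
  blocks <- list(c("utr5", u5), c("cds", cds_len), c("intron", intron),
                 c("cds", cds_len), c("intron", intron),
                 c("cds", len - u5 - u3 - 2L * cds_len - 2L * intron),
                 c("utr3", u3))
  if (strand == "-") blocks <- rev(blocks)
  cur <- start
  cds <- u5d <- u3d <- NULL
  for (b in blocks) {
    w <- as.integer(b[2])
    seg <- data.frame(chrom = chrom, start = cur, end = cur + w,
                      name = name, score = "0", strand = strand,
                      stringsAsFactors = FALSE)
    if (b[1] == "cds") cds <- rbind(cds, seg)
    if (b[1] == "utr5") u5d <- seg
    if (b[1] == "utr3") u3d <- seg
    cur <- cur + w
  }
  gene <- data.frame(chrom = chrom, start = start, end = end, name = name,
                     score = "0", strand = strand, stringsAsFactors = FALSE)
  list(gene = gene, cds = cds, utr5 = u5d, utr3 = u3d)
}

# Scattered placement with same-class overlap rejection.
place_scattered <- function(n, lens, lo, hi, max_try = 1000L) {
  starts <- integer(0); ends <- integer(0)
  out <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_try)) {
      s <- lo + sample.int(hi - lo - lens[i], 1L)
      if (!any(s < ends & s + lens[i] > starts)) { ok <- TRUE; break }
    }
    if (!ok) stop("placement failure after ", max_try, " retries")
    starts <- c(starts, s); ends <- c(ends, s + lens[i])
    out[i] <- s
  }
  out
}

place_mirnas <- function(config, genes, cds, L) {
  n <- config$n_mirnas
  counts <- round(config$mirna_split / sum(config$mirna_split) * n)
  counts["intergenic"] <- n - counts["intron"] - counts["cds"]
  mlen <- function(k) sample(seq(config$mirna_len[1], config$mirna_len[2]),
                             k, replace = TRUE)
  out <- NULL
  # introns: gene span minus CDS/UTRs; derive directly from the layout
  introns <- NULL
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    # intron blocks are the gaps between consecutive CDS exons
    sub <- cds[cds$name == g$name, ]
    sub <- sub[order(sub$start), ]
    for (k in seq_len(nrow(sub) - 1))
      introns <- rbind(introns,
                       data.frame(chrom = g$chrom, start = sub$end[k],
                                  end = sub$start[k + 1],
                                  stringsAsFactors = FALSE))
  }
  pick <- sample(nrow(introns), counts["intron"])
  lens <- mlen(counts["intron"])
  st <- integer(length(pick))
  for (j in seq_along(pick)) {
    iv <- introns[pick[j], ]
    st[j] <- iv$start + sample.int(iv$end - iv$start - lens[j], 1L)
  }
  out <- rbind(out, data.frame(chrom = introns$chrom[pick], start = st,
                               end = st + lens, context = "intron_miRNA",
                               stringsAsFactors = FALSE))
  pick <- sample(nrow(cds), counts["cds"])
  lens <- mlen(counts["cds"])
  st <- integer(length(pick))
  for (j in seq_along(pick)) {
    iv <- cds[pick[j], ]
    st[j] <- iv$start + sample.int(iv$end - iv$start - lens[j], 1L)
  }
  out <- rbind(out, data.frame(chrom = cds$chrom[pick], start = st,
                               end = st + lens, context = "CDS_miRNA",
                               stringsAsFactors = FALSE))
  # intergenic: keep clear of gene spans plus promoter/TTS margins
  k <- counts["intergenic"]
  lens <- mlen(k)
  placed_s <- integer(0); placed_e <- integer(0); chs <- character(0)
  pad <- 1500L
  gaps <- intergenic_gaps(genes, L, pad)
  w <- gaps$end - gaps$start
  for (j in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      gi <- sample.int(nrow(gaps), 1L, prob = w)
      if (w[gi] <= lens[j] + 1L) next
      s <- gaps$start[gi] + sample.int(w[gi] - lens[j], 1L)
      same <- chs == gaps$chrom[gi]
      if (!any(s < placed_e[same] & s + lens[j] > placed_s[same])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("placement failure for intergenic miRNA ", j)
    placed_s <- c(placed_s, s); placed_e <- c(placed_e, s + lens[j])
    chs <- c(chs, gaps$chrom[gi])
  }
  out <- rbind(out, data.frame(chrom = chs, start = placed_s,
                               end = placed_e, context = "intergenic_miRNA",
                               stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("mirna_%03d", seq_len(nrow(out)))
  out$score <- "0"; out$strand <- "."
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "name", "score", "strand", "context")]
}

intergenic_gaps <- function(genes, L, pad) {
  gaps <- NULL
  for (ch in names(L)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    bounds <- c(2000L, as.vector(rbind(g$start - pad, g$end + pad)),
                L[[ch]] - 2000L)
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e - s > 0
    gaps <- rbind(gaps, data.frame(chrom = ch, start = s[keep],
                                   end = e[keep], stringsAsFactors = FALSE))
  }
  gaps
}

#' Generate the per-CpG methylation landscape
#'
#' One record per plus-strand CpG cytosine in the genome. Island CpGs draw
#' levels from `Beta(meth_island)` (hypomethylated), background CpGs from
#' `Beta(meth_background)` (mean ~0.8). With `tumour = TRUE` all levels
#' are reduced by the configured `tumour_shift` fraction, emulating global
#' tumour hypomethylation.
#'
#' @param config a [sim_config()].
#' @param genome named character vector.
#' @param islands island BED-style data.frame.
#' @param seed integer seed.
#' @param tumour emit the globally shifted tumour track.
#' @return methylation data.frame (chrom, pos, level, coverage).
#' @export
generate_methylation <- function(config, genome, islands,
                                 seed = config$seed + 2L, tumour = FALSE) {
  local_seed(seed, {
    isl_set <- merge_intervals(islands)
    out <- NULL
    for (ch in names(genome)) {
      si <- seq_indicators(genome[[ch]])
      pos <- which(si$cg_start) - 1L
      in_isl <- points_in_set(isl_set, rep(ch, length(pos)), pos)
      lv <- numeric(length(pos))
      lv[in_isl] <- stats::rbeta(sum(in_isl), config$meth_island[1],
                                 config$meth_island[2])
      lv[!in_isl] <- stats::rbeta(sum(!in_isl), config$meth_background[1],
                                  config$meth_background[2])
      if (tumour) lv <- lv * (1 - config$tumour_shift)
      out <- rbind(out, data.frame(chrom = ch, pos = pos,
                                   level = round(lv, 4),
                                   coverage = stats::rpois(length(pos),
                                                           30) + 1L,
                                   stringsAsFactors = FALSE))
    }
    out
  })
}

# Per-chromosome fold-multiplier landscape over the feature classes.
fold_landscape <- function(config, genome, features) {
  folds <- config$fold_enrichment
  lam <- lapply(chrom_lengths(genome), function(L) rep(1, L))
  mult_set <- function(lam, df, f) {
    if (f == 1 || is.null(df) || !nrow(df)) return(lam)
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      idx <- (max(df$start[i], 0L) + 1L):min(df$end[i],
                                             length(lam[[ch]]))
      lam[[ch]][idx] <- lam[[ch]][idx] * f
    }
    lam
  }
  class_regions <- sim_class_regions(config, features)
  for (cl in names(class_regions))
    lam <- mult_set(lam, class_regions[[cl]],
                    if (cl %in% names(folds)) folds[[cl]] else 1)
  lam
}

# Feature regions per rate class, including strand-aware promoters.
sim_class_regions <- function(config, features) {
  g <- features$genes
  plus <- g$strand != "-"
  prom <- data.frame(chrom = g$chrom,
                     start = ifelse(plus, g$start - 1000L, g$end - 100L),
                     end = ifelse(plus, g$start + 100L, g$end + 1000L),
                     stringsAsFactors = FALSE)
  regions <- list(miRNA = features$mirnas, promoter = prom)
  for (cl in names(config$n_peaks)) regions[[cl]] <- features[[cl]]
  regions
}

#' Generate the somatic mutation cohort
#'
#' Per sample and base, the SNV probability is `mu0` times the product of
#' the folds of covering feature classes; at methylated CpGs (level >=
#' `meth_threshold`, both strands of the dinucleotide) the C-to-T channel
#' is multiplied by `meth_ct_multiplier`. Alternate alleles are uniform
#' over the three non-reference bases except in the boosted channel.
#' Indel events are added at `indel_fraction` of each sample's SNV count
#' (half insertions, half deletions) following the same fold landscape
#' without the methylation boost. Hypermutator samples scale all rates by
#' `hypermutator_rate`.
#'
#' @param config a [sim_config()].
#' @param genome named character vector.
#' @param features output of [generate_features()].
#' @param methylation output of [generate_methylation()].
#' @param seed integer seed.
#' @return list with `cohort` (a `mutation_cohort`) and `ground_truth`
#'   (planted folds, hypermutator ids, realized per-class and per-sample
#'   counts).
#' @export
generate_mutations <- function(config, genome, features, methylation,
                               seed = config$seed + 3L) {
  m <- config$meth_ct_multiplier
  lam_base <- fold_landscape(config, genome, features)
  for (ch in names(lam_base)) lam_base[[ch]] <- lam_base[[ch]] * config$mu0
  meth_pos <- list()
  for (ch in names(genome)) {
    sel <- methylation$chrom == ch &
      methylation$level >= config$meth_threshold
    p <- methylation$pos[sel]
    meth_pos[[ch]] <- sort(unique(c(p, p + 1L)))   # C and G of the CpG
  }
  lam_tot <- lam_base
  boost <- 1 + (m - 1) / 3
  for (ch in names(lam_tot))
    lam_tot[[ch]][meth_pos[[ch]] + 1L] <-
      lam_tot[[ch]][meth_pos[[ch]] + 1L] * boost
  n_hyper_units <- config$n_samples +
    config$n_hypermutators * (config$hypermutator_rate - 1)
  if (sum(vapply(lam_tot, sum, numeric(1))) * n_hyper_units > 1e7)
    stop("expected mutation count exceeds 1e7; refusing")
  local_seed(seed, {
    ids <- sprintf("S%03d", seq_len(config$n_samples))
    hyper <- if (config$n_hypermutators)
      sort(sample(ids, config$n_hypermutators)) else character(0)
    rows <- vector("list", 0)
    bases <- c("A", "C", "G", "T")
    for (sid in ids) {
      rate_mult <- if (sid %in% hyper) config$hypermutator_rate else 1
      for (ch in names(genome)) {
        lam <- lam_tot[[ch]] * rate_mult
        pos <- which(stats::runif(length(lam)) < lam) - 1L
        n_snv <- length(pos)
        if (n_snv) {
          b <- charToRaw(genome[[ch]])
          ref <- rawToChar(b[pos + 1L], multiple = TRUE)
          is_meth <- pos %in% meth_pos[[ch]]
          alt <- character(n_snv)
          for (i in seq_len(n_snv)) {
            others <- setdiff(bases, ref[i])
            if (is_meth[i] && ref[i] == "C") {
              alt[i] <- sample(c("T", setdiff(others, "T")), 1,
                               prob = c(m, 1, 1) / (m + 2))
            } else if (is_meth[i] && ref[i] == "G") {
              alt[i] <- sample(c("A", setdiff(others, "A")), 1,
                               prob = c(m, 1, 1) / (m + 2))
            } else alt[i] <- sample(others, 1)
          }
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = sid, chrom = ch, pos = pos, ref = ref,
                       alt = alt, stringsAsFactors = FALSE)
        }
        n_ind <- stats::rbinom(1L, n_snv, config$indel_fraction)
        if (n_ind) {
          ip <- sample.int(length(lam), n_ind,
                           prob = lam_base[[ch]]) - 1L
          b <- charToRaw(genome[[ch]])
          iref <- rawToChar(b[ip + 1L], multiple = TRUE)
          is_del <- stats::runif(n_ind) < 0.5
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = sid, chrom = ch, pos = ip,
                       ref = ifelse(is_del, iref, "-"),
                       alt = ifelse(is_del, "-",
                                    sample(bases, n_ind, replace = TRUE)),
                       stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 stringsAsFactors = FALSE)
    cohort <- mutation_cohort(df, sample_ids = ids,
                              provenance = "synthetic cohort")
    gt <- sim_ground_truth(config, cohort, features, hyper)
    list(cohort = cohort, ground_truth = gt)
  })
}

sim_ground_truth <- function(config, cohort, features, hyper) {
  regions <- sim_class_regions(config, features)
  class_counts <- vapply(regions, function(df) {
    set <- merge_intervals(df)
    sum(points_in_set(set, cohort$mutations$chrom, cohort$mutations$pos))
  }, numeric(1))
  list(true_folds = config$fold_enrichment,
       meth_ct_multiplier = config$meth_ct_multiplier,
       hypermutators = hyper,
       per_sample_counts = sample_counts(cohort),
       per_class_counts = class_counts,
       n_mutations = n_mutations(cohort))
}

#' Generate (and optionally write) the complete synthetic dataset
#'
#' Runs all generator stages with seeds derived from `config$seed` and,
#' when `outdir` is given, writes FASTA, BED sets, bedGraph methylation,
#' the MAF-dialect cohort, a ground-truth TSV and the resolved config.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing), or NULL to skip
#'   writing.
#' @return invisible list: genome, islands, features, methylation, cohort,
#'   ground_truth.
#' @export
simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  gg <- generate_genome(config, seed = config$seed)
  feats <- generate_features(config, gg$genome, seed = config$seed + 1L)
  meth <- generate_methylation(config, gg$genome, gg$islands,
                               seed = config$seed + 2L)
  mu <- generate_mutations(config, gg$genome, feats, meth,
                           seed = config$seed + 3L)
  out <- list(genome = gg$genome, islands = gg$islands, features = feats,
              methylation = meth, cohort = mu$cohort,
              ground_truth = mu$ground_truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(gg$genome, file.path(outdir, "genome.fa"))
    write_bed(gg$islands, file.path(outdir, "cpg_islands.bed"))
    for (nm in c("genes", "cds", "utr5", "utr3", names(config$n_peaks)))
      write_bed(feats[[nm]], file.path(outdir, paste0(nm, ".bed")))
    write_bed(feats$mirnas[, c("chrom", "start", "end", "name", "score",
                               "strand")],
              file.path(outdir, "mirnas.bed"))
    utils::write.table(feats$mirnas[, c("name", "context")],
                       file.path(outdir, "mirna_contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph_methylation(meth, file.path(outdir,
                                               "methylation.bedGraph"))
    write_mutations_maf(mu$cohort, file.path(outdir, "mutations.maf"))
    gt <- mu$ground_truth
    gt_lines <- c("# ground truth",
                  paste0("hypermutators\t",
                         paste(gt$hypermutators, collapse = ",")),
                  paste0("n_mutations\t", gt$n_mutations),
                  paste0("fold_", names(gt$true_folds), "\t",
                         gt$true_folds),
                  paste0("count_", names(gt$per_class_counts), "\t",
                         gt$per_class_counts))
    writeLines(gt_lines, file.path(outdir, "ground_truth.tsv"))
    cfg <- config[setdiff(names(config), c("peak_len"))]
    writeLines(paste0(names(unlist(cfg)), "\t", unlist(cfg)),
               file.path(outdir, "config.tsv"))
  }
  invisible(out)
}
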