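#' Build an annotation model for mutation categorisation
#'
#' The model holds the element sets used to place every mutation into
#' exactly one of ten categories: miRNA, exonic (CDS), 5'UTR, 3'UTR,
#' promoter, TTS, ncRNA, pseudogene, intronic, intergenic. Promoter and TTS
#' windows are computed strand-aware from the gene span: on `+` the
#' promoter is `[start - up, start + down)` and the TTS window
#' `[end - up_t, end + down_t)`; on `-` both are mirrored. Strandless
#' features are treated as `+`. Introns are derived as gene span minus the
#' union of exonic blocks (CDS and UTRs, plus `exons` when supplied).
#'
#' @param genes BED-style data.frame of gene spans (chrom, start, end,
#'   strand, name).
#' @param cds,utr5,utr3,exons,mirnas,ncrnas,pseudogenes optional BED-style
#'   data.frames of sub-elements / other feature classes.
#' @param promoter_window `c(upstream_bp, downstream_bp)` around the TSS
#'   (default 1000, 100).
#' @param tts_window `c(upstream_bp, downstream_bp)` around the TES
#'   (default 100, 1000).
#' @param priority category order, most specific first; a position
#'   overlapping several element types gets the earliest category.
#' @return an object of class `annotation_model`.
#' @export
annotation_model <- function(genes, cds = NULL, utr5 = NULL, utr3 = NULL,
                             exons = NULL, mirnas = NULL, ncrnas = NULL,
                             pseudogenes = NULL,
                             promoter_window = c(1000L, 100L),
                             tts_window = c(100L, 1000L),
                             priority = c("miRNA", "exonic", "5'UTR",
                                          "3'UTR", "promoter", "TTS",
                                          "ncRNA", "pseudogene", "intronic",
                                          "intergenic")) {
  categories <- c("miRNA", "exonic", "5'UTR", "3'UTR", "promoter", "TTS",
                  "ncRNA", "pseudogene", "intronic", "intergenic")
  if (!setequal(priority, categories))
    stop("priority must be a permutation of the ten categories")
  if (any(promoter_window < 0) || any(tts_window < 0))
    stop("windows must be non-negative")
  strand <- if (is.null(genes$strand)) rep("+", nrow(genes)) else
    ifelse(genes$strand == "-", "-", "+")
  plus <- strand == "+"
  prom <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$start - promoter_window[1],
                         genes$end - promoter_window[2]),
    end = ifelse(plus, genes$start + promoter_window[2],
                       genes$end + promoter_window[1]))
  tts <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end - tts_window[1],
                         genes$start - tts_window[2]),
    end = ifelse(plus, genes$end + tts_window[2],
                       genes$start + tts_window[1]))
  prom$start <- pmax(prom$start, 0L); tts$start <- pmax(tts$start, 0L)
  exonic_blocks <- do.call(rbind, lapply(
    Filter(Negate(is.null), list(cds, utr5, utr3, exons)),
    function(x) x[, c("chrom", "start", "end")]))
  sets <- list(
    "miRNA" = merge_intervals(mirnas),
    "exonic" = merge_intervals(cds),
    "5'UTR" = merge_intervals(utr5),
    "3'UTR" = merge_intervals(utr3),
    "promoter" = merge_intervals(prom),
    "TTS" = merge_intervals(tts),
    "ncRNA" = merge_intervals(ncrnas),
    "pseudogene" = merge_intervals(pseudogenes),
    "intronic" = merge_intervals(genes))
  introns <- interval_difference(merge_intervals(genes),
                                 merge_intervals(exonic_blocks))
  structure(list(sets = sets, priority = priority, genes = genes,
                 cds_set = merge_intervals(cds), intron_set = introns,
                 promoter_window = promoter_window,
                 tts_window = tts_window),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat("annotation_model:", nrow(x$genes), "genes; priority:",
      paste(x$priority, collapse = " > "), "\n")
  invisible(x)
}

# Merge a BED-style data.frame into per-chromosome sorted disjoint
# intervals: list(chrom -> list(starts, ends)).
merge_intervals <- function(df) {
  if (is.null(df) || !nrow(df)) return(list())
  out <- list()
  for (ch in unique(df$chrom)) {
    s <- df$start[df$chrom == ch]; e <- df$end[df$chrom == ch]
    o <- order(s, e); s <- s[o]; e <- e[o]
    ms <- s[1]; me <- e[1]; rs <- integer(0); re <- integer(0)
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] <= me) me <- max(me, e[i])
        else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
      }
    }
    out[[ch]] <- list(starts = c(rs, ms), ends = c(re, me))
  }
  out
}

# (merged A) minus (merged B), per chromosome.
interval_difference <- function(a, b) {
  out <- list()
  for (ch in names(a)) {
    as <- a[[ch]]$starts; ae <- a[[ch]]$ends
    bs <- if (!is.null(b[[ch]])) b[[ch]]$starts else integer(0)
    be <- if (!is.null(b[[ch]])) b[[ch]]$ends else integer(0)
    rs <- integer(0); re <- integer(0)
    for (i in seq_along(as)) {
      cur <- as[i]
      ov <- which(bs < ae[i] & be > as[i])
      for (j in ov) {
        if (bs[j] > cur) { rs <- c(rs, cur); re <- c(re, bs[j]) }
        cur <- max(cur, be[j])
      }
      if (cur < ae[i]) { rs <- c(rs, cur); re <- c(re, ae[i]) }
    }
    if (length(rs)) out[[ch]] <- list(starts = rs, ends = re)
  }
  out
}

# Vectorised point-in-set query over a merged interval set.
points_in_set <- function(set, chrom, pos) {
  hit <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- set[[ch]]
    if (is.null(iv)) next
    sel <- chrom == ch
    i <- findInterval(pos[sel], iv$starts)
    hit[sel] <- i >= 1 & pos[sel] < iv$ends[pmax(i, 1L)]
  }
  hit
}

# Any-bp overlap of query intervals [s, e) with a merged set.
intervals_overlap_set <- function(set, chrom, start, end) {
  hit <- logical(length(start))
  for (ch in unique(chrom)) {
    iv <- set[[ch]]
    if (is.null(iv)) next
    sel <- chrom == ch
    i <- findInterval(end[sel] - 1L, iv$starts)
    hit[sel] <- i >= 1 & iv$ends[pmax(i, 1L)] > start[sel]
  }
  hit
}

#' Annotate mutations with a single genomic-element category
#'
#' Each mutation (located by its first reference base) gets exactly one
#' category; when a position overlaps several element types the highest
#' priority category in the model wins, and positions covered by nothing
#' (including unknown chromosomes, which trigger one warning) are
#' intergenic.
#'
#' @param cohort a `mutation_cohort` or a data.frame with chrom/pos.
#' @param model an `annotation_model`.
#' @return character vector of categories, one per mutation.
#' @export
annotate_mutations <- function(cohort, model) {
  m <- if (inherits(cohort, "mutation_cohort")) cohort$mutations else cohort
  n <- nrow(m)
  out <- rep("intergenic", n)
  if (!n) return(out)
  known <- unique(unlist(lapply(model$sets, names)))
  if (length(setdiff(unique(m$chrom), known)))
    warning("mutations on chromosome(s) absent from the annotation ",
            "treated as intergenic")
  undecided <- rep(TRUE, n)
  for (cat in model$priority) {
    if (cat == "intergenic") break
    hit <- undecided & points_in_set(model$sets[[cat]], m$chrom, m$pos)
    out[hit] <- cat
    undecided <- undecided & !hit
  }
  out
}

#' Count mutations per genomic-element category
#'
#' @param cohort a `mutation_cohort`.
#' @param model an `annotation_model`.
#' @return named integer vector over the ten categories (priority order);
#'   counts sum to the cohort size.
#' @export
count_by_category <- function(cohort, model) {
  cats <- annotate_mutations(cohort, model)
  out <- stats::setNames(integer(length(model$priority)), model$priority)
  tab <- table(cats)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Classify miRNAs by host-gene context
#'
#' A miRNA overlapping a CDS by at least 1 bp is a `CDS_miRNA`; otherwise
#' one overlapping an intron is an `intron_miRNA`; the remainder are
#' `intergenic_miRNA`. The three classes partition the miRNA set.
#'
#' @param mirnas BED-style data.frame of miRNA intervals.
#' @param model an `annotation_model` (supplies CDS and intron intervals).
#' @return character vector of classes, one per miRNA.
#' @export
classify_mirnas <- function(mirnas, model) {
  out <- rep("intergenic_miRNA", nrow(mirnas))
  in_intron <- intervals_overlap_set(model$intron_set, mirnas$chrom,
                                     mirnas$start, mirnas$end)
  out[in_intron] <- "intron_miRNA"
  in_cds <- intervals_overlap_set(model$cds_set, mirnas$chrom,
                                  mirnas$start, mirnas$end)
  out[in_cds] <- "CDS_miRNA"
  out
}

#' Per-gene mutated-sample counts
#'
#' For each gene, the number of cohort samples carrying at least one
#' mutation inside the gene span (multiple hits in one sample count once),
#' and the corresponding fraction of the cohort.
#'
#' @param cohort a `mutation_cohort`.
#' @param genes BED-style data.frame with a `name` column.
#' @return data.frame (gene, n_samples, fraction) with attribute
#'   `cohort_size`.
#' @export
gene_mutation_frequency <- function(cohort, genes) {
  if (!length(cohort$sample_ids)) stop("empty cohort")
  m <- cohort$mutations
  n_hit <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel_m <- which(m$chrom == ch)
    pos <- m$pos[sel_m]; sid <- m$sample_id[sel_m]
    o <- order(pos); pos <- pos[o]; sid <- sid[o]
    for (gi in which(genes$chrom == ch)) {
      lo <- findInterval(genes$start[gi] - 1L, pos) + 1L
      hi <- findInterval(genes$end[gi] - 1L, pos)
      if (hi >= lo) n_hit[gi] <- length(unique(sid[lo:hi]))
    }
  }
  out <- data.frame(gene = genes$name, n_samples = n_hit,
                    fraction = n_hit / length(cohort$sample_ids),
                    stringsAsFactors = FALSE)
  attr(out, "cohort_size") <- length(cohort$sample_ids)
  out
}

#' Select highly mutated genes
#'
#' Genes mutated in more than `min_fraction` of cohort samples.
#'
#' @param freq_table result of [gene_mutation_frequency()].
#' @param min_fraction fraction threshold (default 0.10, strict
#'   inequality).
#' @return character vector of gene names.
#' @export
top_genes <- function(freq_table, min_fraction = 0.10) {
  freq_table$gene[freq_table$fraction > min_fraction]
}

#' Split a cohort by overlap with a gene set
#'
#' @param cohort a `mutation_cohort`.
#' @param gene_set character vector of gene names.
#' @param genes BED-style data.frame with a `name` column.
#' @return list with `cohort_in` (mutations overlapping any named gene) and
#'   `cohort_out` (the complement); together they partition the cohort.
#' @export
split_by_genes <- function(cohort, gene_set, genes) {
  sel <- genes[genes$name %in% gene_set, , drop = FALSE]
  set <- merge_intervals(sel)
  m <- cohort$mutations
  inside <- if (nrow(m)) points_in_set(set, m$chrom, m$pos) else logical(0)
  list(cohort_in = mutation_cohort(m[inside, , drop = FALSE],
                                   sample_ids = cohort$sample_ids,
                                   provenance = cohort$provenance),
       cohort_out = mutation_cohort(m[!inside, , drop = FALSE],
                                    sample_ids = cohort$sample_ids,
                                    provenance = cohort$provenance))
}
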