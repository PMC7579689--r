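#' Construct a somatic mutation cohort
#'
#' A cohort bundles per-sample somatic variant calls with the set of sample
#' identifiers they came from. All coordinates are 0-based: `pos` is the
#' position of the first reference base (half-open interval convention
#' throughout the package). Mutations are kept sorted by
#' (chrom, pos, sample_id) so that all downstream operations are
#' order-stable.
#'
#' @param mutations data.frame with columns `sample_id`, `chrom`, `pos`
#'   (0-based integer), `ref`, `alt`, and optionally `var_class`; if
#'   `var_class` is absent it is assigned with [classify_substitution()].
#' @param sample_ids character vector of all sample ids in the cohort;
#'   defaults to the ids present in `mutations`. Ids present here but absent
#'   from `mutations` represent samples with zero calls and still count
#'   toward cohort size.
#' @param provenance free-text origin note carried along in reports.
#' @return An object of class `mutation_cohort`: a list with elements
#'   `mutations`, `sample_ids`, `provenance`.
#' @export
mutation_cohort <- function(mutations, sample_ids = NULL, provenance = "") {
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(mutations))
  if (length(miss))
    stop("mutations is missing column(s): ", paste(miss, collapse = ", "))
  mutations$sample_id <- as.character(mutations$sample_id)
  mutations$chrom <- as.character(mutations$chrom)
  mutations$pos <- as.integer(mutations$pos)
  mutations$ref <- as.character(mutations$ref)
  mutations$alt <- as.character(mutations$alt)
  if (nrow(mutations) && any(mutations$pos < 0))
    stop("negative mutation position")
  if (nrow(mutations) && any(mutations$ref == mutations$alt))
    stop("ref == alt for some records; reject them before building a cohort")
  if (is.null(mutations$var_class))
    mutations$var_class <- classify_substitution(mutations$ref, mutations$alt)
  if (is.null(sample_ids)) sample_ids <- unique(mutations$sample_id)
  sample_ids <- sort(unique(as.character(sample_ids)))
  if (nrow(mutations) && !all(mutations$sample_id %in% sample_ids))
    stop("mutation sample_id not in sample_ids")
  o <- order(mutations$chrom, mutations$pos, mutations$sample_id)
  mutations <- mutations[o, , drop = FALSE]
  rownames(mutations) <- NULL
  structure(list(mutations = mutations, sample_ids = sample_ids,
                 provenance = provenance),
            class = "mutation_cohort")
}

#' @export
print.mutation_cohort <- function(x, ...) {
  cat("mutation_cohort:", nrow(x$mutations), "mutations across",
      length(x$sample_ids), "samples\n")
  if (nrow(x$mutations)) {
    tab <- table(x$mutations$var_class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of mutations in a cohort
#' @param cohort a `mutation_cohort`.
#' @return integer count.
#' @export
n_mutations <- function(cohort) nrow(cohort$mutations)

#' Per-sample mutation counts
#'
#' Counts include zero entries for samples with no calls.
#' @param cohort a `mutation_cohort`.
#' @return named integer vector over `cohort$sample_ids`.
#' @export
sample_counts <- function(cohort) {
  n <- integer(length(cohort$sample_ids))
  names(n) <- cohort$sample_ids
  if (nrow(cohort$mutations)) {
    tab <- table(cohort$mutations$sample_id)
    n[names(tab)] <- as.integer(tab)
  }
  n
}

#' Classify substitutions by reference allele
#'
#' Partitions variants into the three strata used throughout the profile
#' plots: `ref_CT` (pyrimidine reference: C or T), `ref_GA` (purine
#' reference: G or A) and `indel` (any length-changing variant, including
#' "-"-allele insertions/deletions). Together with the implicit "all"
#' stratum (their union) these cover every variant. Multi-base variants of
#' equal ref/alt length (MNVs) are classified by their first base.
#'
#' An alternative, literal reading restricts the SNV classes to specific
#' ref->alt pairs (C/T->G/A and G/A->C/T); under `mode = "literal"` SNVs
#' outside those pairs get class `other`, so the three named classes no
#' longer partition the SNVs. The default `mode = "partition"` is used by
#' all built-in analyses.
#'
#' @param ref,alt character vectors of reference/alternate alleles
#'   (`"-"` denotes the empty allele of an insertion/deletion).
#' @param mode `"partition"` (default) or `"literal"`.
#' @return character vector in `{ref_CT, ref_GA, indel}` (plus `other`
#'   under the literal mode).
#' @export
classify_substitution <- function(ref, alt, mode = c("partition", "literal")) {
  mode <- match.arg(mode)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (length(ref) != length(alt)) stop("ref and alt lengths differ")
  if (any(ref == alt)) stop("invalid variant: ref == alt")
  is_indel <- ref == "-" | alt == "-" | nchar(ref) != nchar(alt)
  first <- substr(ref, 1, 1)
  out <- character(length(ref))
  out[is_indel] <- "indel"
  snv <- !is_indel
  if (mode == "partition") {
    out[snv & first %in% c("C", "T")] <- "ref_CT"
    out[snv & first %in% c("G", "A")] <- "ref_GA"
  } else {
    a1 <- substr(alt, 1, 1)
    out[snv] <- "other"
    out[snv & first %in% c("C", "T") & a1 %in% c("G", "A")] <- "ref_CT"
    out[snv & first %in% c("G", "A") & a1 %in% c("C", "T")] <- "ref_GA"
  }
  if (any(out == "")) stop("unclassifiable allele(s): ",
                           paste(unique(ref[out == ""]), collapse = ","))
  out
}

#' Remove hypermutator samples
#'
#' Tumour samples with an outlying total mutation burden distort composite
#' profiles and rate comparisons. The default rule is Tukey's outer fence on
#' per-sample counts: a sample is removed when its count exceeds
#' Q3 + k * IQR (k = 3). The `absolute` method removes samples whose count
#' exceeds a fixed threshold `k`.
#'
#' @param cohort a `mutation_cohort`.
#' @param method `"iqr"` (default) or `"absolute"`.
#' @param k fence multiplier for `"iqr"` (default 3) or the fixed count
#'   threshold for `"absolute"` (must be > 0).
#' @return list with `cohort` (filtered) and `removed_samples`
#'   (named counts of the removed samples).
#' @export
filter_hypermutators <- function(cohort, method = c("iqr", "absolute"), k = NULL) {
  method <- match.arg(method)
  if (!length(cohort$sample_ids)) stop("empty cohort")
  counts <- sample_counts(cohort)
  if (method == "iqr") {
    if (is.null(k)) k <- 3
    q3 <- stats::quantile(counts, 0.75, names = FALSE)
    fence <- q3 + k * stats::IQR(counts)
    drop <- counts > fence
  } else {
    if (is.null(k) || k <= 0)
      stop("absolute method needs a positive count threshold k")
    drop <- counts > k
  }
  if (all(drop))
    stop("hypermutator filter removed every sample; raise the threshold")
  keep_ids <- names(counts)[!drop]
  m <- cohort$mutations
  m <- m[m$sample_id %in% keep_ids, , drop = FALSE]
  list(cohort = mutation_cohort(m, sample_ids = keep_ids,
                                provenance = cohort$provenance),
       removed_samples = counts[drop])
}

#' Subsample a cohort to a fixed number of samples
#'
#' Uniform sampling without replacement, deterministic given `seed`; the
#' returned cohort keeps only mutations from the selected samples.
#'
#' @param cohort a `mutation_cohort`.
#' @param n_samples number of samples to keep.
#' @param seed integer seed.
#' @return a `mutation_cohort` over the selected samples.
#' @export
subsample_cohort <- function(cohort, n_samples, seed) {
  ids <- cohort$sample_ids
  if (n_samples > length(ids))
    stop("n_samples (", n_samples, ") exceeds available samples (",
         length(ids), ")")
  keep <- local_seed(seed, sample(ids, n_samples))
  m <- cohort$mutations
  m <- m[m$sample_id %in% keep, , drop = FALSE]
  mutation_cohort(m, sample_ids = keep, provenance = cohort$provenance)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
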