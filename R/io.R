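#' Read a genome FASTA
#'
#' Sequences are returned uppercase as a named character vector (one element
#' per chromosome, names taken verbatim from the headers). Only the alphabet
#' `{A,C,G,T,N}` is accepted.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("FASTA format error at line 1: empty file")
  if (!startsWith(first, ">"))
    stop("FASTA format error at line 1: expected '>' header")
  ss <- Biostrings::readDNAStringSet(path)
  if (!length(ss)) stop("FASTA format error: no records in ", path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", g)
  if (any(bad))
    stop("FASTA alphabet error: sequence ", names(g)[bad][1],
         " contains characters outside {A,C,G,T,N}")
  g
}

#' Write a genome FASTA
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome named character vector of sequences.
#' @return named integer vector.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

split_fields <- function(lines, what) {
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read genomic features from BED
#'
#' Accepts BED3 or BED6; intervals are 0-based half-open and preserved
#' exactly. The `score` field is kept verbatim (as character) so that
#' [write_bed()] round-trips canonical input byte for byte.
#'
#' @param path BED file. Lines starting with `#`, `track` or `browser` are
#'   skipped.
#' @param category optional category label attached to every feature.
#' @return data.frame with columns chrom, start, end, name, score, strand
#'   (name/score/strand filled with ".", "0", "." for BED3) and attribute
#'   `bed_ncol` (3 or 6).
#' @export
read_bed <- function(path, category = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx)) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = character(),
                     strand = character(), stringsAsFactors = FALSE)
    attr(df, "bed_ncol") <- 6L
    if (!is.null(category)) df$category <- character()
    return(df)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED format error at line ", idx[which(nf < 3)[1]],
         ": fewer than 3 fields")
  ncol_bed <- if (all(nf >= 6)) 6L else 3L
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol_bed))),
              ncol = ncol_bed, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("BED format error at line ", idx[which(bad)[1]],
         ": non-integer coordinates")
  bad <- start >= end
  if (any(bad))
    stop("BED format error at line ", idx[which(bad)[1]], ": start >= end")
  if (any(start < 0))
    stop("BED format error at line ", idx[which(start < 0)[1]],
         ": negative start")
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   name = if (ncol_bed == 6L) m[, 4] else ".",
                   score = if (ncol_bed == 6L) m[, 5] else "0",
                   strand = if (ncol_bed == 6L) m[, 6] else ".",
                   stringsAsFactors = FALSE)
  if (ncol_bed == 6L && !all(df$strand %in% c("+", "-", ".")))
    stop("BED format error: strand must be one of +, -, .")
  attr(df, "bed_ncol") <- ncol_bed
  if (!is.null(category)) df$category <- category
  df
}

#' Write features as BED
#'
#' Writes BED3 or BED6 according to the input's `bed_ncol` attribute
#' (default BED6), tab-separated with no quoting.
#'
#' @param features data.frame as returned by [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(features, path) {
  ncol_bed <- attr(features, "bed_ncol")
  if (is.null(ncol_bed)) ncol_bed <- 6L
  if (ncol_bed == 3L) {
    lines <- paste(features$chrom, features$start, features$end, sep = "\t")
  } else {
    name <- if (is.null(features$name)) "." else features$name
    score <- if (is.null(features$score)) "0" else features$score
    strand <- if (is.null(features$strand)) "." else features$strand
    lines <- paste(features$chrom, features$start, features$end,
                   name, score, strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read per-CpG methylation from bedGraph
#'
#' One record per CpG cytosine; the value column is the methylation fraction
#' in `[0, 1]`, or a percentage in `[0, 100]` when `percent = TRUE`.
#' Records are returned sorted by (chrom, pos).
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param percent set when the file stores percentages; values are divided
#'   by 100.
#' @return data.frame with columns chrom, pos (0-based cytosine position),
#'   level (fraction), coverage (NA; bedGraph does not carry coverage).
#' @export
read_bedgraph_methylation <- function(path, percent = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), pos = integer(),
                      level = numeric(), coverage = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("bedGraph format error at line ", idx[which(nf < 4)[1]],
         ": fewer than 4 fields")
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4, byrow = TRUE)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- is.na(start) | is.na(end) | start >= end
  if (any(bad))
    stop("bedGraph format error at line ", idx[which(bad)[1]],
         ": bad interval")
  val <- as.numeric(m[, 4])
  hi <- if (percent) 100 else 1
  bad <- is.na(val) | val < 0 | val > hi
  if (any(bad))
    stop("bedGraph methylation value outside [0, ", hi, "] at line ",
         idx[which(bad)[1]],
         if (!percent) " (use percent = TRUE for 0-100 files)" else "")
  df <- data.frame(chrom = m[, 1], pos = start,
                   level = if (percent) val / 100 else val,
                   coverage = NA_integer_, stringsAsFactors = FALSE)
  df$level_chr <- if (percent) NULL else m[, 4]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write per-CpG methylation as bedGraph
#' @param records data.frame with chrom, pos, level (and optionally a
#'   verbatim `level_chr` column used for byte-exact output).
#' @param path output file.
#' @export
write_bedgraph_methylation <- function(records, path) {
  val <- if (!is.null(records$level_chr)) records$level_chr
         else format(records$level, trim = TRUE, scientific = FALSE)
  writeLines(paste(records$chrom, records$pos, records$pos + 1L, val,
                   sep = "\t"), path)
  invisible(path)
}

#' Read somatic mutations into a cohort
#'
#' Two dialects are supported. `maf_min` is a minimal MAF-like TSV: one
#' header line, then tab-separated columns (sample, chrom, pos_1based, ref,
#' alt) with `"-"` for the empty allele of an indel; comment lines start
#' with `#`. `vcf` reads VCF v4.x through the vcfR parser; multi-allelic
#' rows are split into one record per alternate allele and anchored
#' indels (e.g. ref `AC` / alt `A`) are normalised to the `"-"` convention.
#'
#' Input positions are 1-based and converted to the package's 0-based
#' convention at this boundary. Records with `ref == alt` are rejected (a
#' single warning reports the count; the number is also available as the
#' `n_rejected` attribute of the result).
#'
#' @param path input file.
#' @param dialect `"maf_min"` or `"vcf"`.
#' @param sample_id sample id applied to every record of a per-sample VCF;
#'   ignored for `maf_min`. When `NULL`, the VCF's first genotype column
#'   name is used, falling back to the file name.
#' @param class_mode passed to [classify_substitution()].
#' @return a `mutation_cohort` (attribute `n_rejected` = rejected records).
#' @export
read_mutations <- function(path, dialect = c("maf_min", "vcf"),
                           sample_id = NULL,
                           class_mode = c("partition", "literal")) {
  dialect <- match.arg(dialect)
  class_mode <- match.arg(class_mode)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "maf_min") {
    lines <- readLines(path)
    keep <- !grepl("^#", lines) & nzchar(lines)
    idx <- which(keep)
    if (!length(idx)) stop("mutation file has no header line: ", path)
    idx <- idx[-1]                       # drop header
    if (!length(idx)) {
      emp <- mutation_cohort(
        data.frame(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   stringsAsFactors = FALSE),
        provenance = path)
      attr(emp, "n_rejected") <- 0L
      return(emp)
    }
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 5))
      stop("MAF format error at line ", idx[which(nf < 5)[1]],
           ": fewer than 5 fields")
    m <- matrix(unlist(lapply(fields, `[`, 1:5)), ncol = 5, byrow = TRUE)
    pos1 <- suppressWarnings(as.integer(m[, 3]))
    if (anyNA(pos1))
      stop("MAF format error at line ", idx[which(is.na(pos1))[1]],
           ": non-integer position")
    df <- data.frame(sample_id = m[, 1], chrom = m[, 2], pos = pos1 - 1L,
                     ref = toupper(m[, 4]), alt = toupper(m[, 5]),
                     stringsAsFactors = FALSE)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    if (is.null(sample_id)) {
      gt_names <- colnames(v@gt)
      sample_id <- if (!is.null(gt_names) && length(gt_names) > 1)
        gt_names[2] else basename(path)
    }
    alt_list <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
    rep_i <- rep(seq_len(nrow(fix)), lengths(alt_list))
    df <- data.frame(sample_id = sample_id,
                     chrom = as.character(fix[rep_i, "CHROM"]),
                     pos = as.integer(fix[rep_i, "POS"]) - 1L,
                     ref = toupper(as.character(fix[rep_i, "REF"])),
                     alt = toupper(unlist(alt_list)),
                     stringsAsFactors = FALSE)
    df <- normalize_indels(df)
  }
  rej <- df$ref == df$alt
  if (any(rej))
    warning(sum(rej), " record(s) with ref == alt rejected")
  df <- df[!rej, , drop = FALSE]
  df$var_class <- if (nrow(df))
    classify_substitution(df$ref, df$alt, mode = class_mode) else character()
  out <- mutation_cohort(df, provenance = path)
  attr(out, "n_rejected") <- sum(rej)
  out
}

# VCF-style anchored indels -> "-" allele convention:
#   del  (ref "AC", alt "A")  -> pos+1, ref "C",  alt "-"
#   ins  (ref "A",  alt "AC") -> pos,   ref "-",  alt "C"
normalize_indels <- function(df) {
  nr <- nchar(df$ref); na <- nchar(df$alt)
  anchored <- nr != na & nr >= 1 & na >= 1 &
    substr(df$ref, 1, 1) == substr(df$alt, 1, 1)
  del <- anchored & nr > na
  ins <- anchored & nr < na
  df$pos[del] <- df$pos[del] + nchar(df$alt[del])
  df$ref[del] <- substr(df$ref[del], nchar(df$alt[del]) + 1, 1e6)
  df$alt[del] <- "-"
  df$alt[ins] <- substr(df$alt[ins], nchar(df$ref[ins]) + 1, 1e6)
  df$ref[ins] <- "-"
  df
}

#' Write a cohort in the minimal MAF-like dialect
#'
#' Five tab-separated columns (sample, chrom, pos_1based, ref, alt) under a
#' single header line; positions are converted back to 1-based.
#'
#' @param cohort a `mutation_cohort`.
#' @param path output file.
#' @export
write_mutations_maf <- function(cohort, path) {
  m <- cohort$mutations
  lines <- c("sample\tchrom\tpos\tref\talt",
             if (nrow(m)) paste(m$sample_id, m$chrom, m$pos + 1L,
                                m$ref, m$alt, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
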