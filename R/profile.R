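#' Binning specification for composite profiles
#'
#' A profile covers a fixed upstream flank, the feature body scaled to a
#' common axis, and a fixed downstream flank. Flanks are cut into fixed
#' `flank_bin_bp` bins; each feature's body is cut into `body_bins` equal
#' fractions of its own length, so bodies of different lengths align on one
#' axis ("metagene" scaling).
#'
#' @param flank_bp flank width in bp on each side (default 5000).
#' @param body_bins number of scaled body bins (default 40).
#' @param flank_bin_bp flank bin width in bp (default 50); must divide
#'   `flank_bp`.
#' @param strand_aware mirror minus-strand features so bin 0 is always the
#'   biologically upstream end (default TRUE).
#' @return object of class `profile_spec`.
#' @export
profile_spec <- function(flank_bp = 5000L, body_bins = 40L,
                         flank_bin_bp = 50L, strand_aware = TRUE) {
  flank_bp <- as.integer(flank_bp); body_bins <- as.integer(body_bins)
  flank_bin_bp <- as.integer(flank_bin_bp)
  if (body_bins < 1L) stop("body_bins must be >= 1")
  if (flank_bp %% flank_bin_bp != 0L)
    stop("flank_bp must be divisible by flank_bin_bp")
  structure(list(flank_bp = flank_bp, body_bins = body_bins,
                 flank_bin_bp = flank_bin_bp, strand_aware = strand_aware),
            class = "profile_spec")
}

# Bin index for positions relative to one feature, or NA when outside the
# window. Bins: 0..nf-1 upstream flank, nf..nf+B-1 body, then downstream
# flank. Minus-strand features are mirrored when strand_aware.
feature_bin <- function(pos, start, end, strand, spec) {
  nf <- spec$flank_bp %/% spec$flank_bin_bp
  B <- spec$body_bins
  L <- end - start
  minus <- spec$strand_aware && identical(strand, "-")
  bin <- rep(NA_integer_, length(pos))
  if (minus) {
    up <- pos >= end & pos < end + spec$flank_bp
    bin[up] <- (end + spec$flank_bp - 1L - pos[up]) %/% spec$flank_bin_bp
    body <- pos >= start & pos < end
    bin[body] <- nf + as.integer(((end - 1L - pos[body]) * B) %/% L)
    dn <- pos >= start - spec$flank_bp & pos < start
    bin[dn] <- nf + B + (start - 1L - pos[dn]) %/% spec$flank_bin_bp
  } else {
    up <- pos >= start - spec$flank_bp & pos < start
    bin[up] <- (pos[up] - start + spec$flank_bp) %/% spec$flank_bin_bp
    body <- pos >= start & pos < end
    # parentheses matter: %/% binds tighter than *
    bin[body] <- nf + as.integer(((pos[body] - start) * B) %/% L)
    dn <- pos >= end & pos < end + spec$flank_bp
    bin[dn] <- nf + B + (pos[dn] - end) %/% spec$flank_bin_bp
  }
  bin
}

# Exact bp width contributed by one feature body to each of the B body
# bins: bin j holds offsets [ceil(jL/B), ceil((j+1)L/B)).
body_bin_widths <- function(L, B) {
  edges <- ceiling((0:B) * L / B)
  diff(edges)
}

profile_classes <- c("all", "ref_CT", "ref_GA", "indel")

#' Scaled metagene mutation-density profile
#'
#' For every feature, mutations falling in the upstream flank, the
#' length-scaled body or the downstream flank contribute one count to the
#' matching bin (a mutation overlapping the windows of two features counts
#' once per feature). Counts are stratified by substitution class
#' (`ref_CT`, `ref_GA`, `indel`) plus their union `all`, and converted to
#' frequencies in mutations per Mb per sample:
#' `frequency = count / (aggregate bin bp * n_samples) * 1e6`, where the
#' aggregate bin bp sums each feature's actual contribution to that bin.
#'
#' Features shorter than `body_bins` are still mapped through the same
#' scaling (some body bins then receive no bases from that feature); a note
#' is emitted via `message()`.
#'
#' @param cohort a `mutation_cohort`.
#' @param features BED-style data.frame (chrom, start, end, strand).
#' @param spec a [profile_spec()].
#' @param body_labels axis end labels, e.g. `c("TSS", "TES")` for gene
#'   bodies or `c("PSS", "PES")` for peaks.
#' @return object of class `metagene_profile`: list with `bins` (data.frame
#'   of label, section, per-class counts and frequencies), `n_features`,
#'   `n_samples`, `spec`.
#' @export
scaled_profile <- function(cohort, features, spec = profile_spec(),
                           body_labels = c("TSS", "TES")) {
  if (!nrow(features)) stop("features must be non-empty")
  nf <- spec$flank_bp %/% spec$flank_bin_bp
  B <- spec$body_bins
  nbins <- 2L * nf + B
  counts <- matrix(0L, nrow = nbins, ncol = length(profile_classes),
                   dimnames = list(NULL, profile_classes))
  bp <- numeric(nbins)
  bp[seq_len(nf)] <- spec$flank_bin_bp * nrow(features)
  bp[nf + B + seq_len(nf)] <- spec$flank_bin_bp * nrow(features)
  if (any(features$end - features$start < B))
    message(sum(features$end - features$start < B),
            " feature(s) shorter than body_bins; scaled bins may be empty")
  m <- cohort$mutations
  strand <- if (is.null(features$strand)) rep(".", nrow(features)) else
    features$strand
  for (ch in unique(features$chrom)) {
    sel_m <- which(m$chrom == ch)
    pos <- m$pos[sel_m]; cls <- m$var_class[sel_m]
    o <- order(pos); pos <- pos[o]; cls <- cls[o]
    for (fi in which(features$chrom == ch)) {
      s <- features$start[fi]; e <- features$end[fi]
      # under the mirrored minus-strand mapping, scaled bin j still
      # receives exactly width_j bases of the body
      bp[nf + seq_len(B)] <- bp[nf + seq_len(B)] + body_bin_widths(e - s, B)
      if (!length(pos)) next
      lo <- findInterval(s - spec$flank_bp - 1L, pos) + 1L
      hi <- findInterval(e + spec$flank_bp - 1L, pos)
      if (hi < lo) next
      idx <- lo:hi
      bin <- feature_bin(pos[idx], s, e, strand[fi], spec)
      ok <- !is.na(bin)
      if (!any(ok)) next
      bin1 <- bin[ok] + 1L
      kls <- cls[idx][ok]
      tab <- table(factor(bin1, levels = seq_len(nbins)))
      counts[, "all"] <- counts[, "all"] + as.integer(tab)
      for (k in c("ref_CT", "ref_GA", "indel")) {
        sk <- kls == k
        if (any(sk)) {
          tab <- table(factor(bin1[sk], levels = seq_len(nbins)))
          counts[, k] <- counts[, k] + as.integer(tab)
        }
      }
    }
  }
  n_samples <- max(1L, length(cohort$sample_ids))
  freq <- counts / (bp * n_samples) * 1e6
  freq[!is.finite(freq)] <- 0
  section <- c(rep("upstream", nf), rep("body", B), rep("downstream", nf))
  label <- c(sprintf("u%03d", seq_len(nf)),
             sprintf("b%03d", seq_len(B)),
             sprintf("d%03d", seq_len(nf)))
  bins <- data.frame(label = label, section = section, bin_bp = bp,
                     stringsAsFactors = FALSE)
  for (k in profile_classes) {
    bins[[paste0("count_", k)]] <- counts[, k]
    bins[[paste0("freq_", k)]] <- freq[, k]
  }
  structure(list(bins = bins, n_features = nrow(features),
                 n_samples = length(cohort$sample_ids), spec = spec,
                 body_labels = body_labels),
            class = "metagene_profile")
}

#' Peak-centered mutation-density profile
#'
#' Identical binning contract to [scaled_profile()] but with peak-style
#' axis labels (PSS/PES) and a per-call flank width: 300 bp suits CTCF
#' binding sites, 4000 bp histone-modification peaks, 5000 bp DNase peaks.
#'
#' @param cohort a `mutation_cohort`.
#' @param peaks BED-style data.frame (strandless peaks are treated as `+`).
#' @param flank_bp flank width in bp.
#' @param body_bins,flank_bin_bp passed to [profile_spec()];
#'   `flank_bin_bp` defaults to `flank_bp / 100` rounded to a divisor
#'   (minimum 10 bp).
#' @return a `metagene_profile`.
#' @export
peak_profile <- function(cohort, peaks, flank_bp = 300L, body_bins = 40L,
                         flank_bin_bp = NULL) {
  if (is.null(flank_bin_bp)) {
    flank_bin_bp <- max(10L, as.integer(flank_bp) %/% 100L)
    while (as.integer(flank_bp) %% flank_bin_bp != 0L)
      flank_bin_bp <- flank_bin_bp - 1L
  }
  spec <- profile_spec(flank_bp = flank_bp, body_bins = body_bins,
                       flank_bin_bp = flank_bin_bp)
  scaled_profile(cohort, peaks, spec, body_labels = c("PSS", "PES"))
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile:", x$n_features, "features,", x$n_samples,
      "samples,", nrow(x$bins), "bins (",
      paste(x$body_labels, collapse = "-"), "body )\n")
  cat("  total mutations binned:", sum(x$bins$count_all), "\n")
  invisible(x)
}

#' Plot a composite mutation-frequency profile
#'
#' Base-graphics line plot of per-bin mutation frequency (per Mb per
#' sample) for the `all`, `ref_CT` and `ref_GA` strata, with the body
#' boundaries marked.
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  b <- x$bins
  i <- seq_len(nrow(b))
  graphics::plot(i, b$freq_all, type = "l", lwd = 2, xlab = "bin",
                 ylab = "mutations / Mb / sample", xaxt = "n", ...)
  graphics::lines(i, b$freq_ref_CT, col = "darkgreen")
  graphics::lines(i, b$freq_ref_GA, col = "orange")
  at <- c(1, which(b$section == "body")[1],
          utils::tail(which(b$section == "body"), 1), nrow(b))
  graphics::axis(1, at = at,
                 labels = c(paste0("-", x$spec$flank_bp), x$body_labels[1],
                            x$body_labels[2], paste0("+", x$spec$flank_bp)))
  graphics::abline(v = at[2:3], lty = 3, col = "grey50")
  graphics::legend("topright", legend = c("all", "Ref-CT", "Ref-GA"),
                   col = c("black", "darkgreen", "orange"), lwd = c(2, 1, 1),
                   bty = "n")
  invisible(x)
}

#' Write a profile as TSV
#'
#' Columns: bin_label, bin_class (upstream/body/downstream), class, count,
#' frequency; `#` header lines carry the binning parameters.
#'
#' @param profile a `metagene_profile`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste0("# metagene_profile: n_features=", profile$n_features,
           " n_samples=", profile$n_samples),
    paste0("# flank_bp=", profile$spec$flank_bp,
           " body_bins=", profile$spec$body_bins,
           " flank_bin_bp=", profile$spec$flank_bin_bp,
           " body_axis=", paste(profile$body_labels, collapse = "..")),
    "bin_label\tbin_class\tclass\tcount\tfrequency"), con)
  b <- profile$bins
  for (k in profile_classes) {
    writeLines(paste(b$label, b$section, k, b[[paste0("count_", k)]],
                     format(b[[paste0("freq_", k)]], trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Oscillation score of a profile's flanks
#'
#' Descriptive measure of the alternating higher/lower mutation frequency
#' seen around open-chromatin peaks: after moving-average smoothing of the
#' per-bin `all` frequency, counts the sign changes of the first difference
#' within the flank bins (each sign change is a local extremum) and reports
#' the relative amplitude `(max - min) / mean` of the smoothed flank
#' frequency.
#'
#' @param profile a `metagene_profile`.
#' @param smoothing_bins moving-average width in bins (default 3).
#' @return list with `n_extrema` and `amplitude`.
#' @export
oscillation_score <- function(profile, smoothing_bins = 3L) {
  b <- profile$bins
  if (nrow(b) < 3L * smoothing_bins)
    stop("profile needs at least 3 * smoothing_bins bins")
  y <- as.numeric(stats::filter(b$freq_all, rep(1 / smoothing_bins,
                                                smoothing_bins),
                                sides = 2))
  flank <- b$section != "body"
  yf <- y[flank]
  yf <- yf[!is.na(yf)]
  if (!length(yf) || all(yf == 0)) return(list(n_extrema = 0L, amplitude = 0))
  d <- diff(yf)
  d <- d[d != 0]
  n_ext <- if (length(d) > 1) sum(diff(sign(d)) != 0) else 0L
  amp <- if (mean(yf) > 0) (max(yf) - min(yf)) / mean(yf) else 0
  list(n_extrema = as.integer(n_ext), amplitude = amp)
}
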