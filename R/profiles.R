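#' Coverage-weighted mean methylation of a united group
#'
#' 100 * sum(n_meth) / sum(coverage) over all retained CpGs and present
#' samples of the group -- the global landscape summary.
#'
#' @param united UnitedMatrix.
#' @return percent in [0, 100].
#' @export
weighted_mean_methylation <- function(united) {
  if (!nrow(united$cpgs)) stop("empty united matrix")
  p <- pooled_counts(united)
  100 * sum(p$m) / sum(p$cov)
}

#' Per-CpG methylation percentages of a united group
#'
#' Pooled over present samples: 100 * sum(m) / sum(cov) per CpG.
#' @param united UnitedMatrix.
#' @return numeric vector aligned with `united$cpgs`.
#' @export
per_cpg_methylation <- function(united) {
  p <- pooled_counts(united)
  ifelse(p$cov > 0, 100 * p$m / p$cov, NA_real_)
}

#' Histogram of per-CpG methylation percentages
#'
#' Left-closed bins of `bin_width` percent spanning [0, 100], with 100
#' falling in the last bin. The summary reports the fractions below 5% and
#' above 95% -- a bimodality proxy for the somatic-methylome landscape.
#'
#' @param per_cpg_percent values in [0, 100].
#' @param bin_width bin width in percent (must divide 100).
#' @return list: `counts` (one per bin), `breaks`, `fraction_low` (< 5%),
#'   `fraction_high` (> 95%), `n`.
#' @export
methylation_histogram <- function(per_cpg_percent, bin_width = 10) {
  v <- per_cpg_percent[!is.na(per_cpg_percent)]
  stopifnot(all(v >= 0 & v <= 100), 100 %% bin_width == 0)
  breaks <- seq(0, 100, by = bin_width)
  n_bins <- length(breaks) - 1L
  idx <- pmin(findInterval(v, breaks), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, breaks = breaks,
       fraction_low = mean(v < 5), fraction_high = mean(v > 95),
       n = length(v))
}

#' Feature-centered methylation profile
#'
#' Bins CpG methylation across a window centered on each feature (midpoint
#' of the interval, rounded down) and reports the per-bin coverage-weighted
#' mean methylation pooled over all features. Minus-strand features are
#' flipped so that negative offsets are always upstream. A cubic smoothing
#' spline over the bin means provides the presentation curve.
#'
#' @param calls a MethylationCallSet or list of them (counts pooled).
#' @param features FeatureTrack; strand column used for flipping when
#'   present.
#' @param window total window width in bp (default 5000).
#' @param n_bins number of bins (default 50, i.e. 100-bp bins).
#' @return data.table of class `MethylationProfile`: bin index, offset (bin
#'   center, bp), mean (percent, NA for empty bins), n_cpgs, smoothed.
#' @export
feature_centered_profile <- function(calls, features, window = 5000L,
                                     n_bins = 50L) {
  if (inherits(calls, "MethylationCallSet")) calls <- list(calls)
  rec <- rbindlist(lapply(calls, function(s)
    s$records[, .(chrom, pos, n_meth, cov = n_meth + n_unmeth)]))
  rec <- rec[, .(n_meth = sum(n_meth), cov = sum(cov)), by = .(chrom, pos)]
  half <- window / 2
  bw <- window / n_bins
  centers_off <- -half + (seq_len(n_bins) - 0.5) * bw
  empty <- data.table(bin = seq_len(n_bins), offset = centers_off,
                      mean = NA_real_, n_cpgs = 0L, smoothed = NA_real_)
  setattr(empty, "class", c("MethylationProfile", class(data.table())))
  if (!nrow(features) || !nrow(rec)) {
    warning("no features or no CpGs; empty profile")
    return(empty[])
  }
  feat <- as.data.table(features)
  feat[, center := (start + end) %/% 2L]
  fstrand <- if ("strand" %in% names(feat)) feat$strand else rep("+", nrow(feat))
  # window intervals in feature order (1-based closed for GRanges)
  ord_win <- GenomicRanges::GRanges(feat$chrom,
    IRanges::IRanges(pmax(0L, as.integer(feat$center - half)) + 1L,
                     as.integer(feat$center + half)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(points_to_granges(rec$chrom, rec$pos),
                                ord_win))   # disjoint seqlevels: no hits
  if (!length(hits)) {
    warning("no CpGs fall in any feature window; empty profile")
    return(empty[])
  }
  qi <- S4Vectors::queryHits(hits)
  fi <- S4Vectors::subjectHits(hits)
  off <- (rec$pos[qi] - 1L) - feat$center[fi]        # 0-based offset
  off <- ifelse(fstrand[fi] == "-", -off, off)
  bin <- floor((off + half) / bw) + 1L
  ok <- bin >= 1L & bin <= n_bins
  agg <- data.table(bin = bin[ok], m = rec$n_meth[qi[ok]], cv = rec$cov[qi[ok]])[
    , .(n_meth_sum = sum(m), cov_sum = sum(cv), n_cpgs = .N), by = bin]
  prof <- merge(data.table(bin = seq_len(n_bins), offset = centers_off),
                agg, by = "bin", all.x = TRUE)
  prof[, mean := ifelse(!is.na(cov_sum) & cov_sum > 0,
                        100 * n_meth_sum / cov_sum, NA_real_)]
  prof[is.na(n_cpgs), n_cpgs := 0L]
  have <- !is.na(prof$mean)
  prof[, smoothed := NA_real_]
  if (sum(have) >= 4L) {
    sp <- smooth.spline(prof$offset[have], prof$mean[have], spar = 0.5)
    prof[have == TRUE, smoothed := predict(sp, prof$offset[have])$y]
  } else if (any(have)) {
    prof[have == TRUE, smoothed := prof$mean[have]]
  }
  out <- prof[, .(bin, offset, mean, n_cpgs, smoothed)]
  setattr(out, "class", c("MethylationProfile", class(data.table())))
  out[]
}

#' Write a methylation profile as TSV
#' @param profile MethylationProfile
#' @param path output path
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(as.data.table(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
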