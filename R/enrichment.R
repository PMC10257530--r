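#' Build promoter intervals from a TSS table
#'
#' Promoters are defined as 2 kb upstream and 500 bp downstream of the
#' transcription start site, strand-aware: for a `+` gene with TSS t the
#' promoter is `[t - upstream, t + downstream)`, mirrored for `-` genes.
#' Intervals are clipped at 0 and, when `chrom_lengths` is given, at the
#' chromosome end.
#'
#' @param tss data.table with gene_id, chrom, tss_pos (0-based), strand.
#' @param upstream,downstream promoter extent in bp (defaults 2000 / 500).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return FeatureTrack with `label` = gene_id.
#' @export
build_promoters <- function(tss, upstream = 2000L, downstream = 500L,
                            chrom_lengths = NULL) {
  t <- as.data.table(tss)
  if (nrow(t) && !all(t$strand %in% c("+", "-"))) stop("invalid strand in TSS table")
  if (!nrow(t))
    return(feature_track(data.table(chrom = character(), start = integer(),
                                    end = integer()), name = "promoters"))
  s <- ifelse(t$strand == "+", t$tss_pos - upstream, t$tss_pos - downstream)
  e <- ifelse(t$strand == "+", t$tss_pos + downstream, t$tss_pos + upstream)
  s <- pmax(s, 0L)
  if (!is.null(chrom_lengths)) e <- pmin(e, chrom_lengths[t$chrom])
  feature_track(data.table(chrom = t$chrom, start = as.integer(s),
                           end = as.integer(e), strand = t$strand,
                           label = t$gene_id), name = "promoters")
}

#' Complement of covered intervals within a universe
#'
#' Half-open interval subtraction `universe \ flatten(covered)`; used e.g.
#' to derive intergenic regions from gene bodies.
#'
#' @param universe FeatureTrack of non-overlapping intervals.
#' @param covered FeatureTrack (may overlap; flattened first).
#' @param name output track name.
#' @return FeatureTrack.
#' @export
complement_intervals <- function(universe, covered, name = "complement") {
  gu <- GenomicRanges::reduce(track_to_granges(universe))
  if (!nrow(covered)) return(granges_to_track(gu, name = name))
  gc <- GenomicRanges::reduce(track_to_granges(covered))
  granges_to_track(GenomicRanges::setdiff(gu, gc), name = name)
}

#' Classify a CpG universe by DMR and feature membership
#'
#' Counts of the 2x2 partition used for odds-ratio enrichment:
#' a = CpGs inside a DMR and inside the feature, b = inside a DMR but
#' outside, c = outside DMRs but inside the feature, d = outside both.
#' `a + b + c + d` equals the universe size.
#'
#' @param cpg_universe data.table chrom, pos (1-based CpG positions).
#' @param dmrs tiles (chrom, start, end; 0-based half-open).
#' @param feature FeatureTrack.
#' @param feature_name,dmr_set_name labels carried into the result.
#' @return list of class `ContingencyResult` with counts a, b, c, d.
#' @export
cpg_region_contingency <- function(cpg_universe, dmrs, feature,
                                   feature_name = attr(feature, "track_name"),
                                   dmr_set_name = "dmrs") {
  if (!nrow(cpg_universe)) stop("empty CpG universe")
  gp <- points_to_granges(cpg_universe$chrom, cpg_universe$pos)
  in_dmr <- if (nrow(dmrs))
    IRanges::overlapsAny(gp, track_to_granges(feature_track(
      dmrs[, .(chrom, start, end)]))) else rep(FALSE, length(gp))
  in_feat <- if (nrow(feature))
    IRanges::overlapsAny(gp, track_to_granges(feature)) else rep(FALSE, length(gp))
  structure(list(a = sum(in_dmr & in_feat), b = sum(in_dmr & !in_feat),
                 c = sum(!in_dmr & in_feat), d = sum(!in_dmr & !in_feat),
                 odds_ratio = NA_real_, log_or = NA_real_, p_value = NA_real_,
                 feature_name = if (is.null(feature_name)) "feature" else feature_name,
                 dmr_set_name = dmr_set_name),
            class = "ContingencyResult")
}

#' Two-sided Fisher exact p-value by hypergeometric tail summation
#'
#' Sums, over the support of the hypergeometric distribution given the
#' table margins, the probabilities of all tables no more likely than the
#' observed one (with the conventional 1e-7 relative tolerance for
#' floating-point ties).
#'
#' @param a,b,c,d 2x2 table counts.
#' @return p-value in [0, 1].
#' @export
fisher_exact_p <- function(a, b, c, d) {
  m <- a + b       # white balls (row 1)
  n <- c + d       # black balls (row 2)
  k <- a + c       # drawn (column 1)
  if (m + n == 0) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Odds ratio and Fisher significance for a contingency result
#'
#' OR = (a/c)/(b/d) = ad/bc with natural-log `log_or`; a zero in b*c flags
#' the OR infinite/undefined (no continuity correction is applied). The
#' p-value is the two-sided Fisher exact test via [fisher_exact_p()].
#'
#' @param result ContingencyResult from [cpg_region_contingency()].
#' @return ContingencyResult with odds_ratio, log_or and p_value filled in.
#' @export
odds_ratio_test <- function(result) {
  a <- result$a; b <- result$b; c <- result$c; d <- result$d
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (b * c > 0) {
    result$odds_ratio <- (a * d) / (b * c)
    result$log_or <- log(result$odds_ratio)   # -Inf when a*d == 0
  } else {
    result$odds_ratio <- if (a * d > 0) Inf else NaN
    result$log_or <- if (a * d > 0) Inf else NaN
  }
  result$p_value <- fisher_exact_p(a, b, c, d)
  result
}

#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("ContingencyResult %s x %s: a=%d b=%d c=%d d=%d OR=%s p=%s\n",
              x$dmr_set_name, x$feature_name, x$a, x$b, x$c, x$d,
              format(x$odds_ratio), format(x$p_value)))
  invisible(x)
}

#' Enrichment of DMR CpGs by distance to the nearest TSS
#'
#' Assigns every universe CpG to a bin of its unsigned, strand-blind
#' distance (bp) to the nearest TSS and computes one odds ratio per bin
#' (DMR membership x bin membership against the whole universe). Empty bins
#' (a = c = 0) are flagged with undefined OR.
#'
#' @param dmrs tiles (chrom, start, end).
#' @param tss TSS table (gene_id, chrom, tss_pos 0-based).
#' @param bins numeric vector of bin edges in bp; bin i is
#'   `[bins[i], bins[i+1])`, with a final open-ended bin `>= max(bins)`
#'   appended when the last edge is finite. Default edges 0, 1e3, 5e3, 1e4,
#'   5e4, 1e5.
#' @param cpg_universe data.table chrom, pos.
#' @return data.table: bin label, a, b, c, d, odds_ratio, log_or, p_value.
#' @export
tss_distance_enrichment <- function(dmrs, tss, cpg_universe,
                                    bins = c(0, 1e3, 5e3, 1e4, 5e4, 1e5)) {
  stopifnot(nrow(cpg_universe) > 0, !is.unsorted(bins))
  edges <- c(bins, Inf)
  uni <- as.data.table(cpg_universe)[, .(chrom, pos)]
  # unsigned distance: nearest TSS per chromosome via rolling join.
  # CpG pos is 1-based; compare on the same 0-based axis as tss_pos.
  tt <- as.data.table(tss)[, .(chrom, tpos = as.numeric(tss_pos))]
  tt[, match_pos := tpos]
  setkey(tt, chrom, tpos)
  qq <- uni[, .(chrom, tpos = as.numeric(pos - 1L), idx = .I)]
  setkey(qq, chrom, tpos)
  nearest <- tt[qq, roll = "nearest"]
  dist <- numeric(nrow(uni))
  dist[nearest$idx] <- abs(nearest$match_pos - nearest$tpos)  # NA: chrom w/o TSS
  gp <- points_to_granges(uni$chrom, uni$pos)
  in_dmr <- if (nrow(dmrs))
    IRanges::overlapsAny(gp, track_to_granges(feature_track(
      dmrs[, .(chrom, start, end)]))) else rep(FALSE, nrow(uni))
  binned <- findInterval(dist, edges, rightmost.closed = FALSE)
  out <- rbindlist(lapply(seq_len(length(edges) - 1L), function(i) {
    lab <- if (is.infinite(edges[i + 1L]))
      sprintf(">=%g", edges[i]) else sprintf("[%g,%g)", edges[i], edges[i + 1L])
    in_bin <- !is.na(binned) & binned == i
    a <- sum(in_dmr & in_bin); b <- sum(in_dmr & !in_bin)
    c <- sum(!in_dmr & in_bin); d <- sum(!in_dmr & !in_bin)
    r <- odds_ratio_test(structure(
      list(a = a, b = b, c = c, d = d, odds_ratio = NA_real_,
           log_or = NA_real_, p_value = NA_real_, feature_name = lab,
           dmr_set_name = "dmrs"), class = "ContingencyResult"))
    data.table(bin = lab, a = a, b = b, c = c, d = d,
               odds_ratio = r$odds_ratio, log_or = r$log_or,
               p_value = r$p_value, empty = (a + c) == 0L)
  }))
  out[]
}

#' Run odds-ratio enrichment of one DMR set against many feature tracks
#'
#' @param cpg_universe data.table chrom, pos.
#' @param dmrs tiles.
#' @param tracks named list of FeatureTracks.
#' @param dmr_set_name label.
#' @return data.table feature, a, b, c, d, odds_ratio, log_or, p_value.
#' @export
enrichment_report <- function(cpg_universe, dmrs, tracks,
                              dmr_set_name = "dmrs") {
  rbindlist(lapply(names(tracks), function(nm) {
    r <- odds_ratio_test(cpg_region_contingency(
      cpg_universe, dmrs, tracks[[nm]], feature_name = nm,
      dmr_set_name = dmr_set_name))
    data.table(feature = nm, a = r$a, b = r$b, c = r$c, d = r$d,
               odds_ratio = r$odds_ratio, log_or = r$log_or,
               p_value = r$p_value)
  }))
}
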