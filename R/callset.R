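#' Merge opposite-strand calls of a CpG dinucleotide
#'
#' Methylation at a CpG is symmetric across strands: a minus-strand call at
#' position p+1 reports the same dinucleotide as the plus-strand call at p.
#' This sums minus-strand counts into the plus-strand record one base to the
#' left and re-keys everything to the plus strand. Minus-strand records with
#' no plus partner are re-keyed to p-1 on `+`. Total methylated and
#' unmethylated counts are conserved.
#'
#' @param calls MethylationCallSet with strand on every record.
#' @return MethylationCallSet with all records on `+`.
#' @export
merge_strands <- function(calls) {
  rec <- calls$records
  if (!nrow(rec)) return(calls)
  if (any(rec$strand == "-" & rec$pos <= 1L))
    stop("minus-strand record at position 1 has no valid plus-strand partner")
  key_pos <- ifelse(rec$strand == "-", rec$pos - 1L, rec$pos)
  merged <- rec[, .(pos = key_pos, chrom, n_meth, n_unmeth)][
    , .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)), by = .(chrom, pos)]
  merged[, strand := "+"]
  methylation_calls(merged, calls$sample_id)
}

#' Unite replicate call sets into a group-level filtered matrix
#'
#' Builds the cross-sample CpG universe of a group and retains the CpGs
#' covered at `min_coverage` or more in at least `min_per_group` samples
#' (the study design keeps CpGs captured in at least two of three
#' replicates). Per-sample counts are kept for every retained CpG; samples
#' without the site (or below coverage) are flagged absent in the presence
#' mask. Sites are keyed by (chrom, pos); unite after [merge_strands()] so
#' that opposite-strand calls do not split a CpG across keys.
#'
#' @param samples list of MethylationCallSet.
#' @param min_coverage minimum per-sample read coverage (default 5).
#' @param min_per_group minimum number of samples a CpG must be covered in
#'   (default 2). `min_per_group = length(samples)` reproduces strict
#'   all-sample intersection.
#' @param group_id group label.
#' @return object of class `UnitedMatrix`: list with `group_id`, `cpgs`
#'   (data.table chrom/pos, sorted), matrices `meth` and `cov`
#'   (CpG x sample, `NA` where absent), logical `present` mask, `sample_ids`,
#'   and the filter parameters.
#' @export
unite_groups <- function(samples, min_coverage = 5L, min_per_group = 2L,
                         group_id = "group") {
  if (!length(samples)) stop("need at least one sample")
  if (min_per_group < 1L || min_per_group > length(samples))
    stop("min_per_group must be between 1 and the number of samples")
  ids <- vapply(samples, function(s) s$sample_id, "")
  if (anyDuplicated(ids)) ids <- paste0(ids, "_", seq_along(ids))
  # deterministic union, invariant to sample order
  tabs <- lapply(samples, function(s)
    s$records[, .(chrom, pos, n_meth, cov = n_meth + n_unmeth)])
  keys <- unique(rbindlist(lapply(tabs, function(t) t[, .(chrom, pos)])))
  setorder(keys, chrom, pos)
  n <- nrow(keys)
  meth <- cov <- matrix(NA_integer_, nrow = n, ncol = length(samples),
                        dimnames = list(NULL, ids))
  for (j in seq_along(tabs)) {
    idx <- tabs[[j]][keys, on = c("chrom", "pos"), which = TRUE]
    hit <- !is.na(idx)
    meth[hit, j] <- tabs[[j]]$n_meth[idx[hit]]
    cov[hit, j] <- tabs[[j]]$cov[idx[hit]]
  }
  present <- !is.na(cov) & cov >= min_coverage
  keep <- rowSums(present) >= min_per_group
  structure(list(group_id = group_id,
                 cpgs = keys[keep],
                 meth = meth[keep, , drop = FALSE],
                 cov = cov[keep, , drop = FALSE],
                 present = present[keep, , drop = FALSE],
                 sample_ids = ids,
                 min_coverage = as.integer(min_coverage),
                 min_per_group = as.integer(min_per_group)),
            class = "UnitedMatrix")
}

#' @export
print.UnitedMatrix <- function(x, ...) {
  cat("UnitedMatrix", x$group_id, "-", nrow(x$cpgs), "CpGs x",
      length(x$sample_ids), "samples (>=", x$min_coverage, "x in >=",
      x$min_per_group, "samples)\n")
  invisible(x)
}

# pooled per-CpG methylated / total counts over present samples
pooled_counts <- function(united) {
  m <- united$meth
  cv <- united$cov
  m[!united$present] <- 0L
  cv[!united$present] <- 0L
  list(m = rowSums(m), cov = rowSums(cv))
}
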