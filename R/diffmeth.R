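#' Analysis configuration
#'
#' Bundles the pipeline thresholds: per-sample coverage filter, replicate
#' presence rule, DMC gates (absolute methylation difference in percent,
#' inclusive, and FDR q-value, strict), DMR chaining gap and minimum tile
#' width, and the per-CpG test.
#'
#' @param min_coverage minimum per-sample read coverage (default 5).
#' @param min_per_group minimum samples per group covering a CpG (default 2).
#' @param diff_cutoff DMC gate on |methylation difference| in percentage
#'   points; inclusive (default 35, i.e. |diff| >= 35 passes).
#' @param q_cutoff DMC gate on BH q-value; strict (default 0.01, q < 0.01).
#' @param merge_gap maximum distance in bp between neighboring DMCs chained
#'   into one tile (default 500, inclusive).
#' @param min_tile_width minimum DMR tile width in bp (default 100).
#' @param test `"logistic_lrt"` (binomial logistic likelihood-ratio test on
#'   replicate counts; default) or `"fisher_pooled"` (two-sided exact test on
#'   the pooled 2x2 table, for 1-vs-1 designs).
#' @return list of class `AnalysisConfig`.
#' @export
analysis_config <- function(min_coverage = 5L, min_per_group = 2L,
                            diff_cutoff = 35, q_cutoff = 0.01,
                            merge_gap = 500L, min_tile_width = 100L,
                            test = c("logistic_lrt", "fisher_pooled")) {
  test <- match.arg(test)
  stopifnot(min_coverage >= 1, min_per_group >= 1, diff_cutoff > 0,
            q_cutoff > 0, q_cutoff < 1, merge_gap > 0, min_tile_width > 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_per_group = as.integer(min_per_group),
                 diff_cutoff = diff_cutoff, q_cutoff = q_cutoff,
                 merge_gap = as.integer(merge_gap),
                 min_tile_width = as.integer(min_tile_width),
                 test = test),
            class = "AnalysisConfig")
}

#' Pooled methylation difference between two groups at one CpG
#'
#' Coverage-weighted group proportions: 100 * (sum(m_t)/sum(cov_t) -
#' sum(m_c)/sum(cov_c)), treatment minus control, in percentage points.
#'
#' @param treatment_counts,control_counts numeric vectors or 2-column
#'   matrices of per-sample (n_meth, n_unmeth) counts.
#' @return percent difference in [-100, 100].
#' @export
pooled_methylation_difference <- function(treatment_counts, control_counts) {
  tc <- .as_count_matrix(treatment_counts)
  cc <- .as_count_matrix(control_counts)
  cov_t <- sum(tc)
  cov_c <- sum(cc)
  if (cov_t == 0 || cov_c == 0)
    stop("zero total coverage in one group; difference undefined")
  100 * (sum(tc[, 1]) / cov_t - sum(cc[, 1]) / cov_c)
}

.as_count_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2)
    x
  } else {
    stopifnot(length(x) == 2)
    matrix(x, ncol = 2)
  }
}

# binomial log-likelihood at the group MLE, from pooled counts
.binom_ll <- function(m, u) {
  tot <- m + u
  p <- ifelse(tot > 0, m / tot, 0)
  ifelse(m > 0, m * log(p), 0) + ifelse(u > 0, u * log(1 - p), 0)
}

# Vectorized LRT p-values for a binomial-logit group model. Because the
# group-only model's sufficient statistics are the pooled group counts, the
# closed form below equals glm(cbind(m,u) ~ group, binomial) LRT exactly.
lrt_p_values <- function(Mt, Ut, Mc, Uc) {
  stat <- 2 * (.binom_ll(Mt, Ut) + .binom_ll(Mc, Uc) - .binom_ll(Mt + Mc, Ut + Uc))
  pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

#' Per-CpG differential methylation test
#'
#' `logistic_lrt` compares binomial-logit models with and without a group
#' term on per-sample (n_meth, n_unmeth) counts by a 1-df likelihood-ratio
#' chi-square. `fisher_pooled` runs a two-sided exact test on the pooled
#' 2x2 table.
#'
#' @inheritParams pooled_methylation_difference
#' @param method test name.
#' @return p-value.
#' @export
dmc_test <- function(treatment_counts, control_counts,
                     method = c("logistic_lrt", "fisher_pooled")) {
  method <- match.arg(method)
  tc <- .as_count_matrix(treatment_counts)
  cc <- .as_count_matrix(control_counts)
  if (sum(tc) == 0 || sum(cc) == 0) stop("all-zero coverage in a group")
  Mt <- sum(tc[, 1]); Ut <- sum(tc[, 2])
  Mc <- sum(cc[, 1]); Uc <- sum(cc[, 2])
  if (method == "logistic_lrt") {
    lrt_p_values(Mt, Ut, Mc, Uc)
  } else {
    fisher.test(matrix(c(Mt, Ut, Mc, Uc), nrow = 2))$p.value
  }
}

#' Per-CpG differential methylation statistics for two united groups
#'
#' Intersects the CpG universes of the two groups, pools counts over present
#' samples, computes the coverage-weighted methylation difference
#' (treatment - control, percent), the per-CpG p-value, and
#' Benjamini-Hochberg q-values over all tested CpGs.
#'
#' @param united_treatment,united_control UnitedMatrix objects.
#' @param config AnalysisConfig.
#' @return data.table chrom, pos, meth_diff, p_value, q_value for every
#'   tested CpG (q-values span the full tested set, not just called DMCs).
#' @export
dmc_stats <- function(united_treatment, united_control,
                      config = analysis_config()) {
  kt <- copy(united_treatment$cpgs)[, it := .I]
  kc <- copy(united_control$cpgs)[, ic := .I]
  common <- kt[kc, on = c("chrom", "pos"), nomatch = NULL]
  if (!nrow(common)) {
    warning("empty CpG intersection between groups")
    return(data.table(chrom = character(), pos = integer(),
                      meth_diff = numeric(), p_value = numeric(),
                      q_value = numeric()))
  }
  pt <- pooled_counts(united_treatment)
  pc <- pooled_counts(united_control)
  Mt <- pt$m[common$it]; Ct <- pt$cov[common$it]
  Mc <- pc$m[common$ic]; Cc <- pc$cov[common$ic]
  ok <- Ct > 0 & Cc > 0
  if (any(!ok))
    message(sum(!ok), " CpGs skipped for zero pooled coverage in a group")
  common <- common[ok]
  Mt <- Mt[ok]; Ct <- Ct[ok]; Mc <- Mc[ok]; Cc <- Cc[ok]
  diff <- 100 * (Mt / Ct - Mc / Cc)
  p <- if (config$test == "logistic_lrt") {
    lrt_p_values(Mt, Ct - Mt, Mc, Cc - Mc)
  } else {
    vapply(seq_along(Mt), function(i)
      fisher.test(matrix(c(Mt[i], Ct[i] - Mt[i], Mc[i], Cc[i] - Mc[i]),
                         nrow = 2))$p.value, 0)
  }
  out <- data.table(chrom = common$chrom, pos = common$pos,
                    meth_diff = diff, p_value = p,
                    q_value = p.adjust(p, method = "BH"))
  setorder(out, chrom, pos)
  out[]
}

#' Gate tested CpGs into called DMCs
#'
#' Applies the DMC thresholds: |meth_diff| >= diff_cutoff (inclusive) and
#' q_value < q_cutoff (strict). Direction is `hyper` iff meth_diff > 0
#' (hypermethylated in treatment relative to control), else `hypo`.
#'
#' @param stats output of [dmc_stats()].
#' @param config AnalysisConfig.
#' @return data.table of called DMCs with a `direction` column.
#' @export
filter_dmcs <- function(stats, config = analysis_config()) {
  out <- stats[abs(meth_diff) >= config$diff_cutoff & q_value < config$q_cutoff]
  out[, direction := ifelse(meth_diff > 0, "hyper", "hypo")]
  setorder(out, chrom, pos)
  out[]
}

#' Call differentially methylated cytosines between two groups
#'
#' Convenience composition of [dmc_stats()] and [filter_dmcs()].
#'
#' @inheritParams dmc_stats
#' @return data.table of called DMCs (chrom, pos, meth_diff, p_value,
#'   q_value, direction).
#' @export
call_dmcs <- function(united_treatment, united_control,
                      config = analysis_config()) {
  filter_dmcs(dmc_stats(united_treatment, united_control, config), config)
}

#' Write DMCs as TSV
#' @param dmcs data.table from [call_dmcs()]
#' @param path output path
#' @export
write_dmc_tsv <- function(dmcs, path) {
  out <- copy(dmcs)[, strand := "+"]
  setcolorder(out, c("chrom", "pos", "strand", "p_value", "q_value",
                     "meth_diff", "direction"))
  setorder(out, chrom, pos)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
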