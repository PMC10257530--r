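#' Bliss-independence expected combination viability
#'
#' Under Bliss independence the expected viability of a drug combination is
#' the product of the single-drug viabilities (fractions normalized to
#' control).
#'
#' @param v_a,v_b single-drug viability fractions (>= 0; vectorized).
#' @return expected combination viability `v_a * v_b`.
#' @export
expected_combination_viability <- function(v_a, v_b) {
  stopifnot(all(v_a >= 0), all(v_b >= 0))
  v_a * v_b
}

#' Read a long-format viability plate CSV
#'
#' Columns replicate_id, treatment, viability with treatments drug_a,
#' drug_b, combination, control; reshaped to the wide per-replicate table
#' used by [synergy_score()].
#'
#' @param path CSV path.
#' @return data.table replicate_id, drug_a, drug_b, combination, control.
#' @export
read_viability_table <- function(path) {
  long <- fread(path)
  need <- c("replicate_id", "treatment", "viability")
  if (!all(need %in% names(long)))
    stop("viability CSV needs columns: ", paste(need, collapse = ", "))
  wide <- dcast(long, replicate_id ~ treatment, value.var = "viability")
  setorder(wide, replicate_id)
  wide[]
}

#' Exclude replicate sets with outlying control viability
#'
#' A replicate set is excluded if its control value deviates 3 or more
#' standard deviations from the mean control viability. Mean and sample SD
#' (n-1 denominator) are computed leave-one-out, over the other replicates'
#' controls: with the candidate left in, a 3-SD deviation is unattainable
#' below 10 replicates (the maximum standardized deviation of one of n
#' points is (n-1)/sqrt(n)), which would make the rule vacuous at typical
#' plate sizes. Zero SD among the other controls excludes nothing.
#'
#' @param table wide viability table with a control column.
#' @param control_column name of the control column (default "control").
#' @return list: `table` (filtered), `n_excluded`.
#' @export
exclude_outlier_replicates <- function(table, control_column = "control") {
  t <- as.data.table(table)
  ctrl <- t[[control_column]]
  if (length(ctrl) < 2L) stop("need >= 2 control replicates to define an SD")
  drop <- vapply(seq_along(ctrl), function(i) {
    others <- ctrl[-i]
    s <- sd(others)
    if (is.na(s) || s == 0) return(FALSE)
    abs(ctrl[i] - mean(others)) >= 3 * s
  }, TRUE)
  list(table = t[!drop][], n_excluded = sum(drop))
}

#' Bliss synergy score across replicates
#'
#' Per retained replicate set, delta = expected - observed =
#' `drug_a * drug_b - combination`; the score is the mean delta, and the
#' combination is synergistic iff the mean is positive. Replicate sets with
#' outlying controls are excluded first when a control column is present.
#'
#' @param table wide viability table (columns drug_a, drug_b, combination,
#'   optionally control and replicate_id); fractions normalized to control.
#' @param exclude_outliers apply [exclude_outlier_replicates()] when a
#'   control column with >= 2 values is present (default TRUE).
#' @return list of class `SynergyResult`: per-replicate `expected`,
#'   `observed`, `delta`, plus `mean_delta`, `sem_delta`, `is_synergistic`,
#'   `n_replicates`, `n_excluded`.
#' @export
synergy_score <- function(table, exclude_outliers = TRUE) {
  t <- as.data.table(table)
  need <- c("drug_a", "drug_b", "combination")
  if (!all(need %in% names(t)))
    stop("viability table needs columns: ", paste(need, collapse = ", "))
  if (any(t$drug_a < 0 | t$drug_b < 0 | t$combination < 0, na.rm = TRUE))
    stop("negative viabilities")
  n_excluded <- 0L
  if (exclude_outliers && "control" %in% names(t) && nrow(t) >= 2L) {
    ex <- exclude_outlier_replicates(t)
    t <- ex$table
    n_excluded <- ex$n_excluded
  }
  if (!nrow(t)) stop("zero retained replicate sets")
  expected <- expected_combination_viability(t$drug_a, t$drug_b)
  observed <- t$combination
  delta <- expected - observed
  structure(list(expected = expected, observed = observed, delta = delta,
                 mean_delta = mean(delta),
                 sem_delta = if (length(delta) > 1L)
                   sd(delta) / sqrt(length(delta)) else NA_real_,
                 is_synergistic = mean(delta) > 0,
                 n_replicates = length(delta), n_excluded = n_excluded),
            class = "SynergyResult")
}

#' @export
print.SynergyResult <- function(x, ...) {
  cat(sprintf("SynergyResult: mean delta %.4f over %d replicates (%d excluded); %s\n",
              x$mean_delta, x$n_replicates, x$n_excluded,
              if (x$is_synergistic) "synergistic" else "not synergistic"))
  invisible(x)
}
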