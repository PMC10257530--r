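library(data.table)

# call set from a compact spec: list of c(chrom, pos, strand, m, u)
toy_calls <- function(rows, sample_id = "s") {
  rec <- rbindlist(lapply(rows, function(r)
    data.table(chrom = r[[1]], pos = as.integer(r[[2]]), strand = r[[3]],
               n_meth = as.integer(r[[4]]), n_unmeth = as.integer(r[[5]]))))
  methylation_calls(rec, sample_id)
}

# united matrix for one group from per-sample (m, cov) matrices at shared CpGs
toy_united <- function(chrom, pos, meth, cov, group_id = "g",
                       min_coverage = 1L, min_per_group = 1L) {
  samples <- lapply(seq_len(ncol(cov)), function(j) {
    keep <- cov[, j] > 0
    methylation_calls(data.table(
      chrom = chrom[keep], pos = pos[keep], strand = "+",
      n_meth = meth[keep, j], n_unmeth = cov[keep, j] - meth[keep, j]),
      paste0(group_id, "_", j))
  })
  unite_groups(samples, min_coverage = min_coverage,
               min_per_group = min_per_group, group_id = group_id)
}

# DMC table builder
toy_dmcs <- function(pos, diff, chrom = "chr1") {
  data.table(chrom = chrom, pos = as.integer(pos), meth_diff = diff,
             p_value = 1e-6, q_value = 1e-4,
             direction = ifelse(diff > 0, "hyper", "hypo"))
}

# brute-force single-linkage tiling oracle (quadratic, independent of the
# implementation's cumsum chaining)
oracle_tiles <- function(pos, diff, gap, min_width, chrom = "chr1") {
  o <- order(pos)
  pos <- pos[o]; diff <- diff[o]
  n <- length(pos)
  # union-find over all pairs within gap
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(pos[i] - pos[j]) <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  rbindlist(lapply(unique(roots), function(r) {
    p <- pos[roots == r]; d <- diff[roots == r]
    s <- min(p) - 1L; e <- max(p)
    w <- e - s
    if (w < min_width) {
      add <- min_width - w
      left <- add %/% 2L
      s <- max(0L, s - left); e <- e + (add - left)
    }
    data.table(chrom = chrom, start = s, end = e, n = length(p),
               ambiguous = length(unique(sign(d))) > 1L,
               mean_diff = mean(d))
  }))[order(start)]
}
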