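test_that("promoters are strand-aware TSS flanks, clipped at zero", {
  tss <- data.table(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                    tss_pos = c(10000L, 10000L, 1000L),
                    strand = c("+", "-", "+"))
  pr <- build_promoters(tss)
  expect_equal(unlist(pr[label == "g1", .(start, end)]),
               c(start = 8000L, end = 10500L))
  expect_equal(unlist(pr[label == "g2", .(start, end)]),
               c(start = 9500L, end = 12000L))
  expect_equal(unlist(pr[label == "g3", .(start, end)]),
               c(start = 0L, end = 1500L))
  expect_error(build_promoters(data.table(gene_id = "g", chrom = "c",
                                          tss_pos = 1L, strand = "*")),
               "strand")
})

test_that("interval complement subtracts flattened cover from the universe", {
  uni <- feature_track(data.table(chrom = "chr1", start = 0L, end = 1000L))
  cov <- feature_track(data.table(chrom = "chr1", start = 200L, end = 300L))
  got <- complement_intervals(uni, cov)
  expect_equal(got$start, c(0L, 300L))
  expect_equal(got$end, c(200L, 1000L))
  # empty cover is identity
  none <- feature_track(data.table(chrom = character(), start = integer(),
                                   end = integer()))
  expect_equal(as.data.table(complement_intervals(uni, none))[, .(start, end)],
               data.table(start = 0L, end = 1000L))
})

test_that("complement matches a per-bp membership oracle on random layouts", {
  withr::with_seed(41, {
    for (rep in 1:25) {
      L <- 2000L
      uni <- feature_track(data.table(chrom = "chr1", start = 0L, end = L))
      k <- sample(1:8, 1)
      s <- sample.int(L - 50L, k)
      cov <- feature_track(data.table(chrom = "chr1", start = s - 1L,
                                      end = s - 1L + sample(10:200, k,
                                                            replace = TRUE)))
      cov$end <- pmin(cov$end, L)
      got <- complement_intervals(uni, cov)
      # oracle: bp-level membership
      inside <- rep(FALSE, L)
      for (i in seq_len(nrow(cov))) inside[(cov$start[i] + 1):cov$end[i]] <- TRUE
      want <- rep(FALSE, L)
      for (i in seq_len(nrow(got))) want[(got$start[i] + 1):got$end[i]] <- TRUE
      expect_equal(want, !inside)
    }
  })
})

test_that("contingency counts partition the CpG universe", {
  # 1000 CpGs at 1..1000 (1-based); DMRs cover 0-based [0,100): CpGs 1..100;
  # feature covers [0,30) and [500,670): 30 + 170 = 200 CpGs, 30 inside DMRs
  uni <- data.table(chrom = "chr1", pos = 1:1000)
  dmrs <- data.table(chrom = "chr1", start = 0L, end = 100L)
  feat <- feature_track(data.table(chrom = "chr1", start = c(0L, 500L),
                                   end = c(30L, 670L)))
  r <- cpg_region_contingency(uni, dmrs, feat)
  expect_equal(c(r$a, r$b, r$c, r$d), c(30L, 70L, 170L, 730L))
  expect_equal(r$a + r$b + r$c + r$d, 1000L)
  # feature covering everything: b = d = 0
  all_feat <- feature_track(data.table(chrom = "chr1", start = 0L, end = 1000L))
  r2 <- cpg_region_contingency(uni, dmrs, all_feat)
  expect_equal(c(r2$b, r2$d), c(0L, 0L))
  # counts invariant to feature fragmentation
  frag <- feature_track(data.table(chrom = "chr1",
                                   start = c(0L, 10L, 500L, 600L),
                                   end = c(10L, 30L, 600L, 670L)))
  r3 <- cpg_region_contingency(uni, dmrs, frag)
  expect_equal(c(r3$a, r3$b, r3$c, r3$d), c(r$a, r$b, r$c, r$d))
})

test_that("contingency matches per-CpG brute force on random layouts", {
  withr::with_seed(42, {
    for (rep in 1:15) {
      uni <- data.table(chrom = "chr1", pos = sort(sample.int(3000, 400)))
      ds <- sort(sample.int(2900, 5))
      dmrs <- data.table(chrom = "chr1", start = ds,
                         end = ds + sample(20:100, 5, replace = TRUE))
      fs <- sort(sample.int(2900, 6))
      feat <- feature_track(data.table(chrom = "chr1", start = fs - 1L,
                                       end = fs - 1L + sample(20:150, 6,
                                                              replace = TRUE)))
      r <- cpg_region_contingency(uni, dmrs, feat)
      in_dmr <- vapply(uni$pos, function(p)
        any(p - 1 >= dmrs$start & p - 1 < dmrs$end), TRUE)
      in_f <- vapply(uni$pos, function(p)
        any(p - 1 >= feat$start & p - 1 < feat$end), TRUE)
      expect_equal(c(r$a, r$b, r$c, r$d),
                   c(sum(in_dmr & in_f), sum(in_dmr & !in_f),
                     sum(!in_dmr & in_f), sum(!in_dmr & !in_f)))
    }
  })
})

test_that("odds ratio is ad/bc with natural log; zero cells are flagged", {
  mk <- function(a, b, c, d) structure(
    list(a = a, b = b, c = c, d = d, odds_ratio = NA_real_, log_or = NA_real_,
         p_value = NA_real_, feature_name = "f", dmr_set_name = "d"),
    class = "ContingencyResult")
  r <- odds_ratio_test(mk(25, 25, 25, 25))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$log_or, 0)
  r2 <- odds_ratio_test(mk(30, 70, 170, 730))
  expect_equal(r2$odds_ratio, 21900 / 11900)
  expect_equal(r2$log_or, log(21900 / 11900))
  # b*c = 0 with a*d > 0: infinite flag, no correction
  r3 <- odds_ratio_test(mk(5, 0, 3, 2))
  expect_identical(r3$odds_ratio, Inf)
  withr::with_seed(2, {
    for (i in 1:20) {
      x <- sample(1:50, 4)
      rr <- odds_ratio_test(mk(x[1], x[2], x[3], x[4]))
      expect_equal(rr$odds_ratio, x[1] * x[4] / (x[2] * x[3]))
    }
  })
})

test_that("Fisher p equals fisher.test and the enumeration oracle", {
  expect_equal(round(fisher_exact_p(8, 2, 2, 8), 4), 0.023)
  withr::with_seed(43, {
    for (i in 1:200) {
      x <- sample(0:12, 4, replace = TRUE)
      expect_equal(fisher_exact_p(x[1], x[2], x[3], x[4]),
                   fisher.test(matrix(x, 2, byrow = TRUE))$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("TSS-distance enrichment bins CpGs by nearest-TSS distance", {
  # toy genome: TSS at 0-based 1000 and 60000; universe CpGs laid out so the
  # DMR CpGs all sit < 1 kb from a TSS
  tss <- data.table(gene_id = c("g1", "g2"), chrom = "chr1",
                    tss_pos = c(1000L, 60000L), strand = c("+", "-"))
  uni <- data.table(chrom = "chr1",
                    pos = c(seq(600, 1400, by = 50),        # near TSS1
                            seq(170000, 180000, by = 100))) # far
  dmrs <- data.table(chrom = "chr1", start = 590L, end = 1410L)
  td <- tss_distance_enrichment(dmrs, tss, uni)
  first <- td[bin == "[0,1000)"]
  last <- td[bin == ">=100000"]
  expect_gt(first$odds_ratio, 1)
  expect_lt(last$odds_ratio, 1)
  # CpG exactly at a TSS lands in the bin containing zero
  at_tss <- data.table(chrom = "chr1", pos = 1001L)   # 1-based for 0-based 1000
  td0 <- tss_distance_enrichment(dmrs, tss, rbind(uni, at_tss))
  expect_equal(sum(td0$a + td0$c), nrow(uni) + 1L)
  # bins with no CpGs at that distance are flagged empty
  expect_true(td[bin == "[1000,5000)", empty])
  expect_equal(td[bin == "[1000,5000)", a + c], 0L)
  # brute-force distances
  d_oracle <- vapply(uni$pos, function(p)
    min(abs((p - 1) - tss$tss_pos)), 0)
  bins <- c(0, 1e3, 5e3, 1e4, 5e4, 1e5, Inf)
  oracle_counts <- table(cut(d_oracle, bins, right = FALSE))
  expect_equal(as.integer(td$a + td$c), as.integer(oracle_counts))
})

test_that("permuting DMR labels over the universe centers the OR at 1", {
  withr::with_seed(44, {
    uni <- data.table(chrom = "chr1", pos = sort(sample.int(50000, 2000)))
    feat <- feature_track(data.table(chrom = "chr1", start = 0L, end = 25000L))
    in_f <- uni$pos - 1 < 25000
    ors <- replicate(500, {
      lab <- sample(c(rep(TRUE, 200), rep(FALSE, 1800)))
      a <- sum(lab & in_f); b <- sum(lab & !in_f)
      c <- sum(!lab & in_f); d <- sum(!lab & !in_f)
      (a * d) / (b * c)
    })
    expect_lt(abs(median(ors) - 1), 0.15)
  })
})
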