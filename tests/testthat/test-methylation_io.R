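test_that("cytosine-report reader applies the coverage filter inclusively", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t100\t+\t5\t5\tCpG\tCGA",      # coverage 10
               "chr1\t200\t+\t3\t1\tCpG\tCGT",      # coverage 4 -> dropped at 5x
               "chr1\t300\t-\t2\t3\tCpG\tCGC"),     # coverage 5, at threshold
             f)
  cs <- read_cytosine_calls(f, "cytosine_report", min_coverage = 5)
  expect_equal(n_sites(cs), 2L)
  expect_equal(cs$records$pos, c(100L, 300L))
  expect_equal(cs$records[pos == 100, n_meth], 5L)
  # no filtering keeps everything
  expect_equal(n_sites(read_cytosine_calls(f, "cytosine_report")), 3L)
})

test_that("coverage dialect reads counts and assigns plus strand", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr2\t50\t50\t80.0\t8\t2",
               "chr2\t90\t90\t20.0\t1\t4"), f)
  cs <- read_cytosine_calls(f, "coverage", min_coverage = 5)
  expect_equal(n_sites(cs), 2L)
  expect_true(all(cs$records$strand == "+"))
  expect_equal(cs$records[pos == 50, n_meth], 8L)
  expect_equal(cs$records[pos == 90, n_unmeth], 4L)
})

test_that("empty files give empty call sets; malformed input errors with line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f)
  expect_equal(n_sites(read_cytosine_calls(f, "cytosine_report")), 0L)

  writeLines(c("chr1\t100\t+\t5\t5\tCpG\tCGA", "chr1\t200"), f)
  expect_error(read_cytosine_calls(f, "cytosine_report"), "line 2")

  writeLines("chr1\tNOTANUMBER\t+\t5\t5\tCpG\tCGA", f)
  expect_error(read_cytosine_calls(f, "cytosine_report"), "line 1")

  expect_error(methylation_calls(data.table(
    chrom = "chr1", pos = 1L, strand = "+", n_meth = -1L, n_unmeth = 2L)),
    "negative")
})

test_that("round trip read->write->read is lossless for both dialects, incl. gz", {
  cs <- toy_calls(list(c("chr1", 100, "+", 5, 5), c("chr1", 250, "+", 0, 9),
                       c("chr2", 10, "+", 7, 0)))
  for (dialect in c("cytosine_report", "coverage")) {
    for (ext in c(".txt", ".txt.gz")) {
      f <- withr::local_tempfile(fileext = ext)
      write_cytosine_calls(cs, f, dialect)
      back <- read_cytosine_calls(f, dialect, sample_id = cs$sample_id)
      expect_equal(back$records, cs$records, info = paste(dialect, ext))
    }
  }
})

test_that("merge_strands sums minus-strand counts into the plus partner", {
  cs <- toy_calls(list(c("chr1", 100, "+", 5, 5), c("chr1", 101, "-", 3, 7)))
  m <- merge_strands(cs)
  expect_equal(nrow(m$records), 1L)
  expect_equal(m$records$pos, 100L)
  expect_equal(m$records$n_meth, 8L)
  expect_equal(m$records$n_unmeth, 12L)
  # identity on a lone plus record
  lone <- toy_calls(list(c("chr1", 100, "+", 5, 5)))
  expect_equal(merge_strands(lone)$records, lone$records)
  # orphan minus record re-keyed to p-1 on +
  orphan <- merge_strands(toy_calls(list(c("chr1", 101, "-", 3, 7))))
  expect_equal(orphan$records$pos, 100L)
  expect_equal(orphan$records$strand, "+")
  expect_equal(orphan$records$n_meth, 3L)
})

test_that("merge_strands matches a brute-force pairing oracle and conserves counts", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:30, 1)
      pos <- sort(sample(10:200, n))
      strand <- sample(c("+", "-"), n, replace = TRUE)
      m <- sample(0:9, n, replace = TRUE)
      u <- sample(0:9, n, replace = TRUE)
      rec <- data.table(chrom = "chr1", pos = pos, strand = strand,
                        n_meth = m, n_unmeth = u)
      rec <- unique(rec, by = c("chrom", "pos", "strand"))
      cs <- methylation_calls(rec, "r")
      got <- merge_strands(cs)$records
      # oracle: re-key each record independently, aggregate with tapply
      key <- ifelse(rec$strand == "-", rec$pos - 1L, rec$pos)
      exp_m <- tapply(rec$n_meth, key, sum)
      exp_u <- tapply(rec$n_unmeth, key, sum)
      expect_equal(got$pos, as.integer(names(exp_m)))
      expect_equal(got$n_meth, as.integer(exp_m), ignore_attr = TRUE)
      expect_equal(got$n_unmeth, as.integer(exp_u), ignore_attr = TRUE)
      expect_equal(sum(got$n_meth), sum(rec$n_meth))       # conservation
      expect_equal(sum(got$n_unmeth), sum(rec$n_unmeth))
      expect_true(all(got$strand == "+"))
    }
  })
})

test_that("unite_groups retains CpGs covered in enough samples", {
  # CpG 100: >=5x in samples 1,2; CpG 200: >=5x only in sample 1
  s1 <- toy_calls(list(c("chr1", 100, "+", 5, 5), c("chr1", 200, "+", 6, 0)), "a")
  s2 <- toy_calls(list(c("chr1", 100, "+", 2, 3)), "b")
  s3 <- toy_calls(list(c("chr1", 300, "+", 9, 9)), "c")
  u <- unite_groups(list(s1, s2, s3), min_coverage = 5, min_per_group = 2)
  expect_equal(u$cpgs$pos, 100L)
  expect_equal(sum(u$present), 2L)
  # counts of present samples preserved
  expect_equal(u$meth[1, "a"], c(a = 5L))
  expect_equal(u$cov[1, "b"], c(b = 5L))
  # 1-of-3 at min_per_group=1 keeps everything covered somewhere
  u1 <- unite_groups(list(s1, s2, s3), min_coverage = 5, min_per_group = 1)
  expect_equal(u1$cpgs$pos, c(100L, 200L, 300L))
  expect_error(unite_groups(list(s1, s2), min_per_group = 3), "min_per_group")
})

test_that("min_per_group = n samples reproduces strict set intersection", {
  withr::with_seed(5, {
    mk <- function(id) {
      pos <- sort(sample(seq(10, 2000, by = 2), 60))
      toy_calls(lapply(pos, function(p)
        c("chr1", p, "+", sample(3:20, 1), sample(3:20, 1))), id)
    }
    ss <- lapply(c("x", "y", "z"), mk)
    u <- unite_groups(ss, min_coverage = 5, min_per_group = 3)
    inter <- Reduce(intersect, lapply(ss, function(s)
      s$records[n_meth + n_unmeth >= 5, pos]))
    expect_equal(u$cpgs$pos, sort(inter))
  })
})

test_that("unite_groups retained universe is invariant to sample order", {
  withr::with_seed(6, {
    ss <- lapply(1:3, function(i) {
      pos <- sort(sample(seq(10, 500, by = 2), 30))
      toy_calls(lapply(pos, function(p)
        c("chr1", p, "+", sample(0:15, 1), sample(0:15, 1))), paste0("s", i))
    })
    u_fwd <- unite_groups(ss, min_coverage = 5, min_per_group = 2)
    u_rev <- unite_groups(rev(ss), min_coverage = 5, min_per_group = 2)
    expect_equal(u_fwd$cpgs, u_rev$cpgs)
    expect_equal(u_fwd$meth[, u_fwd$sample_ids],
                 u_rev$meth[, u_fwd$sample_ids])
  })
})

test_that("BED round trip preserves intervals, labels and strand", {
  tr <- feature_track(data.table(chrom = c("chr1", "chr2"),
                                 start = c(0L, 500L), end = c(100L, 900L),
                                 strand = c("+", "-"),
                                 label = c("f1", "f2")), name = "toy")
  f <- withr::local_tempfile(fileext = ".bed.gz")
  write_bed(tr, f)
  back <- read_bed(f)
  expect_equal(back$start, tr$start)
  expect_equal(back$end, tr$end)
  expect_equal(back$label, tr$label)
  expect_equal(back$strand, tr$strand)
  expect_error(feature_track(data.table(chrom = "c", start = 10L, end = 10L)),
               "start < end")
})
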