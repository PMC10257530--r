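test_that("tiling chains neighbors within the gap and extends short tiles", {
  d <- toy_dmcs(c(1000, 1400, 2100), c(-40, -50, -45))
  tiles <- tile_dmcs(d, merge_gap = 500, min_tile_width = 100)
  expect_equal(nrow(tiles), 2L)
  # span {1000..1400}: width 401, unextended -> [999, 1400) half-open
  expect_equal(tiles[1, .(start, end)], data.table(start = 999L, end = 1400L))
  # singleton at 2100 extended to width 100 spanning {2051..2150}
  expect_equal(tiles[2, .(start, end)], data.table(start = 2050L, end = 2150L))
  expect_equal(tiles$end - tiles$start, c(401L, 100L))
})

test_that("DMCs exactly merge_gap apart are merged (inclusive)", {
  d <- toy_dmcs(c(1000, 1500), c(-40, -40))
  expect_equal(nrow(tile_dmcs(d, 500, 100)), 1L)
  d2 <- toy_dmcs(c(1000, 1501), c(-40, -40))
  expect_equal(nrow(tile_dmcs(d2, 500, 100)), 2L)
})

test_that("tiles already >= min width are unchanged; extension clips at 0", {
  wide <- toy_dmcs(c(1000, 1150), c(-40, -40))
  t1 <- tile_dmcs(wide, 500, 100)
  expect_equal(t1$start, 999L); expect_equal(t1$end, 1150L)
  edge <- toy_dmcs(10, -40)
  t2 <- tile_dmcs(edge, 500, 100)
  expect_equal(t2$start, 0L)         # clipped, not negative
  expect_equal(t2$end, 60L)
})

test_that("tiling matches the brute-force chaining oracle on random layouts", {
  withr::with_seed(33, {
    for (rep in 1:60) {
      n <- sample(1:50, 1)
      pos <- sort(sample.int(20000, n))
      diff <- sample(c(-60, -40, 40, 55), n, replace = TRUE)
      got <- tile_dmcs(toy_dmcs(pos, diff), 500, 100)
      want <- oracle_tiles(pos, diff, 500, 100)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_dmcs, want$n)
      expect_equal(got$direction == "ambiguous", want$ambiguous)
      expect_equal(got$mean_diff, want$mean_diff)
    }
  })
})

test_that("tiling is idempotent and partitions the input DMCs", {
  withr::with_seed(34, {
    pos <- sort(sample.int(50000, 40))
    d <- toy_dmcs(pos, rep(-40, 40))
    tiles <- tile_dmcs(d, 500, 100)
    # every DMC in exactly one tile
    members <- unlist(tiles$member_pos)
    expect_equal(sort(members), pos)
    # no two tiles separated by <= merge_gap
    if (nrow(tiles) > 1) {
      mem_gaps <- vapply(seq_len(nrow(tiles) - 1), function(i)
        min(unlist(tiles$member_pos[i + 1])) - max(unlist(tiles$member_pos[i])),
        0)
      expect_true(all(mem_gaps > 500))
    }
    # re-tiling the members of one tile reproduces its raw span
    for (i in seq_len(nrow(tiles))) {
      again <- tile_dmcs(toy_dmcs(unlist(tiles$member_pos[i]),
                                  unlist(tiles$member_diff[i])), 500, 100)
      expect_equal(nrow(again), 1L)
      expect_equal(again$start, tiles$start[i])
      expect_equal(again$end, tiles$end[i])
    }
    # shuffled input gives identical tiles
    shuf <- tile_dmcs(toy_dmcs(pos, rep(-40, 40))[sample(.N)], 500, 100)
    expect_equal(shuf, tiles)
  })
})

test_that("ambiguous tiles are removed and the fraction reported", {
  mixed <- rbind(toy_dmcs(c(100, 200), c(40, -40)),
                 toy_dmcs(c(5000, 5100), c(-40, -36)),
                 toy_dmcs(10000, -50), toy_dmcs(20000, 45))
  tiles <- tile_dmcs(mixed, 500, 100)
  expect_equal(nrow(tiles), 4L)
  fa <- filter_ambiguous(tiles)
  expect_equal(fa$ambiguous_fraction, 0.25)
  expect_equal(nrow(fa$tiles), 3L)
  expect_false(any(fa$tiles$direction == "ambiguous"))
  kept <- fa$tiles[chrom == "chr1" & start == 4999L]
  expect_equal(kept$direction, "hypo")
})

test_that("summarize_dmrs averages member differences unweighted", {
  d <- toy_dmcs(c(100, 200), c(-40, -60))
  s <- summarize_dmrs(tile_dmcs(d, 500, 100))
  expect_equal(s$mean_diff, -50)
  s1 <- summarize_dmrs(tile_dmcs(toy_dmcs(300, -35), 500, 100))
  expect_equal(s1$mean_diff, -35)
  withr::with_seed(9, {
    diffs <- runif(12, -90, -36)
    s2 <- summarize_dmrs(tile_dmcs(toy_dmcs(seq(100, by = 50, length.out = 12),
                                            diffs), 500, 100))
    expect_equal(s2$mean_diff, mean(diffs))
  })
})

test_that("Venn partition counts overlap components with correct patterns", {
  mk <- function(start, end) data.table(chrom = "chr1", start = start,
                                        end = end, direction = "hypo")
  # three mutually overlapping tiles -> one A&B&C component
  v1 <- intersect_dmr_sets(list(A = mk(100, 200), B = mk(150, 250),
                                C = mk(180, 220)))
  expect_equal(v1$counts, c(`A&B&C` = 1L))
  # three disjoint tiles -> three singletons
  v2 <- intersect_dmr_sets(list(A = mk(0, 100), B = mk(500, 600),
                                C = mk(1000, 1100)))
  expect_equal(v2$counts[c("A", "B", "C")], c(A = 1L, B = 1L, C = 1L))
  expect_equal(v2$total, 3L)
  # chain: A overlaps B, B overlaps C, A disjoint from C -> one A&B&C
  v3 <- intersect_dmr_sets(list(A = mk(0, 100), B = mk(90, 200),
                                C = mk(190, 300)))
  expect_equal(v3$counts, c(`A&B&C` = 1L))
  # adjacency (shared boundary, no shared bp) does not connect
  v4 <- intersect_dmr_sets(list(A = mk(0, 100), B = mk(100, 200)))
  expect_equal(sort(names(v4$counts)), c("A", "B"))
  expect_error(intersect_dmr_sets(list(
    A = mk(0, 100), B = data.table(chrom = "chr1", start = 0L, end = 50L,
                                   direction = "hyper"))), "mixed directions")
})

test_that("Venn components match a union-find oracle on random tile sets", {
  withr::with_seed(35, {
    for (rep in 1:20) {
      sets <- lapply(1:3, function(i) {
        k <- sample(3:12, 1)
        s <- sort(sample.int(5000, k))
        data.table(chrom = "chr1", start = s, end = s + sample(50:400, k,
                                                               replace = TRUE),
                   direction = "hypo")
      })
      names(sets) <- c("A", "B", "C")
      v <- intersect_dmr_sets(sets)
      # oracle: per-bp component labelling
      all_t <- rbindlist(lapply(names(sets), function(nm)
        sets[[nm]][, .(start, end, set = nm)]))
      covered <- rep(FALSE, 6000)
      for (i in seq_len(nrow(all_t)))
        covered[(all_t$start[i] + 1):all_t$end[i]] <- TRUE
      runs <- rle(covered)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1
      comp_iv <- data.table(s = starts[runs$values], e = ends[runs$values])
      expect_equal(v$total, nrow(comp_iv))
      pats <- vapply(seq_len(nrow(comp_iv)), function(i) {
        inside <- all_t[start + 1 <= comp_iv$e[i] & end >= comp_iv$s[i]]
        paste(sort(unique(inside$set)), collapse = "&")
      }, "")
      expect_equal(sort(rep(names(v$counts), v$counts)), sort(pats))
    }
  })
})
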