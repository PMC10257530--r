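#' Tile DMCs into differentially methylated regions
#'
#' Single-linkage chaining: consecutive DMCs on the same chromosome whose
#' positions differ by at most `merge_gap` bp (inclusive) join one tile. A
#' raw tile spans the minimum to maximum member position (width = span + 1
#' bp, counting both end CpGs). Tiles narrower than `min_tile_width` are
#' extended symmetrically, with an odd remainder adding the extra base on
#' the right; extension is clipped at position 0. Output coordinates are
#' 0-based half-open (BED convention); member DMC positions stay 1-based.
#'
#' @param dmcs data.table with chrom, pos (1-based), meth_diff, direction
#'   (as from [call_dmcs()]).
#' @param merge_gap chaining distance in bp (default 500, inclusive).
#' @param min_tile_width minimum tile width in bp (default 100).
#' @return data.table of tiles: chrom, start, end, n_dmcs, direction
#'   (`hyper`/`hypo`/`ambiguous`), mean_diff (arithmetic mean of member
#'   diffs), and list columns member_pos, member_diff.
#' @export
tile_dmcs <- function(dmcs, merge_gap = 500L, min_tile_width = 100L) {
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_dmcs = integer(), direction = character(),
                      mean_diff = numeric(), member_pos = list(),
                      member_diff = list())
  if (!nrow(dmcs)) return(empty)
  merge_gap <- as.integer(merge_gap)
  min_tile_width <- as.integer(min_tile_width)
  d <- as.data.table(dmcs)[, .(chrom, pos = as.integer(pos), meth_diff)]
  setorder(d, chrom, pos)
  new_tile <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                  d$pos[-1] - d$pos[-nrow(d)] > merge_gap)
  d[, tile_id := cumsum(new_tile)]
  tiles <- d[, {
    lo <- min(pos); hi <- max(pos)
    start0 <- lo - 1L; end0 <- hi
    w <- end0 - start0
    if (w < min_tile_width) {
      add <- min_tile_width - w
      left <- add %/% 2L
      start0 <- max(0L, start0 - left)
      end0 <- end0 + (add - left)
    }
    dirs <- unique(sign(meth_diff))
    .(start = as.integer(start0), end = as.integer(end0), n_dmcs = .N,
      direction = if (length(dirs) > 1L) "ambiguous"
                  else if (dirs > 0) "hyper" else "hypo",
      mean_diff = mean(meth_diff),
      member_pos = list(pos), member_diff = list(meth_diff))
  }, by = .(chrom, tile_id)][, tile_id := NULL]
  setorder(tiles, chrom, start)
  tiles[]
}

#' Remove direction-ambiguous tiles
#'
#' Tiles whose member DMCs mix hyper- and hypomethylation are ambiguous and
#' removed before downstream analysis; the removed fraction is reported.
#'
#' @param tiles data.table from [tile_dmcs()].
#' @return list with `tiles` (clean) and `ambiguous_fraction` (removed /
#'   total; 0 for empty input).
#' @export
filter_ambiguous <- function(tiles) {
  if (!nrow(tiles)) return(list(tiles = tiles, ambiguous_fraction = 0))
  amb <- tiles$direction == "ambiguous"
  list(tiles = tiles[!amb], ambiguous_fraction = mean(amb))
}

#' Summarize DMR methylation difference
#'
#' Sets `mean_diff` to the unweighted arithmetic mean of member DMC
#' methylation differences (the region-level summary).
#'
#' @param tiles unambiguous tiles.
#' @return tiles with recomputed mean_diff.
#' @export
summarize_dmrs <- function(tiles) {
  if (!nrow(tiles)) return(tiles)
  if (any(tiles$direction == "ambiguous"))
    stop("summarize_dmrs expects unambiguous tiles; run filter_ambiguous first")
  out <- copy(tiles)
  out[, mean_diff := vapply(member_diff, mean, 0)]
  out[]
}

#' Intersect DMR sets across comparisons
#'
#' Builds the union of all tiles from 2-3 named same-direction sets, forms
#' connected components under >= 1 bp overlap, and assigns each component the
#' membership pattern of the groups contributing at least one tile. This
#' yields symmetric, order-free Venn counts.
#'
#' @param sets named list (length 2-3) of tile data.tables sharing one
#'   direction.
#' @return list of class `VennPartition`: `counts` (named integer vector
#'   keyed by patterns like `"A&B"`), `regions` (data.table of component
#'   chrom/start/end/pattern), `total` components.
#' @export
intersect_dmr_sets <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L) stop("need 2-3 named sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  dirs <- unique(unlist(lapply(sets, function(s) unique(s$direction))))
  if (length(dirs) > 1L)
    stop("mixed directions across sets: ", paste(dirs, collapse = ", "))
  all_tiles <- rbindlist(lapply(names(sets), function(nm)
    sets[[nm]][, .(chrom, start, end)][, set := nm]))
  if (!nrow(all_tiles))
    return(structure(list(counts = integer(), regions = data.table(),
                          total = 0L), class = "VennPartition"))
  gr <- GenomicRanges::GRanges(all_tiles$chrom,
                               IRanges::IRanges(all_tiles$start + 1L,
                                                all_tiles$end))
  # components under strict >=1 bp overlap: adjacency is not shared sequence
  comps <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, comps, minoverlap = 1L)
  member <- data.table(set = all_tiles$set[S4Vectors::queryHits(hits)],
                       comp = S4Vectors::subjectHits(hits))
  pat <- member[, .(pattern = paste(sort(unique(set)), collapse = "&")),
                by = comp]
  regions <- data.table(chrom = as.character(GenomicRanges::seqnames(comps)),
                        start = GenomicRanges::start(comps) - 1L,
                        end = GenomicRanges::end(comps))
  regions[pat$comp, pattern := pat$pattern]
  counts <- table(pat$pattern)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(list(counts = counts, regions = regions[],
                 total = length(comps)), class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition -", x$total, "union regions\n")
  for (nm in names(x$counts)) cat(" ", nm, ":", x$counts[[nm]], "\n")
  invisible(x)
}

#' Write DMR tiles as BED-like TSV
#' @param tiles tile data.table
#' @param path output path
#' @export
write_dmr_tsv <- function(tiles, path) {
  out <- tiles[, .(chrom, start, end, mean_diff, direction, n_dmcs)]
  setorder(out, chrom, start)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
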