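#' Associate DMRs to genes by basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal domain (`basal_up` bp upstream to
#' `basal_down` bp downstream of the TSS) extended in both directions up to
#' `max_extension` bp or until the nearest neighboring gene's basal domain,
#' whichever comes first. A DMR is associated with every gene whose
#' regulatory domain it overlaps by at least 1 bp; neighboring genes'
#' extensions may both cover the intergenic gap between their basal domains,
#' so a DMR can map to several genes.
#'
#' @param dmrs tiles (chrom, start, end; 0-based half-open).
#' @param genes data.table with gene_id, chrom, tss_pos (0-based), strand.
#' @param basal_up,basal_down basal domain extent in bp (defaults 5000 /
#'   1000).
#' @param max_extension maximum extension in bp (default 1e6).
#' @return list: `associations` (data.table gene_id, dmr_id, chrom, start,
#'   end) and `domains` (data.table gene_id, chrom, domain_start,
#'   domain_end, basal_start, basal_end).
#' @export
associate_regions_to_genes <- function(dmrs, genes, basal_up = 5000L,
                                       basal_down = 1000L,
                                       max_extension = 1000000L) {
  g <- as.data.table(genes)
  stopifnot(all(g$strand %in% c("+", "-")))
  g[, basal_start := pmax(0, ifelse(strand == "+", tss_pos - basal_up,
                                    tss_pos - basal_down))]
  g[, basal_end := ifelse(strand == "+", tss_pos + basal_down,
                          tss_pos + basal_up)]
  dom <- g[, {
    bs <- basal_start; be <- basal_end
    n <- .N
    ds <- de <- numeric(n)
    for (i in seq_len(n)) {
      other_ends <- be[-i][be[-i] <= bs[i]]
      ds[i] <- max(0, bs[i] - max_extension,
                   if (length(other_ends)) max(other_ends) else -Inf)
      other_starts <- bs[-i][bs[-i] >= be[i]]
      de[i] <- min(be[i] + max_extension,
                   if (length(other_starts)) min(other_starts) else Inf)
    }
    .(gene_id = gene_id, domain_start = ds, domain_end = de,
      basal_start = bs, basal_end = be, tss_pos = tss_pos, strand = strand)
  }, by = chrom]
  d <- as.data.table(dmrs)
  if (!nrow(d)) {
    return(list(associations = data.table(gene_id = character(),
                                          dmr_id = integer(),
                                          chrom = character(),
                                          start = integer(), end = integer()),
                domains = dom[]))
  }
  d <- d[, .(chrom, start, end)][, dmr_id := .I]
  gdom <- GenomicRanges::GRanges(dom$chrom,
    IRanges::IRanges(dom$domain_start + 1L, dom$domain_end))
  gdmr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
  hits <- GenomicRanges::findOverlaps(gdmr, gdom, minoverlap = 1L)
  assoc <- data.table(gene_id = dom$gene_id[S4Vectors::subjectHits(hits)],
                      dmr_id = d$dmr_id[S4Vectors::queryHits(hits)],
                      chrom = d$chrom[S4Vectors::queryHits(hits)],
                      start = d$start[S4Vectors::queryHits(hits)],
                      end = d$end[S4Vectors::queryHits(hits)])
  setorder(assoc, gene_id, chrom, start)
  list(associations = assoc[], domains = dom[])
}

#' Partition associated genes by promoter overlap
#'
#' A gene is "within promoter" if at least one of its associated DMRs
#' overlaps its own promoter interval by >= 1 bp, otherwise "outside".
#' Counts are over genes with at least one association.
#'
#' @param associations data.table from [associate_regions_to_genes()].
#' @param promoters FeatureTrack from [build_promoters()] (label = gene_id).
#' @return list: counts `within` / `outside`, proportions, and the per-gene
#'   table.
#' @export
promoter_partition <- function(associations, promoters) {
  a <- as.data.table(associations)
  if (!nrow(a))
    return(list(within = 0L, outside = 0L,
                proportion_within = NaN, proportion_outside = NaN,
                genes = data.table(gene_id = character(),
                                   in_promoter = logical())))
  p <- as.data.table(promoters)[, .(gene_id = label, chrom, start, end)]
  j <- p[a, on = "gene_id", allow.cartesian = TRUE, nomatch = NA]
  # overlap of half-open intervals on the same chromosome
  j[, in_promoter := !is.na(start) & chrom == i.chrom &
      pmax(start, i.start) < pmin(end, i.end)]
  per_gene <- j[, .(in_promoter = any(in_promoter)), by = gene_id]
  w <- sum(per_gene$in_promoter)
  o <- nrow(per_gene) - w
  list(within = w, outside = o,
       proportion_within = w / nrow(per_gene),
       proportion_outside = o / nrow(per_gene),
       genes = per_gene[order(gene_id)])
}

#' Select the n most hypomethylated DMRs
#'
#' Sorts ascending by mean_diff (most negative first), breaking ties by
#' (chrom, start), and returns the first `min(n, total)` tiles.
#'
#' @param dmrs hypo-direction tiles with mean_diff.
#' @param n number to keep (default 8000).
#' @export
select_top_hypomethylated <- function(dmrs, n = 8000L) {
  d <- as.data.table(dmrs)
  if (nrow(d) && any(d$direction != "hypo"))
    stop("select_top_hypomethylated expects hypo-direction DMRs")
  setorder(d, mean_diff, chrom, start)
  head(d, n)[]
}

#' Classify a gene's cancer role from citation counts
#'
#' More oncogene citations -> "Oncogene"; more tumor-suppressor citations ->
#' "Tumor Suppressor Gene"; equal and positive -> the dual label; no
#' citations at all -> "Neither".
#'
#' @param oncogene_citations,tsg_citations nonnegative counts (vectorized).
#' @return character vector of roles.
#' @export
classify_cancer_role <- function(oncogene_citations, tsg_citations) {
  stopifnot(all(oncogene_citations >= 0), all(tsg_citations >= 0))
  ifelse(oncogene_citations > tsg_citations, "Oncogene",
    ifelse(tsg_citations > oncogene_citations, "Tumor Suppressor Gene",
      ifelse(oncogene_citations > 0, "Oncogene/Tumor Suppressor Gene",
             "Neither")))
}
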