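#' Construct a per-sample methylation call set
#'
#' A `MethylationCallSet` holds per-CpG (or per-cytosine) bisulfite counts for
#' one sample: chromosome, 1-based position, strand, and methylated /
#' unmethylated read counts.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`"+"` or `"-"`), `n_meth`, `n_unmeth`.
#' @param sample_id sample label.
#' @return object of class `MethylationCallSet`: a list with `sample_id` and a
#'   keyed `records` data.table sorted by (chrom, pos, strand).
#' @export
methylation_calls <- function(records, sample_id = "sample") {
  rec <- as.data.table(records)
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  miss <- base::setdiff(need, names(rec))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  rec <- rec[, need, with = FALSE]
  rec[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
             strand = as.character(strand),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  if (nrow(rec)) {
    if (any(rec$n_meth < 0L | rec$n_unmeth < 0L))
      stop("negative methylation counts")
    if (any(rec$pos < 1L)) stop("positions must be >= 1")
    if (!all(rec$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (anyDuplicated(rec, by = c("chrom", "pos", "strand")))
      stop("duplicate (chrom, pos, strand) records")
  }
  setorder(rec, chrom, pos, strand)
  structure(list(sample_id = as.character(sample_id), records = rec[]),
            class = "MethylationCallSet")
}

#' @export
print.MethylationCallSet <- function(x, ...) {
  cat("MethylationCallSet", x$sample_id, "-", nrow(x$records), "records\n")
  if (nrow(x$records)) print(head(x$records, 5))
  invisible(x)
}

#' Number of records in a call set
#' @param x MethylationCallSet
#' @export
n_sites <- function(x) nrow(x$records)

.read_tabular <- function(path, n_cols, what) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < n_cols)
  if (length(bad))
    stop(sprintf("%s: malformed line %d (expected >= %d tab-separated fields, got %d)",
                 what, bad[1], n_cols, nf[bad[1]]))
  as.data.table(do.call(rbind, lapply(parts, `[`, seq_len(n_cols))))
}

#' Read per-cytosine bisulfite calls
#'
#' Supports two dialects: `cytosine_report` (Bismark cytosine report: chrom,
#' 1-based pos, strand, count methylated, count unmethylated, context,
#' trinucleotide) and `coverage` (Bismark coverage: chrom, start, end,
#' methylation percent, count methylated, count unmethylated; 1-based
#' inclusive, no strand -- records are read as `+`). Gzipped files are read
#' transparently.
#'
#' @param path file path.
#' @param dialect `"cytosine_report"` or `"coverage"`.
#' @param min_coverage drop records with `n_meth + n_unmeth` below this
#'   (default 1 keeps everything; the pipeline's per-sample filter is 5).
#' @param sample_id sample label; default the file name.
#' @param context for the cytosine-report dialect, keep only records whose
#'   context column matches one of these values (`NULL` keeps all).
#' @return MethylationCallSet
#' @export
read_cytosine_calls <- function(path, dialect = c("cytosine_report", "coverage"),
                                min_coverage = 1L,
                                sample_id = sub("\\.(gz)$", "", basename(path)),
                                context = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(min_coverage >= 1L)
  if (dialect == "cytosine_report") {
    raw <- .read_tabular(path, 5L, "cytosine report")
    if (!nrow(raw)) return(methylation_calls(data.table(
      chrom = character(), pos = integer(), strand = character(),
      n_meth = integer(), n_unmeth = integer()), sample_id))
    setnames(raw, c("chrom", "pos", "strand", "n_meth", "n_unmeth"))
    if (!is.null(context)) {
      full <- .read_tabular(path, 6L, "cytosine report")
      raw <- raw[full$V6 %in% context]
    }
  } else {
    raw <- .read_tabular(path, 6L, "coverage file")
    if (!nrow(raw)) return(methylation_calls(data.table(
      chrom = character(), pos = integer(), strand = character(),
      n_meth = integer(), n_unmeth = integer()), sample_id))
    raw <- raw[, .(chrom = V1, pos = V2, strand = "+", n_meth = V5, n_unmeth = V6)]
  }
  suppressWarnings({
    pos_i <- as.integer(raw$pos)
    m_i <- as.integer(raw$n_meth)
    u_i <- as.integer(raw$n_unmeth)
  })
  bad <- which(is.na(pos_i) | is.na(m_i) | is.na(u_i))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-numeric position or counts", bad[1]))
  rec <- data.table(chrom = raw$chrom, pos = pos_i, strand = raw$strand,
                    n_meth = m_i, n_unmeth = u_i)
  rec <- rec[n_meth + n_unmeth >= min_coverage]
  methylation_calls(rec, sample_id)
}

#' Write a call set in a bisulfite file dialect
#'
#' @param calls MethylationCallSet
#' @param path output path; `.gz` suffix writes gzipped.
#' @param dialect see [read_cytosine_calls()]. The cytosine-report dialect
#'   writes context `CpG` and trinucleotide `CGN`; the coverage dialect writes
#'   1-based inclusive single-base intervals and drops strand.
#' @export
write_cytosine_calls <- function(calls, path,
                                 dialect = c("cytosine_report", "coverage")) {
  dialect <- match.arg(dialect)
  rec <- calls$records
  out <- if (dialect == "cytosine_report") {
    rec[, .(chrom, pos, strand, n_meth, n_unmeth, context = "CpG", tri = "CGN")]
  } else {
    rec[, .(chrom, pos, end = pos,
            pct = ifelse(n_meth + n_unmeth > 0, 100 * n_meth / (n_meth + n_unmeth), 0),
            n_meth, n_unmeth)]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a genomic feature track
#'
#' Feature tracks use the BED convention: 0-based half-open `[start, end)`
#' intervals. They are plain data.tables with columns `chrom`, `start`, `end`
#' and optional `strand` and `label`, carrying the track name as an attribute.
#'
#' @param chrom,start,end vectors (or a data.frame as first argument).
#' @param strand,label optional per-interval annotation.
#' @param name track name.
#' @return data.table of class `FeatureTrack`.
#' @export
feature_track <- function(chrom, start = NULL, end = NULL, strand = NULL,
                          label = NULL, name = "track") {
  if (is.data.frame(chrom)) {
    dt <- as.data.table(chrom)
  } else {
    dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                     end = as.integer(end))
    if (!is.null(strand)) dt[, strand := strand]
    if (!is.null(label)) dt[, label := label]
  }
  if (nrow(dt) && any(dt$start >= dt$end)) stop("intervals require start < end")
  if (nrow(dt) && any(dt$start < 0L)) stop("negative interval start")
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("FeatureTrack", class(data.table())))
  setattr(dt, "track_name", name)
  dt[]
}

#' @export
print.FeatureTrack <- function(x, ...) {
  cat("FeatureTrack", attr(x, "track_name"), "-", nrow(x), "intervals\n")
  NextMethod()
}

#' Read a BED file as a FeatureTrack
#'
#' BED3-BED6; 0-based half-open coordinates; gzip transparently supported.
#' Column 4 (name) is kept as `label`, column 6 as `strand`.
#' @param path BED file path.
#' @param name track name; defaults to the file name.
#' @export
read_bed <- function(path, name = sub("\\.(bed)(\\.gz)?$", "", basename(path))) {
  raw <- .read_tabular(path, 3L, "BED file")
  if (!nrow(raw))
    return(feature_track(data.table(chrom = character(), start = integer(),
                                    end = integer()), name = name))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  full <- strsplit(readLines(con), "\t", fixed = TRUE)
  full <- full[lengths(full) >= 3L]
  nf <- min(lengths(full))
  dt <- data.table(chrom = vapply(full, `[`, "", 1L),
                   start = as.integer(vapply(full, `[`, "", 2L)),
                   end = as.integer(vapply(full, `[`, "", 3L)))
  if (nf >= 4L) dt[, label := vapply(full, `[`, "", 4L)]
  if (nf >= 6L) dt[, strand := vapply(full, `[`, "", 6L)]
  feature_track(dt, name = name)
}

#' Write a FeatureTrack as BED
#' @param track FeatureTrack
#' @param path output path (`.gz` for gzipped)
#' @export
write_bed <- function(track, path) {
  dt <- as.data.table(track)
  out <- data.table(dt$chrom, dt$start, dt$end,
                    if ("label" %in% names(dt)) dt$label else ".",
                    0L,
                    if ("strand" %in% names(dt)) dt$strand else ".")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# FeatureTrack (0-based half-open) -> GRanges (1-based closed)
track_to_granges <- function(track) {
  if (!nrow(track))
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$start + 1L, track$end))
}

granges_to_track <- function(gr, name = "track") {
  feature_track(data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)), name = name)
}

# 1-based point positions -> GRanges
points_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
}
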