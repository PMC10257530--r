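#' Ground-truth parameters for a synthetic bisulfite cohort
#'
#' Fixes every generative choice for a simulated RRBS study: the group
#' design (4 groups x 3 replicates, first group the vehicle control), the
#' bimodal beta-mixture baseline methylome, planted differentially
#' methylated regions with signed effects, negative-binomial read coverage
#' with dropout, and the viability-plate truth for Bliss scoring.
#' Generators are pure functions of this object, so identical truth gives
#' identical cohorts.
#'
#' Planted hypomethylated regions draw their control-side baseline from the
#' high beta component (and hyper regions from the low component) so the
#' planted shift is realizable -- drug-induced hypomethylation happens at
#' methylated loci.
#'
#' @param seed integer seed driving every random draw.
#' @param n_chrom,chrom_length genome shape (default 2 x 25 Mb).
#' @param n_cpgs total CpG sites placed uniformly (default 2e5).
#' @param groups group labels; the first is the control (default PBS plus
#'   three treatment arms).
#' @param n_replicates replicates per group (default 3).
#' @param n_planted number of planted DMRs (default 100).
#' @param planted_width width of each planted region in bp (default 2000).
#' @param effect_range absolute planted effect range in percentage points
#'   (default c(40, 60)).
#' @param hyper_fraction fraction of planted regions hypermethylated
#'   (default 0: all hypo, the study's dominant direction).
#' @param baseline_weights mixture weights (low, high), default
#'   c(0.45, 0.55).
#' @param baseline_low,baseline_high beta shape pairs for the unmethylated
#'   and methylated modes (defaults Beta(0.5, 10) and Beta(10, 0.5)).
#' @param coverage_mean,coverage_dispersion negative-binomial mean and size
#'   (defaults 30, 5).
#' @param dropout probability a site yields no reads in a sample (default
#'   0.05).
#' @param v_a,v_b,epsilon,noise_sd viability truth: single-drug viabilities,
#'   planted synergy (expected - observed shift), Gaussian noise SD
#'   (defaults 0.6, 0.5, 0, 0.05).
#' @return list of class `SimulationTruth`, including the `planted_dmrs`
#'   table (chrom, start, end, effect, direction) drawn from `seed`.
#' @export
simulation_truth <- function(seed = 1L, n_chrom = 2L, chrom_length = 2.5e7,
                             n_cpgs = 2e5,
                             groups = c("PBS", "Aza", "FMTAza", "NPMTAza"),
                             n_replicates = 3L,
                             n_planted = 100L, planted_width = 2000L,
                             effect_range = c(40, 60), hyper_fraction = 0,
                             baseline_weights = c(0.45, 0.55),
                             baseline_low = c(0.5, 10),
                             baseline_high = c(10, 0.5),
                             coverage_mean = 30, coverage_dispersion = 5,
                             dropout = 0.05,
                             v_a = 0.6, v_b = 0.5, epsilon = 0,
                             noise_sd = 0.05) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_cpgs >= 1, length(groups) >= 2,
            n_replicates >= 1, n_planted >= 0, planted_width > 0,
            all(effect_range > 0), all(effect_range <= 100),
            hyper_fraction >= 0, hyper_fraction <= 1,
            coverage_mean > 0, coverage_dispersion > 0,
            dropout >= 0, dropout < 1, noise_sd >= 0,
            v_a >= 0, v_a <= 1, v_b >= 0, v_b <= 1)
  planted <- withr::with_seed(seed, {
    if (n_planted == 0) {
      data.table(chrom = character(), start = integer(), end = integer(),
                 effect = numeric(), direction = character())
    } else {
      per_chrom <- table(factor(sample.int(n_chrom, n_planted, replace = TRUE),
                                levels = seq_len(n_chrom)))
      out <- rbindlist(lapply(seq_len(n_chrom), function(ci) {
        k <- per_chrom[ci]
        if (k == 0) return(NULL)
        # non-overlapping placement by spacing starts on a jittered grid
        slots <- floor(chrom_length / (planted_width * 2))
        if (k > slots) stop("too many planted regions for genome size")
        starts <- sort(sample.int(slots, k)) * planted_width * 2 -
          planted_width * 2 + sample.int(planted_width, k, replace = TRUE)
        data.table(chrom = paste0("chr", ci), start = as.integer(starts),
                   end = as.integer(starts + planted_width))
      }))
      eff <- runif(nrow(out), effect_range[1], effect_range[2])
      hyper <- runif(nrow(out)) < hyper_fraction
      out[, effect := ifelse(hyper, eff, -eff)]
      out[, direction := ifelse(effect > 0, "hyper", "hypo")]
      setorder(out, chrom, start)
      out
    }
  })
  structure(list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, n_cpgs = as.integer(n_cpgs),
                 groups = groups, n_replicates = as.integer(n_replicates),
                 planted_dmrs = planted,
                 baseline_weights = baseline_weights,
                 baseline_low = baseline_low, baseline_high = baseline_high,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion, dropout = dropout,
                 v_a = v_a, v_b = v_b, epsilon = epsilon,
                 noise_sd = noise_sd),
            class = "SimulationTruth")
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping gene bodies with strands and TSSs, then derives
#' consistent feature tracks: promoters (via [build_promoters()]), exons,
#' introns, intergenic regions, and CpG-island-like intervals near a subset
#' of promoters. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param n_chrom,chrom_length genome shape.
#' @param n_genes number of genes (default 300).
#' @param gene_length_range gene body length range in bp.
#' @param island_fraction fraction of promoters given a CpG island (default
#'   0.6).
#' @return list: `genes` (gene_id, chrom, tss_pos, strand, body_start,
#'   body_end), `tss` table, and `tracks` (named list of FeatureTracks:
#'   promoters, gene_bodies, exons, introns, intergenic, cpg_islands).
#' @export
generate_feature_annotation <- function(seed = 1L, n_chrom = 2L,
                                        chrom_length = 2.5e7, n_genes = 300L,
                                        gene_length_range = c(2e3, 2e4),
                                        island_fraction = 0.6) {
  stopifnot(chrom_length > 0, n_genes >= 0)
  empty_track <- function(nm) feature_track(
    data.table(chrom = character(), start = integer(), end = integer()),
    name = nm)
  genome <- feature_track(data.table(chrom = paste0("chr", seq_len(n_chrom)),
                                     start = 0L,
                                     end = as.integer(chrom_length)),
                          name = "genome")
  if (n_genes == 0) {
    tss <- data.table(gene_id = character(), chrom = character(),
                      tss_pos = integer(), strand = character())
    return(list(genes = data.table(), tss = tss,
                tracks = list(promoters = empty_track("promoters"),
                              gene_bodies = empty_track("gene_bodies"),
                              exons = empty_track("exons"),
                              introns = empty_track("introns"),
                              intergenic = granges_to_track(
                                track_to_granges(genome), name = "intergenic"),
                              cpg_islands = empty_track("cpg_islands"))))
  }
  withr::with_seed(seed, {
    per_chrom <- tabulate(sample.int(n_chrom, n_genes, replace = TRUE),
                          nbins = n_chrom)
    genes <- rbindlist(lapply(seq_len(n_chrom), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      len <- as.integer(runif(k, gene_length_range[1], gene_length_range[2]))
      # lay genes on a shuffled grid so bodies never overlap
      slot_w <- floor(chrom_length / k)
      if (slot_w <= max(gene_length_range) + 2e3)
        stop("genome too small for the requested gene count")
      off <- as.integer(runif(k, 1e3, slot_w - len - 1e3))
      start <- (seq_len(k) - 1L) * slot_w + off
      data.table(chrom = paste0("chr", ci), body_start = start,
                 body_end = start + len,
                 strand = sample(c("+", "-"), k, replace = TRUE))
    }))
    genes[, gene_id := sprintf("gene%04d", seq_len(.N))]
    genes[, tss_pos := ifelse(strand == "+", body_start, body_end - 1L)]
    exons <- genes[, {
      n_ex <- sample(2:6, 1)
      len <- body_end - body_start
      cuts <- sort(sample.int(len - 2L, 2L * n_ex - 1L)) # interior breakpoints
      bounds <- c(0L, cuts, len)
      es <- bounds[seq(1, length(bounds) - 1, by = 2)]
      ee <- bounds[seq(2, length(bounds), by = 2)]
      .(start = body_start + es, end = body_start + ee, label = gene_id)
    }, by = .(chrom, gene_id)][, .(chrom, start, end, label)]
    tss <- genes[, .(gene_id, chrom, tss_pos, strand)]
    promoters <- build_promoters(tss)
    bodies <- feature_track(genes[, .(chrom, start = body_start,
                                      end = body_end, strand, label = gene_id)],
                            name = "gene_bodies")
    exon_track <- feature_track(exons, name = "exons")
    introns <- complement_intervals(bodies, exon_track, name = "introns")
    intergenic <- complement_intervals(genome, bodies, name = "intergenic")
    with_island <- genes[runif(.N) < island_fraction]
    islands <- if (nrow(with_island)) {
      iw <- as.integer(runif(nrow(with_island), 300, 1500))
      feature_track(data.table(chrom = with_island$chrom,
                               start = pmax(0L, with_island$tss_pos - iw %/% 2L),
                               end = with_island$tss_pos + iw %/% 2L),
                    name = "cpg_islands")
    } else empty_track("cpg_islands")
    list(genes = genes[], tss = tss[],
         tracks = list(promoters = promoters, gene_bodies = bodies,
                       exons = exon_track, introns = introns,
                       intergenic = intergenic, cpg_islands = islands))
  })
}

#' Generate a synthetic methylome cohort
#'
#' Places CpG sites uniformly, draws per-CpG baseline methylation from the
#' two-component beta mixture, applies the planted effects to the treatment
#' groups (shifts clamped to [0, 1]; control baselines inside planted
#' regions resampled from the mode matching the effect direction), then
#' draws per-sample coverage from a negative binomial with dropout and
#' methylated counts from a binomial. Sites with zero coverage in a sample
#' are absent from that sample's call set.
#'
#' @param truth SimulationTruth.
#' @param split_strands emit per-strand records (counts split binomially
#'   between the `+` call at p and the `-` call at p+1) to exercise
#'   [merge_strands()]; default FALSE emits merged `+` records.
#' @return list: `samples` (list of MethylationCallSet named
#'   `<group>_<rep>`), `sites` (data.table chrom, pos, p per group), `truth`.
#' @export
generate_methylome_cohort <- function(truth, split_strands = FALSE) {
  stopifnot(inherits(truth, "SimulationTruth"))
  withr::with_seed(truth$seed, {
    n <- truth$n_cpgs
    per_chrom <- tabulate(sample.int(truth$n_chrom, n, replace = TRUE),
                          nbins = truth$n_chrom)
    sites <- rbindlist(lapply(seq_len(truth$n_chrom), function(ci) {
      k <- per_chrom[ci]
      # even positions >= 2 keep room for a minus-strand partner at p+1
      pos <- sort(sample.int(floor((truth$chrom_length - 2) / 2), k)) * 2L
      data.table(chrom = paste0("chr", ci), pos = pos)
    }))
    w_high <- truth$baseline_weights[2] / sum(truth$baseline_weights)
    comp_high <- runif(nrow(sites)) < w_high
    p0 <- ifelse(comp_high,
                 rbeta(nrow(sites), truth$baseline_high[1], truth$baseline_high[2]),
                 rbeta(nrow(sites), truth$baseline_low[1], truth$baseline_low[2]))
    planted <- truth$planted_dmrs
    region_of <- rep(0L, nrow(sites))
    if (nrow(planted)) {
      hits <- GenomicRanges::findOverlaps(
        points_to_granges(sites$chrom, sites$pos),
        track_to_granges(feature_track(planted[, .(chrom, start, end)])))
      region_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
      # make the planted shift realizable: resample baseline from the mode
      # the effect moves away from
      idx <- which(region_of > 0L)
      eff <- planted$effect[region_of[idx]]
      hi <- eff < 0
      p0[idx[hi]] <- rbeta(sum(hi), truth$baseline_high[1], truth$baseline_high[2])
      p0[idx[!hi]] <- rbeta(sum(!hi), truth$baseline_low[1], truth$baseline_low[2])
    }
    p_treat <- p0
    if (nrow(planted)) {
      idx <- which(region_of > 0L)
      p_treat[idx] <- pmin(1, pmax(0, p0[idx] +
                                     planted$effect[region_of[idx]] / 100))
    }
    sites[, `:=`(p_control = p0, p_treatment = p_treat,
                 planted_region = region_of)]
    # draw all coverage/count vectors first so the strand-split option does
    # not perturb the stream those draws come from
    draws <- list()
    for (gi in seq_along(truth$groups)) {
      p_g <- if (gi == 1L) p0 else p_treat
      for (r in seq_len(truth$n_replicates)) {
        cov <- rnbinom(nrow(sites), mu = truth$coverage_mean,
                       size = truth$coverage_dispersion)
        cov[runif(nrow(sites)) < truth$dropout] <- 0L
        m <- rbinom(nrow(sites), cov, p_g)
        draws[[paste0(truth$groups[gi], "_", r)]] <- list(cov = cov, m = m)
      }
    }
    samples <- lapply(names(draws), function(id) {
      cov <- draws[[id]]$cov
      m <- draws[[id]]$m
      keep <- cov > 0L
      rec <- if (split_strands) {
        mp <- rbinom(sum(keep), m[keep], 0.5)
        up <- rbinom(sum(keep), cov[keep] - m[keep], 0.5)
        rec2 <- rbind(
          data.table(chrom = sites$chrom[keep], pos = sites$pos[keep],
                     strand = "+", n_meth = mp, n_unmeth = up),
          data.table(chrom = sites$chrom[keep], pos = sites$pos[keep] + 1L,
                     strand = "-", n_meth = m[keep] - mp,
                     n_unmeth = cov[keep] - m[keep] - up))
        rec2[n_meth + n_unmeth > 0L]       # strand-level zero-read records
      } else {
        data.table(chrom = sites$chrom[keep], pos = sites$pos[keep],
                   strand = "+", n_meth = m[keep],
                   n_unmeth = cov[keep] - m[keep])
      }
      methylation_calls(rec, id)
    })
    names(samples) <- names(draws)
    list(samples = samples, sites = sites[], truth = truth)
  })
}

#' Generate a synthetic viability plate
#'
#' Observed combination viability is `v_a * v_b - epsilon` plus Gaussian
#' noise, floored at 0; single drugs and controls are noised around their
#' own truth (control base 1). Optional planted control outliers shift the
#' control value by `outlier_shift`.
#'
#' @param truth SimulationTruth (fields v_a, v_b, epsilon, noise_sd).
#' @param n_replicates number of replicate sets (default 3).
#' @param n_outliers replicate sets given an outlying control (default 0).
#' @param outlier_shift control shift for planted outliers (default 0.8).
#' @return list: `table` (wide viability data.table), `truth`.
#' @export
generate_viability_table <- function(truth, n_replicates = 3L,
                                     n_outliers = 0L, outlier_shift = 0.8) {
  stopifnot(inherits(truth, "SimulationTruth"), n_replicates >= 1,
            n_outliers >= 0, n_outliers <= n_replicates)
  withr::with_seed(truth$seed + 1L, {
    noise <- function(n) rnorm(n, 0, truth$noise_sd)
    tab <- data.table(
      replicate_id = sprintf("rep%03d", seq_len(n_replicates)),
      drug_a = pmax(0, truth$v_a + noise(n_replicates)),
      drug_b = pmax(0, truth$v_b + noise(n_replicates)),
      combination = pmax(0, truth$v_a * truth$v_b - truth$epsilon +
                           noise(n_replicates)),
      control = pmax(0, 1 + noise(n_replicates)))
    if (n_outliers > 0) {
      idx <- seq_len(n_outliers)
      tab[idx, control := control + outlier_shift]
    }
    list(table = tab[], truth = truth)
  })
}
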