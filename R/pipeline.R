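#' Run the full methylome + synergy pipeline
#'
#' Orchestrates the stages end-to-end on a synthetic cohort (or caller-read
#' inputs): strand handling, per-group uniting, DMC calling per
#' treatment-vs-control comparison, DMR tiling with ambiguity removal, Venn
#' intersection of hypo-DMR sets across comparisons, feature odds-ratio
#' enrichment, feature-centered profiles, gene association and promoter
#' partition, and (optionally) Bliss synergy scoring. All artifacts are
#' written under `out_dir` as TSV/JSON; outputs are a pure function of the
#' config.
#'
#' @param config either a YAML file path or a list with elements:
#'   `seed` (integer), `out_dir` (output directory), optional `truth`
#'   (overrides passed to [simulation_truth()]), optional `analysis`
#'   (overrides passed to [analysis_config()]), optional `annotation`
#'   (overrides passed to [generate_feature_annotation()]), and optional
#'   logical `synergy` (default TRUE).
#' @return RunManifest: list with the echoed config, output paths, per-file
#'   md5 checksums, stage timings (seconds) and the package version;
#'   also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$out_dir)) stop("config error: missing field 'out_dir'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), "wt")
  on.exit(close(log_con), add = TRUE)
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  timings <- c()
  stage <- function(name, expr) {
    say("== stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  outputs <- character()
  emit <- function(path) { outputs <<- c(outputs, path); path }

  truth <- do.call(simulation_truth,
                   c(list(seed = seed), config$truth))
  cfg <- do.call(analysis_config, as.list(config$analysis))

  cohort <- stage("simulate", generate_methylome_cohort(truth))
  say("  ", length(cohort$samples), " samples, ", nrow(cohort$sites), " CpG sites")
  anno <- stage("annotation", do.call(generate_feature_annotation,
    c(list(seed = seed, n_chrom = truth$n_chrom,
           chrom_length = truth$chrom_length), config$annotation)))

  groups <- truth$groups
  by_group <- split(cohort$samples,
                    sub("_[0-9]+$", "", names(cohort$samples)))[groups]
  united <- stage("unite", lapply(groups, function(g)
    unite_groups(by_group[[g]], min_coverage = cfg$min_coverage,
                 min_per_group = cfg$min_per_group, group_id = g)))
  names(united) <- groups
  for (g in groups)
    say("  ", g, ": ", nrow(united[[g]]$cpgs), " CpGs retained")

  control <- groups[1]
  treatments <- groups[-1]
  comparisons <- stage("dmc", {
    lapply(treatments, function(g) {
      st <- dmc_stats(united[[g]], united[[control]], cfg)
      dm <- filter_dmcs(st, cfg)
      write_dmc_tsv(dm, emit(file.path(out_dir, paste0("dmc_", g, ".tsv"))))
      say("  ", g, " vs ", control, ": ", nrow(st), " tested, ",
          nrow(dm), " DMCs (", sum(dm$direction == "hypo"), " hypo)")
      list(stats = st, dmcs = dm)
    })
  })
  names(comparisons) <- treatments

  dmrs <- stage("dmr", {
    lapply(treatments, function(g) {
      tiles <- tile_dmcs(comparisons[[g]]$dmcs, merge_gap = cfg$merge_gap,
                         min_tile_width = cfg$min_tile_width)
      fa <- filter_ambiguous(tiles)
      clean <- summarize_dmrs(fa$tiles)
      write_dmr_tsv(clean, emit(file.path(out_dir, paste0("dmr_", g, ".tsv"))))
      say("  ", g, ": ", nrow(tiles), " tiles, ",
          sprintf("%.2f%%", 100 * fa$ambiguous_fraction), " ambiguous removed")
      clean
    })
  })
  names(dmrs) <- treatments

  venn <- stage("venn", {
    hypo_sets <- lapply(dmrs, function(d) d[direction == "hypo"])
    v <- if (length(hypo_sets) >= 2 && all(vapply(hypo_sets, nrow, 0L) > 0)) {
      intersect_dmr_sets(hypo_sets)
    } else {
      structure(list(counts = integer(), regions = data.table(), total = 0L),
                class = "VennPartition")
    }
    jsonlite::write_json(list(counts = as.list(v$counts), total = v$total),
                         emit(file.path(out_dir, "venn_hypo.json")),
                         auto_unbox = TRUE)
    v
  })

  universe <- united[[control]]$cpgs
  enrich <- stage("enrich", {
    rbindlist(lapply(treatments, function(g) {
      rep <- enrichment_report(universe, dmrs[[g]], anno$tracks,
                               dmr_set_name = g)
      rep[, comparison := g]
      rep
    }))
  })
  fwrite_tsv(enrich, emit(file.path(out_dir, "enrichment.tsv")))

  profiles <- stage("profile", {
    prof <- rbindlist(lapply(groups, function(g) {
      pr <- suppressWarnings(feature_centered_profile(
        by_group[[g]], anno$tracks$promoters))
      as.data.table(pr)[, group := g]
    }))
    fwrite_tsv(prof, emit(file.path(out_dir, "profiles_promoters.tsv")))
    prof
  })

  gene_assoc <- stage("genes", {
    first_t <- treatments[1]
    hypo <- dmrs[[first_t]][direction == "hypo"]
    top <- select_top_hypomethylated(hypo, n = 8000L)
    assoc <- associate_regions_to_genes(top, anno$tss)
    part <- promoter_partition(assoc$associations, anno$tracks$promoters)
    fwrite_tsv(assoc$associations,
               emit(file.path(out_dir, "gene_associations.tsv")))
    jsonlite::write_json(list(within = part$within, outside = part$outside,
                              proportion_within = part$proportion_within),
                         emit(file.path(out_dir, "promoter_partition.json")),
                         auto_unbox = TRUE)
    say("  ", nrow(assoc$associations), " gene-DMR associations; ",
        part$within, " genes with a promoter DMR")
    list(assoc = assoc, partition = part)
  })

  syn <- NULL
  if (is.null(config$synergy) || isTRUE(config$synergy)) {
    syn <- stage("synergy", {
      vt <- generate_viability_table(truth)
      s <- synergy_score(vt$table)
      jsonlite::write_json(list(mean_delta = s$mean_delta,
                                is_synergistic = s$is_synergistic,
                                n_replicates = s$n_replicates,
                                n_excluded = s$n_excluded),
                           emit(file.path(out_dir, "synergy.json")),
                           auto_unbox = TRUE, digits = NA)
      s
    })
  }

  manifest <- list(config = config,
                   seed = seed,
                   outputs = basename(outputs),
                   checksums = as.list(tools::md5sum(outputs)),
                   timings = as.list(timings),
                   version = as.character(packageVersion("methylsynergy")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  say("pipeline complete: ", length(outputs), " artifacts in ", out_dir)
  invisible(manifest)
}

fwrite_tsv <- function(dt, path) {
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
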