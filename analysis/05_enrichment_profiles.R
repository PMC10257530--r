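# Genomic-feature characterization of the hypo-DMRs: CpG-level odds-ratio
# enrichment against annotation tracks, TSS-distance enrichment, and 5-kb
# promoter-centered methylation profiles per group.
source("analysis/00_config.R")

truth <- study_truth()
cohort <- generate_methylome_cohort(truth)
united <- unite_all(cohort)
control <- truth$groups[1]
g1 <- setdiff(truth$groups, control)[1]
anno <- generate_feature_annotation(seed = SEED, n_chrom = truth$n_chrom,
                                    chrom_length = truth$chrom_length)

dmcs <- call_dmcs(united[[g1]], united[[control]], study_cfg)
dmrs <- summarize_dmrs(filter_ambiguous(
  tile_dmcs(dmcs, study_cfg$merge_gap, study_cfg$min_tile_width))$tiles)
hypo <- dmrs[direction == "hypo"]
universe <- united[[control]]$cpgs

enr <- enrichment_report(universe, hypo, anno$tracks, dmr_set_name = g1)
fwrite(enr, file.path(OUT, "feature_enrichment.tsv"), sep = "\t")
cat("CpG odds-ratio enrichment of", g1, "hypo-DMRs (universe:",
    nrow(universe), "CpGs):\n")
print(enr[, .(feature, a, odds_ratio = round(odds_ratio, 3),
              log_or = round(log_or, 3), p_value = signif(p_value, 3))])

tssd <- tss_distance_enrichment(hypo, anno$tss, universe)
fwrite(tssd, file.path(OUT, "tss_distance_enrichment.tsv"), sep = "\t")
cat("\nTSS-distance enrichment (unsigned bp to nearest TSS):\n")
print(tssd[, .(bin, a, c, log_or = round(log_or, 3))])

# 5-kb promoter-centered methylation curves per group
gs <- split(cohort$samples, sub("_[0-9]+$", "", names(cohort$samples)))
profs <- rbindlist(lapply(truth$groups, function(g) {
  pr <- as.data.table(feature_centered_profile(gs[[g]], anno$tracks$promoters))
  pr[, group := g]
}))
fwrite(profs, file.path(OUT, "promoter_profiles.tsv"), sep = "\t")
cat(sprintf("\nwrote promoter-centered profiles (%d bins x %d groups)\n",
            max(profs$bin), length(truth$groups)))
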