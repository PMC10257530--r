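# Per-CpG differential methylation of each treatment arm against the PBS
# control: binomial logistic LRT, BH q-values, and the |diff| >= 35 / q < 0.01
# DMC gate. Also checks recovery of the planted regions at DMC level.
source("analysis/00_config.R")

truth <- study_truth()
cohort <- generate_methylome_cohort(truth)
united <- unite_all(cohort)
control <- truth$groups[1]

dmc_summary <- rbindlist(lapply(setdiff(truth$groups, control), function(g) {
  st <- dmc_stats(united[[g]], united[[control]], study_cfg)
  dm <- filter_dmcs(st, study_cfg)
  write_dmc_tsv(dm, file.path(OUT, paste0("dmc_", g, "_vs_", control, ".tsv")))
  data.table(comparison = paste0(g, "v", control),
             tested = nrow(st),
             dmcs = nrow(dm),
             hypo = sum(dm$direction == "hypo"),
             hyper = sum(dm$direction == "hyper"),
             median_abs_diff = stats::median(abs(dm$meth_diff)))
}))
fwrite(dmc_summary, file.path(OUT, "dmc_summary.tsv"), sep = "\t")
print(dmc_summary)

# planted CpGs recovered as DMCs
sites <- cohort$sites[planted_region > 0, .(chrom, pos)]
first_t <- setdiff(truth$groups, control)[1]
dm1 <- fread(file.path(OUT, paste0("dmc_", first_t, "_vs_", control, ".tsv")))
hit <- nrow(dm1[sites, on = c("chrom", "pos"), nomatch = NULL])
cat(sprintf("\n%s: %d of %d planted-region CpGs called as DMCs (%.1f%%)\n",
            first_t, hit, nrow(sites), 100 * hit / max(1, nrow(sites))))
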