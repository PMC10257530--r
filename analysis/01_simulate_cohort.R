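# Generate the synthetic study: a 4-group x 3-replicate bisulfite cohort
# with planted hypomethylated regions, a matching genome annotation, and a
# viability plate. Writes the raw artifacts the later scripts consume.
source("analysis/00_config.R")

truth <- study_truth()
cohort <- generate_methylome_cohort(truth)
anno <- generate_feature_annotation(seed = SEED, n_chrom = truth$n_chrom,
                                    chrom_length = truth$chrom_length)

data_dir <- file.path(OUT, "data")
dir.create(data_dir, showWarnings = FALSE)

for (id in names(cohort$samples))
  write_cytosine_calls(cohort$samples[[id]],
                       file.path(data_dir, paste0(id, ".cov.gz")), "coverage")
for (nm in names(anno$tracks))
  write_bed(anno$tracks[[nm]], file.path(data_dir, paste0(nm, ".bed.gz")))
fwrite(anno$tss, file.path(data_dir, "tss.tsv"), sep = "\t")
fwrite(truth$planted_dmrs, file.path(data_dir, "planted_dmrs.tsv"),
       sep = "\t")
jsonlite::write_json(
  list(seed = truth$seed, n_cpgs = truth$n_cpgs, groups = truth$groups,
       n_replicates = truth$n_replicates, n_planted = nrow(truth$planted_dmrs),
       coverage_mean = truth$coverage_mean, dropout = truth$dropout),
  file.path(data_dir, "truth.json"), auto_unbox = TRUE)

cat(sprintf("cohort: %d samples x ~%d CpGs; %d planted hypoDMRs; %d genes annotated\n",
            length(cohort$samples), truth$n_cpgs, nrow(truth$planted_dmrs),
            nrow(anno$genes)))
cat("raw artifacts written under", data_dir, "\n")
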