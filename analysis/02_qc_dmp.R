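#!/usr/bin/env Rscript
# Probe filtering, PCA sample QC, and per-probe differential methylation for
# both contrasts (PSC-UC vs UC, PSC-UC vs HC) on M-values with age and
# steroid adjustment. Writes DMP tables, the top-10 table and a BED of
# nominally significant loci under results/.

suppressPackageStartupMessages(library(methcohort))

ds <- read_dataset("results/data/manifest.tsv", "results/data/beta.tsv",
                   "results/data/samples.csv")
flt <- filter_probes(ds$manifest, ds$beta)   # drop SNP/cross-reactive, keep chrX
cat(sprintf("probe filtering: %d -> %d probes\n",
            nrow(ds$manifest), nrow(flt$manifest)))

qc <- pca_qc(flt$beta, k = 2, outlier_sd = 3, sheet = ds$sheet)
print(qc)
print(qc$group_assoc)

m <- beta_to_m(flt$beta)
dir.create("results", showWarnings = FALSE)
for (ctr in c("PSC_UC_vs_UC", "PSC_UC_vs_HC")) {
  dmp <- fit_probe_models(m, ds$sheet, ctr, beta = flt$beta)
  write_report(dmp, sprintf("results/dmp_%s.tsv", ctr), "tsv")
  top <- top_table(dmp, 10)
  cat(sprintf("\n%s: %d probes at raw p < 0.05, %d at BH < 0.05; top probe %s (p = %.2e, %s)\n",
              ctr, sum(dmp$p < 0.05, na.rm = TRUE),
              sum(dmp$adj_p < 0.05, na.rm = TRUE),
              top$probe_id[1], top$p[1], top$direction[1]))
  print(top[, c("probe_id", "effect", "t", "p", "adj_p", "direction")])
  sig <- dmp[!is.na(dmp$p) & dmp$p < 0.05, ]
  write_report(sig, sprintf("results/dmp_%s_nominal.bed", ctr), "bed",
               manifest = flt$manifest)
  if (ctr == "PSC_UC_vs_UC") {
    write_report(top, "results/dmp_top10_PSC_UC_vs_UC.tsv", "tsv")
  }
}
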