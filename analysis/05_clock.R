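#!/usr/bin/env Rscript
# Epigenetic-clock age prediction, correlation with chronological age, and
# group comparison of the age acceleration, on raw and quantile-normalized
# beta values (the normalization sensitivity the acceleration estimate is
# known to carry).

suppressPackageStartupMessages(library(methcohort))

ds <- read_dataset("results/data/manifest.tsv", "results/data/beta.tsv",
                   "results/data/samples.csv")
dir.create("results", showWarnings = FALSE)
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
clock <- structure(list(
  intercept = truth$clock$intercept,
  coefficients = unlist(truth$clock$coefficients),
  adult_age = truth$clock$adult_age,
  reference_means = unlist(truth$clock$reference_means)),
  class = "clock_model")

for (norm in c("none", "quantile")) {
  beta <- if (norm == "quantile") quantile_normalize(ds$beta) else ds$beta
  res <- predict_age(beta, clock, ds$sheet)
  cmp <- compare_acceleration(res, ds$sheet)
  cat(sprintf("\nnormalization = %s\n", norm))
  cat(sprintf("  Spearman rho (predicted vs chronological): %.3f\n",
              res$spearman_rho))
  print(cmp$by_group)
  cat(sprintf("  Kruskal-Wallis omnibus p = %.3f\n", cmp$kruskal_p))
  if (norm == "none") {
    utils::write.table(res$ages, "results/dnam_age.tsv", sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(spearman_rho = res$spearman_rho,
                              by_group = cmp$by_group,
                              kruskal_p = cmp$kruskal_p),
                         "results/age_acceleration.json",
                         auto_unbox = TRUE, digits = NA)
  }
}
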