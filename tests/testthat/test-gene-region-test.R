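test_that("genome ordering sorts chromosomes, positions and ties", {
  mf <- data.frame(
    probe_id = c("cgD", "cgA", "cgC", "cgB", "cgE"),
    chromosome = c("chr2", "chr1", "chr1", "chr1", "chrX"),
    position = c(10, 100, 50, 100, 5),
    gene_symbol = "", snp_associated = FALSE, cross_reactive = FALSE,
    allosomal = FALSE, stringsAsFactors = FALSE)
  ord <- order_probes(mf)
  expect_equal(ord$probe_id, c("cgC", "cgA", "cgB", "cgD", "cgE"))
  expect_identical(order_probes(ord), ord)        # idempotent
  # chr10 sorts after chr2 numerically, not lexically
  mf2 <- data.frame(probe_id = c("a", "b"), chromosome = c("chr10", "chr2"),
                    position = c(1, 1), gene_symbol = "",
                    snp_associated = FALSE, cross_reactive = FALSE,
                    allosomal = FALSE, stringsAsFactors = FALSE)
  expect_equal(order_probes(mf2)$chromosome, c("chr2", "chr10"))
})

test_that("Fisher statistic matches its closed form and handles edge cases", {
  expect_equal(as.numeric(fisher_statistic(c(1, 1))), 0)
  expect_equal(as.numeric(fisher_statistic(c(0.5, 0.5))), 4 * log(2),
               tolerance = 1e-12)
  x <- fisher_statistic(c(0.1, NA, 0.2))
  expect_equal(as.numeric(x), -2 * (log(0.1) + log(0.2)))
  expect_equal(attr(x, "n_missing"), 1)
  expect_warning(x0 <- fisher_statistic(c(0, 0.5)), "floored")
  expect_true(is.finite(x0))
})

test_that("stretch sampling is deterministic with the documented edge cases", {
  p <- runif(10)
  chrom <- rep("chr1", 10)
  # the only admissible stretch is the whole chromosome
  s <- sample_null_stretches(p, chrom, N = 10, B = 20, seed = 1)
  expect_equal(s, rep(-2 * sum(log(p)), 20), tolerance = 1e-12)
  # N = 1 reduces to -2 log of single sampled p-values
  s1 <- sample_null_stretches(p, chrom, N = 1, B = 50, seed = 2)
  match_one <- vapply(s1, function(v) min(abs(v - (-2 * log(p)))) < 1e-9, TRUE)
  expect_true(all(match_one))
  expect_identical(sample_null_stretches(p, chrom, 3, 100, seed = 9),
                   sample_null_stretches(p, chrom, 3, 100, seed = 9))
  # within-chromosome confinement: no admissible stretch is an error
  expect_error(sample_null_stretches(p, rep(c("chr1", "chr2"), 5), N = 6,
                                     B = 5, seed = 1), "consecutive")
})

test_that("gene test recovers the boundary conventions", {
  mf <- tiny_manifest()
  dmp <- data.frame(probe_id = mf$probe_id, p = rep(1, 10),
                    stringsAsFactors = FALSE)
  res <- gene_test("A", dmp, mf, B = 200, seed = 3)
  expect_equal(res$x_obs, 0)
  expect_equal(res$p_empirical, 1)

  # all-null-below boundary: empirical p hits the add-one floor 1/(B+1)
  dmp2 <- dmp
  dmp2$p[match(c("cg005", "cg006"), dmp2$probe_id)] <- 1e-10  # gene B on chr2
  dmp2$p[dmp2$p == 1] <- 0.9
  res2 <- gene_test("B", dmp2, mf, B = 100, seed = 3)
  expect_equal(res2$exceed_count, 0)
  expect_equal(res2$p_empirical, 1 / 101)

  # analytic p is the chi-square upper tail at 2N degrees of freedom
  expect_equal(res2$p_analytic,
               pchisq(res2$x_obs, df = 2 * res2$n_probes, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(gene_test("NOPE", dmp, mf), "absent")
})

test_that("gene-set testing is order-invariant and reports unknown genes", {
  coh <- small_cohort(n_probes = 1500, seed = 61)
  dmp <- fit_probe_models(beta_to_m(coh$beta), coh$sheet, "PSC_UC_vs_UC")
  genes <- head(names(coh$genes), 8)
  r1 <- test_gene_set(genes, dmp, coh$manifest, B = 300, seed = 7)
  r2 <- test_gene_set(rev(genes), dmp, coh$manifest, B = 300, seed = 7)
  expect_equal(r1$p_empirical,
               r2$p_empirical[match(r1$gene_symbol, r2$gene_symbol)])

  one <- test_gene_set(genes[1], dmp, coh$manifest, B = 300, seed = 7)
  expect_equal(one$adj_p, one$p_empirical)

  expect_warning(bad <- test_gene_set(c(genes[1], "MISSING"), dmp,
                                      coh$manifest, B = 100, seed = 7),
                 "MISSING")
  expect_true(is.na(bad$p_empirical[bad$gene_symbol == "MISSING"]))
  expect_false(is.na(bad$p_empirical[1]))
})

test_that("null cohorts reject about 5% of genes at alpha = 0.05", {
  coh <- small_cohort(n_probes = 2500, seed = 67, clock_probe_count = 0)
  dmp <- fit_probe_models(beta_to_m(coh$beta), coh$sheet, "PSC_UC_vs_UC")
  genes <- head(names(coh$genes), 200)
  gt <- test_gene_set(genes, dmp, coh$manifest, B = 1000, seed = 11)
  n_sig <- sum(gt$p_empirical < 0.05)
  expect_gte(n_sig, 4)     # binomial(200, 0.05) central 95% interval
  expect_lte(n_sig, 17)
})

test_that("rejection rate grows with the injected effect size", {
  rate_at <- function(delta) {
    genes <- sprintf("G%05d", 1:60)
    eff <- if (delta > 0) {
      lapply(genes, function(g) list(gene = g, delta = delta, group = "PSC_UC"))
    } else list()
    coh <- small_cohort(n_probes = 3000, seed = 71, clock_probe_count = 0,
                        injected_effects = eff)
    dmp <- fit_probe_models(beta_to_m(coh$beta), coh$sheet, "PSC_UC_vs_UC")
    gt <- test_gene_set(genes, dmp, coh$manifest, B = 500, seed = 13)
    mean(gt$p_empirical < 0.05)
  }
  rates <- vapply(c(0, 0.5, 1.0), rate_at, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.8)
})
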