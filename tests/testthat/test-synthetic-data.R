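test_that("generated manifest has ordered positions, contiguous genes, flags", {
  cfg <- simulation_config(n_probes = 500, n_chromosomes = 3, seed = 2)
  mf <- generate_manifest(cfg)
  expect_equal(nrow(mf$manifest), 500)
  for (ch in unique(mf$manifest$chromosome)) {
    pos <- mf$manifest$position[mf$manifest$chromosome == ch]
    expect_true(all(diff(pos) > 0))
  }
  # every gene's probes are consecutive rows on one chromosome
  for (g in names(mf$genes)) {
    idx <- match(mf$genes[[g]], mf$manifest$probe_id)
    expect_equal(idx, seq(min(idx), max(idx)))
    expect_length(unique(mf$manifest$chromosome[idx]), 1)
  }
  sizes <- lengths(mf$genes)
  expect_true(all(sizes >= 1 & sizes <= cfg$gene_block_size_range[2]))
  expect_true(all(mf$manifest$allosomal == (mf$manifest$chromosome == "chrX")))

  expect_identical(generate_manifest(cfg), mf)  # same seed, same manifest
  expect_error(generate_manifest(simulation_config(n_probes = 3,
                                                   gene_block_size_range = c(5, 8))),
               "smaller")
})

test_that("cell-type reference separates types only at discriminating probes", {
  cfg <- simulation_config(n_probes = 400, seed = 3)
  mf <- generate_manifest(cfg)
  ref <- generate_reference(mf$manifest, 4, seed = 3, n_discriminating = 50)
  expect_true(all(ref$means > 0 & ref$means < 1))
  disc <- ref$means[ref$discriminating, ]
  expect_true(all(apply(disc, 1, max) - apply(disc, 1, min) > 0.7))
  other <- ref$means[setdiff(rownames(ref$means), ref$discriminating), ]
  expect_true(all(apply(other, 1, function(r) diff(range(r))) == 0))
})

test_that("cohort generation honours the zero-noise identity and range", {
  cfg <- simulation_config(n_probes = 300, noise_sd = 0, spatial_sd = 0,
                           clock_probe_count = 0,
                           fixed_fractions = c(0.3, 0.2, 0.1, 0.15, 0.05, 0.2),
                           group_sizes = c(PSC_UC = 3, UC = 3), seed = 5)
  mf <- generate_manifest(cfg)
  ref <- generate_reference(mf$manifest, 6, seed = 5, n_discriminating = 40)
  coh <- generate_cohort(mf$manifest, ref, cfg)
  mixed <- drop(ref$means %*% c(0.3, 0.2, 0.1, 0.15, 0.05, 0.2))
  for (j in seq_len(ncol(coh$beta))) {
    expect_equal(unname(coh$beta[, j]), unname(mixed), tolerance = 1e-12)
  }

  coh2 <- generate_cohort(mf$manifest, ref, cfg)
  expect_identical(coh$beta, coh2$beta)  # determinism

  full <- small_cohort(n_probes = 800, seed = 5)
  expect_true(all(full$beta > 0 & full$beta < 1))
  expect_equal(colSums(full$truth$cell_fractions),
               setNames(rep(1, ncol(full$beta)), colnames(full$beta)),
               tolerance = 1e-12)
})

test_that("injected logit shift raises the affected group's mean beta", {
  inj <- sprintf("cg%08d", 101:150)
  coh <- small_cohort(n_probes = 2000, seed = 11,
                      injected_effects = list(list(probes = inj, delta = 1.0,
                                                   group = "PSC_UC")))
  g1 <- coh$sheet$group == "PSC_UC"
  g2 <- coh$sheet$group == "UC"
  diff_inj <- rowMeans(coh$beta[inj, g1]) - rowMeans(coh$beta[inj, g2])
  expect_gt(mean(diff_inj > 0), 0.95)
  expect_gt(median(diff_inj), 0.1)
})

test_that("spatial field produces positive lag-1 logit correlation, none when off", {
  corr_at <- function(spatial_sd) {
    coh <- small_cohort(n_probes = 1500, seed = 13, spatial_sd = spatial_sd,
                        clock_probe_count = 0)
    l <- qlogis(coh$beta)
    resid <- l - rowMeans(l)          # remove per-probe baseline
    same_chrom <- coh$manifest$chromosome[-1] ==
      coh$manifest$chromosome[-nrow(coh$manifest)]
    a <- resid[-1, ][same_chrom, ]
    b <- resid[-nrow(resid), ][same_chrom, ]
    cor(as.vector(a), as.vector(b))
  }
  expect_gt(corr_at(0.2), 0.3)
  expect_lt(abs(corr_at(0)), 0.05)
})

test_that("null cohort group labels are exchangeable (uniform p-values)", {
  coh <- small_cohort(n_probes = 4000, seed = 17, spatial_sd = 0,
                      clock_probe_count = 0)
  dmp <- fit_probe_models(beta_to_m(coh$beta), coh$sheet, "PSC_UC_vs_UC",
                          moderate = FALSE)
  ks <- ks.test(dmp$p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(dmp$p < 0.05) - 0.05), 0.015)
})

test_that("synthetic clock is self-consistent and deterministic", {
  cfg <- simulation_config(n_probes = 600, noise_sd = 0, spatial_sd = 0,
                           seed = 19)
  mf <- generate_manifest(cfg)
  ref <- generate_reference(mf$manifest, 6, seed = 19, n_discriminating = 60)
  clock <- make_clock(mf$manifest, cfg)
  expect_identical(make_clock(mf$manifest, cfg), clock)

  coh <- generate_cohort(mf$manifest, ref, cfg, clock)
  res <- predict_age(coh$beta, clock, coh$sheet)
  expect_lt(max(abs(res$ages$acceleration)), 1e-6)

  # all-zero coefficients predict a constant age for every sample
  flat <- clock
  flat$coefficients[] <- 0
  flat$intercept <- age_transform(33, flat$adult_age)
  res0 <- predict_age(coh$beta, flat)
  expect_equal(unname(res0$ages$predicted_age),
               rep(33, ncol(coh$beta)), tolerance = 1e-9)
})
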