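test_that("discriminating-probe selection picks only informative probes", {
  probes <- sprintf("p%02d", 1:30)
  means <- matrix(0.5, 30, 2, dimnames = list(probes, c("T1", "T2")))
  means[1:10, "T1"] <- c(rep(0.9, 5), rep(0.1, 5))  # only these differ
  ref <- list(cell_types = c("T1", "T2"), means = means)
  sel <- select_discriminating_probes(ref, n_per_type = 5)
  expect_true(all(sel %in% probes[1:10]))
  expect_identical(select_discriminating_probes(ref, 5), sel)  # deterministic

  flat <- list(cell_types = c("T1", "T2"),
               means = matrix(0.5, 30, 2, dimnames = list(probes, c("T1", "T2"))))
  expect_warning(empty <- select_discriminating_probes(flat, 5),
                 "indistinguishable")
  expect_length(empty, 0)
})

test_that("noiseless mixtures are recovered exactly", {
  coh <- small_cohort(n_probes = 400, seed = 73)
  ref <- coh$reference
  w_true <- c(0.3, 0, 0, 0.7, 0, 0)
  sample_beta <- matrix(ref$means %*% w_true, ncol = 1,
                        dimnames = list(rownames(ref$means), "mix"))
  est <- estimate_fractions(sample_beta, ref)
  w_hat <- as.numeric(est[1, ref$cell_types])
  expect_equal(w_hat, w_true, tolerance = 1e-6)
  expect_lt(est$residual[1], 1e-6)

  # a pure reference column yields the indicator vector
  pure <- matrix(ref$means[, "NK"], ncol = 1,
                 dimnames = list(rownames(ref$means), "pureNK"))
  est_pure <- estimate_fractions(pure, ref)
  expect_equal(as.numeric(est_pure[1, ref$cell_types]),
               as.numeric(ref$cell_types == "NK"), tolerance = 1e-6)

  # optimality certificate: achieved objective no worse than at the truth
  obj <- function(w, b) sum((b - ref$means[ref$discriminating, ] %*% w)^2)
  b <- sample_beta[ref$discriminating, 1]
  expect_lte(obj(w_hat, b), obj(w_true, b) + 1e-8)
})

test_that("estimates respect the simplex constraints and orderings", {
  coh <- small_cohort(n_probes = 600, seed = 79, noise_sd = 0.05)
  est <- estimate_fractions(coh$beta, coh$reference)
  fr <- as.matrix(est[, coh$reference$cell_types])
  expect_true(all(fr >= 0))
  expect_true(all(rowSums(fr) <= 1 + 1e-9))

  # invariance to cell-type and probe order
  ref_perm <- coh$reference
  perm <- c(3, 1, 6, 2, 5, 4)
  ref_perm$means <- ref_perm$means[, perm]
  ref_perm$cell_types <- ref_perm$cell_types[perm]
  est2 <- estimate_fractions(coh$beta, ref_perm)
  expect_equal(as.matrix(est2[, coh$reference$cell_types]), fr,
               tolerance = 1e-7)
  probe_perm <- sample(nrow(coh$beta))
  ref_p <- coh$reference
  ref_p$means <- ref_p$means[probe_perm, ]
  est3 <- estimate_fractions(coh$beta[probe_perm, ], ref_p)
  expect_equal(as.matrix(est3[, coh$reference$cell_types]), fr,
               tolerance = 1e-7)

  # renormalization returns exact unit sums
  est4 <- estimate_fractions(coh$beta, coh$reference, renormalize = TRUE)
  expect_equal(rowSums(as.matrix(est4[, coh$reference$cell_types])),
               rep(1, nrow(est4)), tolerance = 1e-12)
})

test_that("recovery error shrinks monotonically with the noise level", {
  mae_at <- function(sd) {
    coh <- small_cohort(n_probes = 1200, seed = 83, noise_sd = sd,
                        spatial_sd = 0, clock_probe_count = 0)
    est <- estimate_fractions(coh$beta, coh$reference)
    mean(abs(as.matrix(est[, coh$reference$cell_types]) -
               t(coh$truth$cell_fractions)))
  }
  errs <- vapply(c(0.1, 0.03, 0.01, 0), mae_at, 0)
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 1e-6)
})

test_that("two-way ANOVA F matches hand-computed sums of squares", {
  # balanced 2 groups x 2 cell types, 3 replicates per cell
  fr <- c(0.10, 0.12, 0.14, 0.30, 0.32, 0.34,   # grp1: typeA, typeB
          0.20, 0.22, 0.24, 0.28, 0.30, 0.32)   # grp2: typeA, typeB
  deconv <- data.frame(
    sample_id = sprintf("s%02d", 1:6),
    A = c(fr[1:3], fr[7:9]), B = c(fr[4:6], fr[10:12]),
    residual = 0, stringsAsFactors = FALSE)
  class(deconv) <- c("deconv_result", "data.frame")
  sheet <- data.frame(sample_id = deconv$sample_id,
                      group = rep(c("PSC_UC", "UC"), each = 3),
                      stringsAsFactors = FALSE)
  res <- compare_fractions(deconv, sheet)

  # hand-worked two-way ANOVA with interaction on the balanced table
  y <- c(deconv$A, deconv$B)
  g <- rep(rep(c("g1", "g2"), each = 3), 2)
  ct <- rep(c("A", "B"), each = 6)
  gm <- mean(y)
  ss_g <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_t <- sum(tapply(y, ct, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, interaction(g, ct), mean)
  ss_cells <- 3 * sum((cell_means - gm)^2)
  ss_int <- ss_cells - ss_g - ss_t
  ss_err <- sum((y - ave(y, interaction(g, ct)))^2)
  f_g <- (ss_g / 1) / (ss_err / 8)
  f_t <- (ss_t / 1) / (ss_err / 8)
  f_int <- (ss_int / 1) / (ss_err / 8)

  tab <- res$anova_interaction
  expect_equal(tab["group", "F value"], f_g, tolerance = 1e-9)
  expect_equal(tab["cell_type", "F value"], f_t, tolerance = 1e-9)
  expect_equal(tab["group:cell_type", "F value"], f_int, tolerance = 1e-9)

  # degenerate: identical fractions everywhere -> missing p-values, a note
  flat <- deconv
  flat$A <- 0.4; flat$B <- 0.6
  res_flat <- compare_fractions(flat, sheet)
  expect_null(res_flat$anova_interaction)
  expect_match(res_flat$note, "identical")
  expect_true(all(is.na(res_flat$per_type$p)))
})

test_that("lowered NK abundance in patients is detected on a preset cohort", {
  coh <- small_cohort(n_probes = 2000, seed = 89, noise_sd = 0.03,
                      group_alpha = blood_preset_alphas())
  est <- estimate_fractions(coh$beta, coh$reference)
  res <- compare_fractions(est, coh$sheet)
  nk <- res$per_type[res$per_type$cell_type == "NK", ]
  expect_lt(nk$p, 0.05)
  # direction: NK lower in patients than HC
  grp <- coh$sheet$group[match(est$sample_id, coh$sheet$sample_id)]
  expect_lt(mean(est$NK[grp != "HC"]), mean(est$NK[grp == "HC"]))
})
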