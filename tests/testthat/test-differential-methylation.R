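test_that("unmoderated per-probe t equals the pooled two-sample t closed form", {
  set.seed(31)
  y <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("p%02d", 1:20), sprintf("s%d", 1:6)))
  sheet <- data.frame(sample_id = colnames(y),
                      group = rep(c("PSC_UC", "UC"), each = 3),
                      age = 40, stringsAsFactors = FALSE)
  dmp <- fit_probe_models(y, sheet, "PSC_UC_vs_UC", covariates = character(0),
                          moderate = FALSE)
  for (i in seq_len(nrow(y))) {
    tt <- t.test(y[i, 1:3], y[i, 4:6], var.equal = TRUE)
    expect_equal(dmp$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(dmp$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(dmp$effect[i], mean(y[i, 1:3]) - mean(y[i, 4:6]),
                 tolerance = 1e-12)
  }
})

test_that("coefficients agree with an independent linear-model fit", {
  coh <- small_cohort(n_probes = 300, seed = 37)
  m <- beta_to_m(coh$beta)
  dmp <- fit_probe_models(m, coh$sheet, "PSC_UC_vs_HC", moderate = FALSE)
  # cross-check: limma's least-squares fit with the same design and contrast
  grp <- factor(coh$sheet$group, levels = c("HC", "UC", "PSC_UC"))
  design <- model.matrix(~ grp + age + steroids, data = coh$sheet)
  fit <- limma::lmFit(m, design)
  expect_equal(unname(dmp$effect), unname(fit$coefficients[, "grpPSC_UC"]),
               tolerance = 1e-9)
})

test_that("degenerate and missing responses are handled per probe", {
  coh <- small_cohort(n_probes = 200, seed = 41)
  m <- beta_to_m(coh$beta)
  m["cg00000010", ] <- 3                      # constant probe
  m["cg00000020", c(1, 5)] <- NA              # partial missingness
  dmp <- fit_probe_models(m, coh$sheet, "PSC_UC_vs_UC")
  r10 <- dmp[dmp$probe_id == "cg00000010", ]
  expect_equal(r10$effect, 0)
  expect_true(is.na(r10$p))

  # complete-case per probe: matches a direct lm on the reduced samples
  obs <- !is.na(m["cg00000020", ])
  grp <- factor(coh$sheet$group[obs], levels = c("HC", "UC", "PSC_UC"))
  cfit <- lm(m["cg00000020", obs] ~ grp + age + steroids,
             data = coh$sheet[obs, ])
  r20 <- dmp[dmp$probe_id == "cg00000020", ]
  expect_equal(r20$effect,
               unname(coef(cfit)["grpPSC_UC"] - coef(cfit)["grpUC"]),
               tolerance = 1e-9)
})

test_that("location shifts move the intercept, not the contrast", {
  coh <- small_cohort(n_probes = 100, seed = 43)
  m <- beta_to_m(coh$beta)
  dmp1 <- fit_probe_models(m, coh$sheet, "PSC_UC_vs_UC")
  dmp2 <- fit_probe_models(m + 5, coh$sheet, "PSC_UC_vs_UC")
  expect_equal(dmp1$effect, dmp2$effect, tolerance = 1e-9)
  expect_equal(dmp1$t, dmp2$t, tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear column named", {
  coh <- small_cohort(n_probes = 50, seed = 47)
  sheet <- coh$sheet
  sheet$dup_age <- sheet$age
  expect_error(fit_probe_models(beta_to_m(coh$beta), sheet, "PSC_UC_vs_UC",
                                covariates = c("age", "dup_age")),
               "collinear.*dup_age")
})

test_that("BH adjustment matches the step-up definition", {
  # brute-force step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, p[ord[i]] * m / i)
      adj[ord[i]] <- prev
    }
    pmin(adj, 1)
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
  set.seed(53)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("injected effects are recovered with the right sign, nulls stay flat", {
  inj <- sprintf("cg%08d", seq(10, 500, 10))
  coh <- small_cohort(n_probes = 4000, seed = 59, clock_probe_count = 0,
                      group_sizes = c(PSC_UC = 17, UC = 17),
                      injected_effects = list(list(probes = inj, delta = 1.0,
                                                   group = "PSC_UC")))
  dmp <- fit_probe_models(beta_to_m(coh$beta), coh$sheet, "PSC_UC_vs_UC",
                          beta = coh$beta)
  inj_rows <- dmp$probe_id %in% inj
  expect_gt(median(dmp$effect[inj_rows]), 0)
  expect_true(all(dmp$direction[inj_rows & dmp$effect > 0.5] == "hyper"))
  null_p <- dmp$p[!inj_rows]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.02)
  # adjusted p never drops below raw p
  expect_true(all(dmp$adj_p >= dmp$p - 1e-12, na.rm = TRUE))
})

test_that("top_table sorts by p with documented deterministic tie-breaks", {
  dmp <- data.frame(probe_id = c("cgB", "cgA", "cgC", "cgD"),
                    effect = c(1, -2, 3, 1), se = 1,
                    t = c(1.0, -2.0, 3.0, 0.5), df = 10,
                    p = c(0.02, 0.02, 0.001, NA),
                    adj_p = NA, direction = "hyper", stringsAsFactors = FALSE)
  top <- top_table(dmp, 10)             # n larger than the table: clamped
  expect_equal(top$probe_id, c("cgC", "cgA", "cgB", "cgD"))
  expect_equal(top_table(dmp, 2)$probe_id, c("cgC", "cgA"))
  # p tie broken by |t| descending, then probe_id
  tie <- dmp
  tie$t <- c(1, 1, 3, 0.5)
  expect_equal(top_table(tie, 3)$probe_id, c("cgC", "cgA", "cgB"))
})
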