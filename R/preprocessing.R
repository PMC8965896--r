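#' Filter array probes by manifest exclusion flags
#'
#' Removes probes flagged as SNP-associated or cross-reactive (both dropped
#' by default, the standard array-QC practice). Allosomal probes are kept by
#' default — appropriate for a single-sex cohort, where sex-chromosome probes
#' do not confound group comparisons — and can be dropped with
#' `drop_allosomal = TRUE`. Genome order is preserved and the operation is
#' idempotent.
#'
#' @param manifest probe manifest (data.frame).
#' @param beta beta matrix (probes x samples); rows must be a subset of the
#'   manifest probes.
#' @param drop_snp,drop_cross_reactive,drop_allosomal filter toggles.
#' @return list with the filtered `manifest` and `beta`.
#' @export
filter_probes <- function(manifest, beta, drop_snp = TRUE,
                          drop_cross_reactive = TRUE, drop_allosomal = FALSE) {
  if (!all(rownames(beta) %in% manifest$probe_id)) {
    stop_input("beta matrix contains probes absent from the manifest")
  }
  keep <- rep(TRUE, nrow(manifest))
  if (drop_snp) keep <- keep & !manifest$snp_associated
  if (drop_cross_reactive) keep <- keep & !manifest$cross_reactive
  if (drop_allosomal) keep <- keep & !manifest$allosomal
  if (!any(keep)) {
    stop_input("no probes survive filtering; review the drop_* toggles")
  }
  manifest <- manifest[keep, , drop = FALSE]
  rownames(manifest) <- NULL
  beta <- beta[intersect(manifest$probe_id, rownames(beta)), , drop = FALSE]
  list(manifest = manifest, beta = beta)
}

#' Quantile-normalize a beta matrix across samples
#'
#' Replaces each sample's values so that every sample shares the same
#' empirical distribution — the mean of the per-rank order statistics across
#' samples — while preserving each sample's within-sample rank order. Missing
#' values are rejected: normalize before any masking, or impute explicitly.
#'
#' @param beta beta matrix (probes x samples), no missing values.
#' @return the normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(beta) {
  if (anyNA(beta)) {
    stop_input("quantile_normalize requires a complete matrix (missing values present)")
  }
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}

#' Beta-value to M-value transform (and inverse)
#'
#' M = log2((beta + eps) / (1 - beta + eps)). The offset `epsilon` keeps the
#' transform finite at beta = 0 and 1; M-values stabilize the variance of
#' methylation fractions and are the default modelling scale of the
#' differential stage.
#'
#' @param beta beta values in \[0,1\] (vector or matrix).
#' @param epsilon offset in (0, 0.5).
#' @return M-values (same shape).
#' @export
beta_to_m <- function(beta, epsilon = 0.01) {
  stopifnot(epsilon > 0, epsilon < 0.5)
  log2((beta + epsilon) / (1 - beta + epsilon))
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m, epsilon = 0.01) {
  x <- 2^m
  (x + epsilon * (x - 1)) / (1 + x)
}

#' PCA-based sample quality control
#'
#' Principal components are computed on probe-centered data over samples
#' (zero-variance probes are dropped internally). A sample is flagged as an
#' outlier when its score on any of the first `k` components exceeds
#' `outlier_sd` standard deviations of that component's scores. Flagging is
#' reported, never applied: dropping a sample is a destructive act that must
#' be the caller's explicit choice. When a sample sheet is supplied, each
#' component's association with the group labels is tested per group pair by
#' the two-sample rank-sum (Wilcoxon) test.
#'
#' @param beta beta matrix (probes x samples); at least 3 samples.
#' @param k number of leading components to screen (default 2).
#' @param outlier_sd flagging threshold in component-score SD units.
#' @param sheet optional sample sheet with `sample_id` and `group`.
#' @return a `pca_qc` list: `scores` (samples x k), `explained` (variance
#'   fractions for all components), `outliers` (flagged sample ids),
#'   `group_assoc` (data.frame of per-component pairwise p-values or NULL).
#' @export
pca_qc <- function(beta, k = 2, outlier_sd = 3, sheet = NULL) {
  if (ncol(beta) < 3) stop_input("pca_qc requires at least 3 samples")
  v <- row_vars(beta)
  x <- beta[!is.na(v) & v > 0, , drop = FALSE]
  n <- ncol(beta)
  if (nrow(x) == 0) {
    # all probes constant: degenerate but well-defined result
    return(structure(list(
      scores = matrix(0, n, k, dimnames = list(colnames(beta), paste0("PC", seq_len(k)))),
      explained = numeric(0), outliers = character(0), group_assoc = NULL),
      class = "pca_qc"))
  }
  xc <- x - rowMeans(x)              # probe-centered
  sv <- svd(t(xc))                   # samples x probes
  explained <- sv$d^2 / sum(sv$d^2)
  k_eff <- min(k, length(sv$d))
  scores <- sv$u[, seq_len(k_eff), drop = FALSE] *
    rep(sv$d[seq_len(k_eff)], each = n)
  dimnames(scores) <- list(colnames(beta), paste0("PC", seq_len(k_eff)))

  flagged <- rep(FALSE, n)
  for (j in seq_len(k_eff)) {
    s <- sd(scores[, j])
    if (s > 0) flagged <- flagged | abs(scores[, j]) > outlier_sd * s
  }

  group_assoc <- NULL
  if (!is.null(sheet)) {
    sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
    pairs <- utils::combn(sort(unique(sheet$group)), 2, simplify = FALSE)
    rows <- list()
    for (j in seq_len(k_eff)) {
      for (pr in pairs) {
        a <- scores[sheet$group == pr[1], j]
        b <- scores[sheet$group == pr[2], j]
        p <- tryCatch(wilcox.test(a, b, exact = FALSE)$p.value,
                      error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          component = paste0("PC", j), group1 = pr[1], group2 = pr[2],
          p = p, stringsAsFactors = FALSE)
      }
    }
    group_assoc <- do.call(rbind, rows)
  }

  structure(list(scores = scores, explained = explained,
                 outliers = colnames(beta)[flagged], group_assoc = group_assoc),
            class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("PCA sample QC:", nrow(x$scores), "samples,",
      ncol(x$scores), "components screened\n")
  if (length(x$explained) > 0) {
    cat("Explained variance (leading):",
        paste(sprintf("%.1f%%", 100 * head(x$explained, ncol(x$scores))),
              collapse = ", "), "\n")
  }
  if (length(x$outliers) > 0) {
    cat("Flagged outliers:", paste(x$outliers, collapse = ", "), "\n")
  } else cat("No outliers flagged\n")
  invisible(x)
}
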