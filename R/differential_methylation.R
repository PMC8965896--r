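#' Per-probe differential-methylation linear models
#'
#' Fits, for every probe, an ordinary-least-squares model of the response
#' (M-values by default; beta values optional) on an intercept, the named
#' covariates and the cohort group factor, then tests one of the two group
#' contrasts of interest: PSC-UC vs UC or PSC-UC vs HC. The design mirrors
#' `methylation ~ age + steroids + group`. Per-probe residual variances are
#' optionally shrunk toward their pooled mean by a fixed-prior empirical-Bayes
#' rule (prior weight `d0` extra degrees of freedom) before the t-statistic —
#' a moderated-t in the spirit of the standard EWAS machinery with an
#' explicit, fixed prior; `moderate = FALSE` gives the exact OLS t.
#'
#' Samples with a missing response at a probe are dropped for that probe only
#' (complete-case per probe). Probes with zero variance across samples yield
#' a degenerate row (effect 0, p missing) rather than failure.
#'
#' @param response probes x samples matrix of M-values (or beta values).
#' @param sheet sample sheet with `sample_id`, `group` and the covariates.
#' @param contrast `"PSC_UC_vs_UC"` or `"PSC_UC_vs_HC"`.
#' @param covariates character vector of sheet columns to adjust for.
#' @param moderate apply the fixed-prior variance moderation (default TRUE).
#' @param d0 prior degrees of freedom of the moderation (default 4).
#' @param beta optional beta matrix (same dimnames) used to report the
#'   beta-scale group-mean difference `delta_beta` alongside the
#'   response-scale effect, and to label direction as hyper/hypomethylation
#'   of PSC-UC relative to the comparator.
#' @return a `DmpTable` data.frame: `probe_id`, `effect`, `se`, `t`, `df`,
#'   `p`, `adj_p` (BH), `direction`, and `delta_beta` when `beta` is given.
#' @export
fit_probe_models <- function(response, sheet,
                             contrast = c("PSC_UC_vs_UC", "PSC_UC_vs_HC"),
                             covariates = c("age", "steroids"),
                             moderate = TRUE, d0 = 4, beta = NULL) {
  contrast <- match.arg(contrast)
  comparator <- if (contrast == "PSC_UC_vs_UC") "UC" else "HC"
  sheet <- sheet[match(colnames(response), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) {
    stop_input("response columns and sample sheet do not align")
  }
  for (grp in c("PSC_UC", comparator)) {
    if (!grp %in% sheet$group) {
      stop_input("contrast %s requires group %s in the sheet", contrast, grp)
    }
  }

  present <- intersect(c("HC", "UC", "PSC_UC"), unique(sheet$group))
  grp <- factor(sheet$group, levels = present)
  X <- stats::model.matrix(~grp)
  colnames(X) <- sub("^grp", "group_", colnames(X))
  for (cv in covariates) {
    if (!cv %in% names(sheet)) stop_input("covariate '%s' not in sample sheet", cv)
    X <- cbind(X, as.numeric(sheet[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("design matrix is rank-deficient; collinear column(s): %s",
               paste(dropped, collapse = ", "))
  }

  cvec <- setNames(numeric(ncol(X)), colnames(X))
  cvec[paste0("group_", "PSC_UC")] <- 1
  if (comparator != present[1]) cvec[paste0("group_", comparator)] <- -1
  # (when the comparator is the factor reference level, the PSC_UC indicator
  #  alone is the PSC_UC - comparator contrast)

  n <- ncol(response)
  p_rank <- ncol(X)
  complete <- !anyNA(response)
  XtXi <- solve(crossprod(X))
  hat <- X %*% XtXi                      # n x p
  cXc <- drop(t(cvec) %*% XtXi %*% cvec)

  n_probes <- nrow(response)
  effect <- se2 <- numeric(n_probes)
  dfree <- rep(n - p_rank, n_probes)
  cxc_vec <- rep(cXc, n_probes)

  if (complete) {
    B <- response %*% hat                # probes x p coefficients
    fitted <- B %*% t(X)
    rss <- rowSums((response - fitted)^2)
    effect <- drop(B %*% cvec)
    s2 <- rss / (n - p_rank)
  } else {
    ok_rows <- !apply(is.na(response), 1, any)
    B <- matrix(NA_real_, n_probes, p_rank)
    s2 <- rep(NA_real_, n_probes)
    if (any(ok_rows)) {
      Bc <- response[ok_rows, , drop = FALSE] %*% hat
      fitted <- Bc %*% t(X)
      rss <- rowSums((response[ok_rows, , drop = FALSE] - fitted)^2)
      B[ok_rows, ] <- Bc
      s2[ok_rows] <- rss / (n - p_rank)
    }
    for (i in which(!ok_rows)) {          # complete-case per probe
      obs <- !is.na(response[i, ])
      Xi <- X[obs, , drop = FALSE]
      qri <- qr(Xi)
      if (qri$rank < p_rank || sum(obs) <= p_rank) next  # leaves NA
      XtXii <- chol2inv(qr.R(qri))
      bi <- qr.coef(qri, response[i, obs])
      ri <- response[i, obs] - drop(Xi %*% bi)
      B[i, ] <- bi
      s2[i] <- sum(ri^2) / (sum(obs) - p_rank)
      dfree[i] <- sum(obs) - p_rank
      cxc_vec[i] <- drop(t(cvec) %*% XtXii %*% cvec)
    }
    effect <- drop(B %*% cvec)
  }

  # zero-variance probes: defined degenerate row
  zero_var <- !is.na(s2) & s2 <= .Machine$double.eps * 100
  constant <- row_vars(response) == 0
  constant[is.na(constant)] <- FALSE

  if (moderate) {
    s2_ok <- s2[!is.na(s2) & !zero_var]
    s2_prior <- if (length(s2_ok) > 0) mean(s2_ok) else NA_real_
    s2_post <- (d0 * s2_prior + dfree * s2) / (d0 + dfree)
    df_post <- dfree + d0
  } else {
    s2_post <- s2
    df_post <- dfree
  }
  se <- sqrt(s2_post * cxc_vec)
  tstat <- effect / se
  pval <- 2 * pt(-abs(tstat), df_post)

  effect[constant] <- 0
  se[constant] <- NA_real_
  tstat[constant] <- NA_real_
  pval[constant] <- NA_real_

  out <- data.frame(probe_id = rownames(response), effect = effect, se = se,
                    t = tstat, df = df_post, p = pval,
                    stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p)

  dir_basis <- out$effect
  if (!is.null(beta)) {
    beta <- beta[rownames(response), colnames(response), drop = FALSE]
    g1 <- sheet$group == "PSC_UC"
    g2 <- sheet$group == comparator
    out$delta_beta <- rowMeans(beta[, g1, drop = FALSE], na.rm = TRUE) -
      rowMeans(beta[, g2, drop = FALSE], na.rm = TRUE)
    dir_basis <- out$delta_beta
  }
  out$direction <- ifelse(is.na(out$p), NA_character_,
                          ifelse(dir_basis > 0, "hyper", "hypo"))
  attr(out, "contrast") <- contrast
  attr(out, "moderated") <- moderate
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are capped at 1 with monotonicity enforced from the
#' largest rank downward; input order is preserved. Missing entries are
#' excluded from the adjustment and returned missing.
#'
#' @param p numeric vector of p-values in \[0,1\] (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_input("p-values must lie in [0,1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Extract the top differentially methylated positions
#'
#' Rows are sorted by ascending raw p-value; ties are broken by descending
#' |t| and then probe id, so the ordering is deterministic. Rows with missing
#' p sort last.
#'
#' @param dmp a DmpTable from [fit_probe_models()].
#' @param n number of rows to return (clamped to the table size).
#' @return the first `n` rows in the documented order.
#' @export
top_table <- function(dmp, n = 10) {
  stopifnot(n >= 1)
  ord <- order(dmp$p, -abs(dmp$t), dmp$probe_id, na.last = TRUE)
  out <- dmp[ord, , drop = FALSE][seq_len(min(n, nrow(dmp))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
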