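#' Select cell-type-discriminating probes from a reference
#'
#' For each cell type, ranks probes by the margin between that type's mean
#' beta and the mean of all other types, and takes the `n_per_type` probes
#' with the largest positive and the largest negative margins; the union over
#' types is returned. Probes with zero margin everywhere (types
#' indistinguishable) are never informative; if no probe has a non-zero
#' margin a warning is issued and an empty set returned.
#'
#' @param reference cell-type reference (list with `means`, probes x types).
#' @param n_per_type probes to take per direction per cell type.
#' @return character vector of probe ids (sorted, deduplicated).
#' @export
select_discriminating_probes <- function(reference, n_per_type = 50) {
  stopifnot(n_per_type >= 1)
  means <- reference$means
  K <- ncol(means)
  stopifnot(K >= 2)
  selected <- character(0)
  any_margin <- FALSE
  for (k in seq_len(K)) {
    margin <- means[, k] - rowMeans(means[, -k, drop = FALSE])
    nonzero <- which(margin != 0)
    if (length(nonzero) == 0) next
    any_margin <- TRUE
    pos <- nonzero[order(margin[nonzero], decreasing = TRUE)]
    neg <- nonzero[order(margin[nonzero])]
    take_pos <- head(pos[margin[pos] > 0], n_per_type)
    take_neg <- head(neg[margin[neg] < 0], n_per_type)
    if (length(take_pos) < n_per_type || length(take_neg) < n_per_type) {
      warning(sprintf("cell type %s: fewer candidate probes than requested",
                      colnames(means)[k]))
    }
    selected <- c(selected, rownames(means)[c(take_pos, take_neg)])
  }
  if (!any_margin) {
    warning("reference cell types are indistinguishable; no discriminating probes")
    return(character(0))
  }
  sort(unique(selected))
}

#' Estimate cell-type fractions by constrained projection
#'
#' For each sample, minimizes the sum of squared differences between the
#' sample's beta values and the reference-profile combination over the
#' discriminating probes, subject to non-negative weights summing to at most
#' 1 — the standard constrained quadratic program of reference-based blood
#' deconvolution. Leaving the sum free below 1 keeps the problem feasible
#' for samples containing cell populations absent from the reference; the
#' unexplained mass is visible as 1 - sum(fractions). `renormalize = TRUE`
#' rescales each sample's fractions to sum to exactly 1 on output.
#'
#' @param beta beta matrix (probes x samples).
#' @param reference cell-type reference (list with `means` and optionally
#'   `discriminating`).
#' @param probes probe ids to project on; defaults to the reference's
#'   discriminating set, else all shared probes.
#' @param renormalize rescale fractions to sum to 1.
#' @return a `deconv_result` data.frame: `sample_id`, one fraction column
#'   per cell type, and `residual` (the residual norm of the projection).
#' @export
estimate_fractions <- function(beta, reference, probes = NULL,
                               renormalize = FALSE) {
  means <- reference$means
  if (is.null(probes)) {
    probes <- reference$discriminating %||% rownames(means)
  }
  probes <- intersect(probes, rownames(beta))
  if (length(probes) == 0) {
    stop_input("none of the discriminating probes are present in the beta matrix")
  }
  A <- means[probes, , drop = FALSE]
  K <- ncol(A)
  if (qr(A)$rank < K) {
    stop_input("reference is rank-deficient over the selected probes")
  }
  Dmat <- crossprod(A)
  # small ridge keeps the Cholesky inside solve.QP stable without moving the
  # optimum beyond solver tolerance
  Dmat <- Dmat + diag(1e-10, K)
  Amat <- cbind(diag(K), -1)
  bvec <- c(rep(0, K), -1)

  samples <- colnames(beta)
  W <- matrix(NA_real_, length(samples), K,
              dimnames = list(samples, colnames(A)))
  residual <- numeric(length(samples))
  for (i in seq_along(samples)) {
    b <- beta[probes, i]
    obs <- !is.na(b)
    if (!all(obs)) {
      Ai <- A[obs, , drop = FALSE]
      sol <- quadprog::solve.QP(crossprod(Ai) + diag(1e-10, K),
                                crossprod(Ai, b[obs]), Amat, bvec, meq = 0)
      residual[i] <- sqrt(sum((b[obs] - Ai %*% sol$solution)^2))
    } else {
      sol <- quadprog::solve.QP(Dmat, crossprod(A, b), Amat, bvec, meq = 0)
      residual[i] <- sqrt(sum((b - A %*% sol$solution)^2))
    }
    w <- pmax(sol$solution, 0)          # clip solver-tolerance negatives
    if (renormalize && sum(w) > 0) w <- w / sum(w)
    W[i, ] <- w
  }
  out <- data.frame(sample_id = samples, W, residual = residual,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("deconv_result", "data.frame")
  out
}

#' Compare estimated cell fractions between groups
#'
#' Fits a two-way ANOVA of fraction on group and cell type — both with and
#' without the group:cell-type interaction, since either reading of "two-way
#' ANOVA" is defensible — and follows up with per-cell-type nonparametric
#' group tests: a Kruskal-Wallis omnibus per cell type (BH-adjusted across
#' cell types) and pairwise rank-sum comparisons. Degenerate inputs
#' (identical fractions everywhere) yield missing p-values with a note
#' rather than failure.
#'
#' @param deconv a `deconv_result` from [estimate_fractions()].
#' @param sheet sample sheet with `sample_id` and `group`.
#' @return list with `anova_interaction`, `anova_additive` (ANOVA tables),
#'   `per_type` (data.frame: cell_type, kruskal p, BH-adjusted p) and
#'   `pairwise` (data.frame of per-type pairwise rank-sum p-values).
#' @export
compare_fractions <- function(deconv, sheet) {
  types <- setdiff(names(deconv), c("sample_id", "residual"))
  stopifnot(length(types) >= 2)
  sheet <- sheet[match(deconv$sample_id, sheet$sample_id), ]
  groups <- unique(sheet$group)
  if (length(groups) < 2) stop_input("compare_fractions needs >= 2 groups")
  if (any(table(sheet$group) < 2)) {
    stop_input("every group needs >= 2 samples")
  }

  long <- data.frame(
    fraction = unlist(deconv[types], use.names = FALSE),
    cell_type = factor(rep(types, each = nrow(deconv))),
    group = factor(rep(sheet$group, times = length(types))),
    stringsAsFactors = FALSE)

  # degenerate when every cell type is constant across samples: the residual
  # and between-group sums of squares vanish and F is undefined
  degenerate <- all(vapply(types, function(tp) var(deconv[[tp]]) == 0, TRUE))
  if (degenerate) {
    anova_int <- anova_add <- NULL
    note <- "fractions identical across samples; ANOVA F undefined, p-values missing"
  } else {
    tidy_aov <- function(form) {
      tab <- summary(aov(form, data = long))[[1]]
      rownames(tab) <- trimws(rownames(tab))
      tab
    }
    anova_int <- tidy_aov(fraction ~ group * cell_type)
    anova_add <- tidy_aov(fraction ~ group + cell_type)
    note <- NULL
  }

  per_type <- data.frame(cell_type = types, p = NA_real_,
                         stringsAsFactors = FALSE)
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  pw <- list()
  for (i in seq_along(types)) {
    fr <- deconv[[types[i]]]
    if (var(fr) > 0) {
      per_type$p[i] <- kruskal.test(fr, factor(sheet$group))$p.value
    }
    for (pr in pairs) {
      a <- fr[sheet$group == pr[1]]
      b <- fr[sheet$group == pr[2]]
      p <- if (var(c(a, b)) > 0) {
        wilcox.test(a, b, exact = FALSE)$p.value
      } else NA_real_
      pw[[length(pw) + 1]] <- data.frame(
        cell_type = types[i], group1 = pr[1], group2 = pr[2], p = p,
        stringsAsFactors = FALSE)
    }
  }
  per_type$adj_p <- bh_adjust(per_type$p)
  pairwise <- do.call(rbind, pw)
  pairwise$adj_p <- NA_real_
  for (pr in pairs) {
    sel <- pairwise$group1 == pr[1] & pairwise$group2 == pr[2]
    pairwise$adj_p[sel] <- bh_adjust(pairwise$p[sel])
  }

  list(anova_interaction = anova_int, anova_additive = anova_add,
       per_type = per_type, pairwise = pairwise, note = note)
}
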