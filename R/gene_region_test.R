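#' Order probes along the genome
#'
#' Sorts the manifest by chromosome (autosomes in numeric order, then chrX,
#' chrY, then any other labels alphabetically), position ascending, with ties
#' in position broken by probe id. "Consecutive probes" everywhere in the
#' gene-region test means consecutive in this ordering. Idempotent.
#'
#' @param manifest probe manifest (data.frame).
#' @return the manifest reordered genome-wise.
#' @export
order_probes <- function(manifest) {
  stopifnot(nrow(manifest) > 0)
  chrom <- manifest$chromosome
  core <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.numeric(core))
  rank[core == "X"] <- 1e6
  rank[core == "Y"] <- 1e6 + 1
  # unrecognized labels sort after, alphabetically
  rank[is.na(rank)] <- 1e6 + 2 + as.numeric(factor(chrom[is.na(rank)]))
  ord <- order(rank, manifest$position, manifest$probe_id)
  out <- manifest[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's combined statistic
#'
#' X = -2 * sum(log p) over the non-missing p-values; under independence X is
#' chi-square distributed with 2N degrees of freedom. Zeros are floored to
#' 1e-300 (counted in the `n_floored` attribute) so the statistic stays
#' finite.
#'
#' @param p p-values in (0, 1\]; NAs are excluded (count kept in the
#'   `n_missing` attribute).
#' @return the statistic, with attributes `n_used`, `n_missing`, `n_floored`.
#' @export
fisher_statistic <- function(p) {
  n_missing <- sum(is.na(p))
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) stop_input("p-values must lie in [0,1]")
  n_floored <- sum(p < 1e-300)
  if (n_floored > 0) {
    warning(sprintf("%d p-value(s) at or below 1e-300 floored", n_floored))
    p <- pmax(p, 1e-300)
  }
  structure(-2 * sum(log(p)), n_used = length(p), n_missing = n_missing,
            n_floored = n_floored)
}

# cumulative log-p machinery shared by the stretch sampler: missing p-values
# contribute 0 (the stretch aggregates its non-missing members; N is not
# re-matched)
.stretch_cumsums <- function(p) {
  lp <- ifelse(is.na(p), 0, log(pmax(p, 1e-300)))
  c(0, cumsum(lp))
}

#' Sample the empirical null of Fisher statistics over probe stretches
#'
#' Draws `B` start positions uniformly with replacement from all positions
#' that admit `N` consecutive genome-ordered probes — within a single
#' chromosome by default, since a stretch spanning a chromosome boundary is
#' not biologically contiguous — and returns each stretch's Fisher statistic.
#' Because the stretches inherit the local correlation of neighbouring
#' probes' p-values, this null captures the correlated nature of DNA
#' methylation that the analytic chi-square reference ignores.
#'
#' @param p p-values in genome order (align with `chromosome`).
#' @param chromosome chromosome label per probe, in the same order.
#' @param N stretch length in probes.
#' @param B number of null draws.
#' @param seed integer seed; the draw is fully determined by it.
#' @param within_chromosome confine stretches to one chromosome (default).
#' @return numeric vector of `B` null Fisher statistics.
#' @export
sample_null_stretches <- function(p, chromosome, N, B, seed,
                                  within_chromosome = TRUE) {
  stopifnot(B >= 1, N >= 1, length(p) == length(chromosome))
  n <- length(p)
  if (within_chromosome) {
    # admissible starts: runs of N probes not crossing a chromosome boundary
    ends <- cumsum(rle(chromosome)$lengths)
    starts_chrom <- c(1, head(ends, -1) + 1)
    admissible <- unlist(mapply(function(s, e) {
      if (e - s + 1 >= N) s:(e - N + 1) else integer(0)
    }, starts_chrom, ends, SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    admissible <- if (n >= N) 1:(n - N + 1) else integer(0)
  }
  if (length(admissible) == 0) {
    stop_input("no chromosome admits a stretch of %d consecutive probes", N)
  }
  cs <- .stretch_cumsums(p)
  with_seed(seed, {
    starts <- admissible[sample.int(length(admissible), B, replace = TRUE)]
    -2 * (cs[starts + N] - cs[starts])
  })
}

#' Gene-level aggregated methylation test with a stretch null
#'
#' Aggregates the raw per-probe p-values of a gene's probes with Fisher's
#' method and compares the observed statistic against an empirical null of
#' `B` randomly placed stretches of the same number of consecutive
#' genome-ordered probes. The empirical p uses the add-one permutation
#' convention, p = (#\{null >= X_obs\} + 1)/(B + 1), so it is never exactly
#' zero. Comparing statistics is equivalent to comparing aggregated p-values
#' because the Fisher map is monotone.
#'
#' @param gene gene symbol present in the manifest.
#' @param dmp DmpTable with `probe_id` and raw `p`.
#' @param manifest probe manifest (any order; ordered internally).
#' @param B number of null stretches (default 5000).
#' @param seed integer seed.
#' @param within_chromosome confine null stretches to one chromosome.
#' @param exclude_self drop the gene's own probes from the null pool.
#' @return a one-row data.frame: `gene_symbol`, `n_probes`, `x_obs`,
#'   `b_draws`, `exceed_count`, `p_empirical`, `p_analytic` (the naive
#'   chi-square Fisher p, for comparison).
#' @export
gene_test <- function(gene, dmp, manifest, B = 5000, seed = 1L,
                      within_chromosome = TRUE, exclude_self = FALSE) {
  manifest <- order_probes(manifest)
  gene_probes <- manifest$probe_id[manifest$gene_symbol == gene]
  if (length(gene_probes) == 0) stop_input("gene %s absent from manifest", gene)
  p_all <- dmp$p[match(manifest$probe_id, dmp$probe_id)]
  gp <- p_all[match(gene_probes, manifest$probe_id)]
  if (all(is.na(gp))) {
    stop_input("gene %s has no probe with a non-missing p-value", gene)
  }
  N <- length(gene_probes)
  x_obs <- fisher_statistic(gp)
  n_used <- attr(x_obs, "n_used")

  keep <- rep(TRUE, nrow(manifest))
  if (exclude_self) keep <- manifest$gene_symbol != gene
  null_stats <- sample_null_stretches(p_all[keep], manifest$chromosome[keep],
                                      N = N, B = B, seed = seed,
                                      within_chromosome = within_chromosome)
  exceed <- sum(null_stats >= as.numeric(x_obs))
  data.frame(
    gene_symbol = gene, n_probes = N, x_obs = as.numeric(x_obs),
    b_draws = B, exceed_count = exceed,
    p_empirical = (exceed + 1) / (B + 1),
    p_analytic = pchisq(as.numeric(x_obs), df = 2 * n_used, lower.tail = FALSE),
    stringsAsFactors = FALSE)
}

#' Test a user-supplied gene list
#'
#' Runs [gene_test()] for every gene, with per-gene seeds derived
#' deterministically from the master seed and the gene name (so each gene's
#' result is independent of the list's order), and BH-adjusts the empirical
#' p-values across the supplied list. Genes absent from the manifest are
#' reported with missing results and a warning, not an error.
#'
#' @param genes character vector of gene symbols (the hypothesis list).
#' @param dmp DmpTable with raw per-probe p-values.
#' @param manifest probe manifest.
#' @param B null draws per gene.
#' @param seed master seed.
#' @param ... further arguments to [gene_test()].
#' @return data.frame, one row per gene, columns as [gene_test()] plus
#'   `adj_p`.
#' @export
test_gene_set <- function(genes, dmp, manifest, B = 5000, seed = 1L,
                          within_chromosome = TRUE, exclude_self = FALSE) {
  stopifnot(length(genes) > 0)
  manifest <- order_probes(manifest)
  known <- genes %in% manifest$gene_symbol
  if (any(!known)) {
    warning(sprintf("gene(s) not in manifest: %s",
                    paste(genes[!known], collapse = ", ")))
  }
  # shared genome-ordered machinery, computed once for the whole list
  p_all <- dmp$p[match(manifest$probe_id, dmp$probe_id)]
  gene_rows <- split(seq_len(nrow(manifest)), manifest$gene_symbol)

  rows <- lapply(genes, function(g) {
    idx <- gene_rows[[g]]
    if (is.null(idx)) {
      return(data.frame(gene_symbol = g, n_probes = NA_integer_,
                        x_obs = NA_real_, b_draws = B,
                        exceed_count = NA_integer_, p_empirical = NA_real_,
                        p_analytic = NA_real_, stringsAsFactors = FALSE))
    }
    gp <- p_all[idx]
    if (all(is.na(gp))) {
      stop_input("gene %s has no probe with a non-missing p-value", g)
    }
    N <- length(idx)
    x_obs <- fisher_statistic(gp)
    keep <- if (exclude_self) manifest$gene_symbol != g else
      rep(TRUE, nrow(manifest))
    null_stats <- sample_null_stretches(
      p_all[keep], manifest$chromosome[keep], N = N, B = B,
      seed = str_seed(seed, g), within_chromosome = within_chromosome)
    exceed <- sum(null_stats >= as.numeric(x_obs))
    data.frame(
      gene_symbol = g, n_probes = N, x_obs = as.numeric(x_obs),
      b_draws = B, exceed_count = exceed,
      p_empirical = (exceed + 1) / (B + 1),
      p_analytic = pchisq(as.numeric(x_obs), df = 2 * attr(x_obs, "n_used"),
                          lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_empirical)
  rownames(out) <- NULL
  out
}
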