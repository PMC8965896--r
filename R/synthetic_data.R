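#' Configuration of a synthetic EPIC-like cohort
#'
#' Collects every knob of the synthetic-data generator with validated
#' defaults. The default cohort emulates a three-group peripheral-blood
#' methylation study — 17 PSC-UC, 17 UC and 12 healthy-control samples — at a
#' desk-scale 2e4 probes (a scaled-down stand-in for the 850k EPIC array).
#' Signals combine on the logit scale and are mapped back through the
#' inverse-logit, which guarantees beta values strictly inside (0,1) without
#' clipping; clipping would distort tails and break null-calibration
#' properties downstream.
#'
#' @param n_probes total number of array probes.
#' @param n_chromosomes number of chromosomes to lay probes on; when
#'   `allosome = TRUE` the last one is "chrX" and its probes are flagged
#'   allosomal.
#' @param gene_block_size_range integer pair: min/max probes per gene block.
#' @param intergenic_gap_range integer pair: probes between gene blocks.
#' @param group_sizes named integer vector of samples per group.
#' @param age_range sampling range (years) of chronological ages.
#' @param correlation_length decay scale (in probes) of the local spatial
#'   correlation of methylation; 0 disables the spatial field.
#' @param spatial_sd stationary standard deviation (logit scale) of the
#'   spatial field.
#' @param noise_sd independent measurement-noise standard deviation (logit
#'   scale).
#' @param n_cell_types number of leukocyte types in the mixture reference.
#' @param n_discriminating number of cell-type-discriminating probes in the
#'   reference.
#' @param injected_effects list of effects, each a list with `delta`
#'   (logit-scale shift), `group` (affected group) and either `gene` (a gene
#'   symbol) or `probes` (probe ids).
#' @param clock_probe_count number of probes carrying the age-clock signal
#'   (0 disables the clock signal).
#' @param snp_fraction,cross_reactive_fraction fractions of probes flagged
#'   SNP-associated / cross-reactive in the manifest.
#' @param allosome whether to include an allosome ("chrX") chromosome.
#' @param group_alpha optional named list group -> Dirichlet concentration
#'   vector over cell types; `NULL` uses one whole-blood-like vector for all
#'   groups (exchangeable mixture null).
#' @param fixed_fractions optional vector (length `n_cell_types`) or matrix
#'   (types x samples) of cell fractions, bypassing the Dirichlet draw.
#' @param seed master seed; every generator operation derives its own stream
#'   from it.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_probes = 20000L,
                              n_chromosomes = 10L,
                              gene_block_size_range = c(5L, 10L),
                              intergenic_gap_range = c(1L, 3L),
                              group_sizes = c(PSC_UC = 17L, UC = 17L, HC = 12L),
                              age_range = c(25, 65),
                              correlation_length = 5,
                              spatial_sd = 0.2,
                              noise_sd = 0.1,
                              n_cell_types = 6L,
                              n_discriminating = 600L,
                              injected_effects = list(),
                              clock_probe_count = 30L,
                              snp_fraction = 0.03,
                              cross_reactive_fraction = 0.02,
                              allosome = TRUE,
                              group_alpha = NULL,
                              fixed_fractions = NULL,
                              seed = 1L) {
  stopifnot(n_probes >= 1, n_chromosomes >= 1,
            length(gene_block_size_range) == 2,
            gene_block_size_range[1] >= 1,
            gene_block_size_range[1] <= gene_block_size_range[2],
            all(group_sizes >= 1), length(age_range) == 2,
            correlation_length >= 0, spatial_sd >= 0, noise_sd >= 0,
            n_cell_types >= 2, clock_probe_count >= 0)
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% c("PSC_UC", "UC", "HC"))) {
    stop_input("group_sizes must be named with labels from {PSC_UC, UC, HC}")
  }
  for (eff in injected_effects) {
    if (!is.finite(eff$delta)) stop_input("injected effect delta must be finite")
    if (is.null(eff$gene) && is.null(eff$probes)) {
      stop_input("each injected effect needs 'gene' or 'probes'")
    }
  }
  structure(list(
    n_probes = as.integer(n_probes), n_chromosomes = as.integer(n_chromosomes),
    gene_block_size_range = as.integer(gene_block_size_range),
    intergenic_gap_range = as.integer(intergenic_gap_range),
    group_sizes = group_sizes, age_range = age_range,
    correlation_length = correlation_length, spatial_sd = spatial_sd,
    noise_sd = noise_sd, n_cell_types = as.integer(n_cell_types),
    n_discriminating = as.integer(n_discriminating),
    injected_effects = injected_effects,
    clock_probe_count = as.integer(clock_probe_count),
    snp_fraction = snp_fraction,
    cross_reactive_fraction = cross_reactive_fraction,
    allosome = allosome, group_alpha = group_alpha,
    fixed_fractions = fixed_fractions, seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate a synthetic probe manifest with gene blocks
#'
#' Probes are laid out with strictly increasing positions on each chromosome.
#' Genes are blocks of consecutive probes whose sizes are drawn from the
#' configured range, separated by short intergenic runs, mirroring the
#' clustering of array probes in CpG islands and gene bodies. A configurable
#' fraction of probes carries SNP-associated / cross-reactive flags; probes on
#' the allosome (if present) are flagged `allosomal`.
#'
#' @param config a [simulation_config()].
#' @return list with `manifest` (data.frame, see [read_manifest()]) and
#'   `genes` (named list gene symbol -> probe ids, in genome order).
#' @export
generate_manifest <- function(config) {
  if (config$n_probes < config$gene_block_size_range[1]) {
    stop_input("n_probes (%d) smaller than one gene block (min %d)",
               config$n_probes, config$gene_block_size_range[1])
  }
  with_seed(str_seed(config$seed, "manifest"), {
    n <- config$n_probes
    chroms <- if (config$allosome && config$n_chromosomes >= 2) {
      c(paste0("chr", seq_len(config$n_chromosomes - 1)), "chrX")
    } else {
      paste0("chr", seq_len(config$n_chromosomes))
    }
    # near-equal split of probes across chromosomes
    base <- n %/% length(chroms)
    counts <- rep(base, length(chroms))
    counts[seq_len(n - base * length(chroms))] <- base + 1
    chromosome <- rep(chroms, counts)
    position <- unlist(lapply(counts, function(k) {
      cumsum(sample(100:10000, k, replace = TRUE))
    }), use.names = FALSE)

    # alternate gene blocks and intergenic gaps along the probe index
    gene_symbol <- character(n)
    gmin <- config$gene_block_size_range[1]
    gmax <- config$gene_block_size_range[2]
    imin <- config$intergenic_gap_range[1]
    imax <- config$intergenic_gap_range[2]
    gene_no <- 0L
    offset <- 0L
    for (k in counts) {
      i <- 1L
      while (i + gmin - 1L <= k) {
        size <- sample(gmin:gmax, 1L)
        size <- min(size, k - i + 1L)
        gene_no <- gene_no + 1L
        gene_symbol[offset + i:(i + size - 1L)] <- sprintf("G%05d", gene_no)
        i <- i + size + sample(imin:imax, 1L)
      }
      offset <- offset + k
    }

    manifest <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(n)),
      chromosome = chromosome,
      position = position,
      gene_symbol = gene_symbol,
      snp_associated = runif(n) < config$snp_fraction,
      cross_reactive = runif(n) < config$cross_reactive_fraction,
      allosomal = chromosome == "chrX",
      stringsAsFactors = FALSE)

    in_gene <- manifest$gene_symbol != ""
    genes <- split(manifest$probe_id[in_gene], manifest$gene_symbol[in_gene])
    list(manifest = manifest, genes = genes)
  })
}

# whole-blood-like Dirichlet concentration (leukocyte proportions x 80)
.blood_alpha <- function(cell_types) {
  props <- c(CD4T = 0.15, CD8T = 0.08, B = 0.05, NK = 0.05,
             Mono = 0.07, Neu = 0.60)
  if (all(cell_types %in% names(props))) {
    props[cell_types] / sum(props[cell_types]) * 80
  } else {
    setNames(rep(80 / length(cell_types), length(cell_types)), cell_types)
  }
}

#' Per-group Dirichlet presets emulating patient-shifted blood composition
#'
#' Returns per-group concentration vectors in which the NK fraction is
#' lowered in both patient groups and the myeloid (Mono/Neu) share is raised
#' in UC, giving the deconvolution and ANOVA stages a realistic alternative
#' to detect.
#'
#' @param cell_types cell-type labels (the default six leukocyte types).
#' @return named list of concentration vectors for PSC_UC, UC and HC.
#' @export
blood_preset_alphas <- function(cell_types = c("CD4T", "CD8T", "B", "NK",
                                               "Mono", "Neu")) {
  base <- .blood_alpha(cell_types)
  patient <- base
  if ("NK" %in% names(patient)) patient["NK"] <- patient["NK"] * 0.4
  uc <- patient
  for (m in intersect(c("Mono", "Neu"), names(uc))) uc[m] <- uc[m] * 1.25
  list(PSC_UC = patient, UC = uc, HC = base)
}

#' Generate a cell-type methylation reference
#'
#' Per-cell-type mean beta per probe. Most probes share one bimodal baseline
#' across types (the typical low/high methylation landscape of an array); a
#' designated subset of probes is made discriminating by pushing cell types
#' toward 0 or 1 in distinct random patterns, emulating lineage-specific
#' differentially methylated sites used for deconvolution. All means are
#' strictly inside (0,1).
#'
#' @param manifest probe manifest (data.frame).
#' @param n_cell_types number of cell types (>= 2).
#' @param seed integer seed.
#' @param n_discriminating number of discriminating probes.
#' @param cell_types optional label vector; defaults to the six common
#'   leukocyte types (extended generically beyond six).
#' @return list with `cell_types`, `means` (probes x types matrix),
#'   `discriminating` (probe ids), `baseline` (shared per-probe baseline).
#' @export
generate_reference <- function(manifest, n_cell_types = 6L, seed = 1L,
                               n_discriminating = 600L, cell_types = NULL) {
  stopifnot(n_cell_types >= 2)
  if (is.null(cell_types)) {
    std <- c("CD4T", "CD8T", "B", "NK", "Mono", "Neu")
    cell_types <- if (n_cell_types <= 6) std[seq_len(n_cell_types)] else
      c(std, paste0("Cell", seq_len(n_cell_types - 6)))
  }
  stopifnot(length(cell_types) == n_cell_types)
  with_seed(str_seed(seed, "reference"), {
    n <- nrow(manifest)
    comp <- sample(c("low", "mid", "high"), n, replace = TRUE,
                   prob = c(0.45, 0.10, 0.45))
    baseline <- numeric(n)
    baseline[comp == "low"] <- stats::rbeta(sum(comp == "low"), 1.5, 10)
    baseline[comp == "mid"] <- stats::rbeta(sum(comp == "mid"), 5, 5)
    baseline[comp == "high"] <- stats::rbeta(sum(comp == "high"), 10, 1.5)
    baseline <- pmin(pmax(baseline, 0.02), 0.98)

    means <- matrix(baseline, n, n_cell_types,
                    dimnames = list(manifest$probe_id, cell_types))
    n_disc <- min(n_discriminating, n)
    disc_idx <- sort(sample.int(n, n_disc))
    K <- n_cell_types
    for (i in disc_idx) {
      k_high <- sample.int(K, sample.int(K - 1L, 1L))
      means[i, ] <- 0.03 + runif(K, 0, 0.05)
      means[i, k_high] <- 0.92 + runif(length(k_high), 0, 0.05)
    }
    list(cell_types = cell_types, means = means,
         discriminating = manifest$probe_id[disc_idx], baseline = baseline)
  })
}

#' Construct a synthetic epigenetic clock consistent with the generator
#'
#' Picks `clock_probe_count` unflagged probes and assigns each a beta-scale
#' baseline m_j and an age slope s_j; the cohort generator makes those
#' probes' noiseless beta equal m_j + s_j * F(age), with F the piecewise
#' log/linear age calibration (see [age_transform()]). The clock's sparse
#' coefficients are u_j = 1/(K s_j) with intercept -sum(u_j m_j), so the
#' linear score of a noiseless cohort equals F(age) exactly and the clock is
#' self-consistent by construction. Baseline/slope ranges keep the noiseless
#' beta inside (0,1) for ages 0-100.
#'
#' @param manifest probe manifest.
#' @param config a [simulation_config()]; uses `clock_probe_count` and `seed`.
#' @return a `clock_model` list: `intercept`, `coefficients` (named),
#'   `adult_age`, `reference_means` (for missing-probe imputation),
#'   `baseline` and `slope` (the generator-side parameters).
#' @export
make_clock <- function(manifest, config) {
  K <- config$clock_probe_count
  stopifnot(K >= 1, K <= nrow(manifest))
  with_seed(str_seed(config$seed, "clock"), {
    eligible <- which(!manifest$snp_associated & !manifest$cross_reactive &
                        manifest$gene_symbol == "")
    if (length(eligible) < K) eligible <- seq_len(nrow(manifest))
    idx <- sort(sample(eligible, K))
    probes <- manifest$probe_id[idx]
    m <- runif(K, 0.35, 0.55)
    s <- runif(K, 0.04, 0.10)
    u <- 1 / (K * s)
    mid_age <- 45
    structure(list(
      intercept = -sum(u * m),
      coefficients = setNames(u, probes),
      adult_age = 20,
      reference_means = setNames(m + s * age_transform(mid_age, 20), probes),
      baseline = setNames(m, probes),
      slope = setNames(s, probes)),
      class = "clock_model")
  })
}

# Dirichlet draw via normalized gammas; rows = cell types, cols = samples
.rdirichlet <- function(n, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop_input("Dirichlet concentration parameters must be positive and finite")
  }
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), length(alpha), n)
  sweep(g, 2, colSums(g), "/")
}

# stationary AR(1) field over probe index, restarted at chromosome boundaries
.spatial_field <- function(chromosome, n_samples, corr_length, sd) {
  n <- length(chromosome)
  if (corr_length <= 0 || sd <= 0) return(matrix(0, n, n_samples))
  phi <- exp(-1 / corr_length)
  innov_sd <- sd * sqrt(1 - phi^2)
  field <- matrix(rnorm(n * n_samples), n, n_samples)
  new_chrom <- c(TRUE, chromosome[-1] != chromosome[-n])
  for (j in seq_len(n)) {
    if (new_chrom[j]) {
      field[j, ] <- field[j, ] * sd
    } else {
      field[j, ] <- phi * field[j - 1, ] + field[j, ] * innov_sd
    }
  }
  field
}

# resolve an injected-effect entry to probe row indices
.effect_probes <- function(eff, manifest) {
  if (!is.null(eff$gene)) {
    idx <- which(manifest$gene_symbol == eff$gene)
    if (length(idx) == 0) stop_input("injected-effect gene %s not in manifest", eff$gene)
  } else {
    idx <- match(eff$probes, manifest$probe_id)
    if (anyNA(idx)) stop_input("injected-effect probe not in manifest")
  }
  idx
}

#' Generate a synthetic methylation cohort with known ground truth
#'
#' For each sample, beta = inverse-logit( logit(sum_k w_k ref_k) + spatial
#' field + group shift + noise ): `w` is a per-group Dirichlet draw over cell
#' types, the spatial field is a zero-mean AR(1) process over probe index with
#' correlation decaying at the configured length (restarted at chromosome
#' boundaries), and logit-scale shifts delta apply at injected probes for the
#' configured group. Clock probes instead carry a beta-linear age signal (see
#' [make_clock()]) before the logit-scale field/noise are added. The returned
#' truth object records every latent quantity for recovery tests.
#'
#' @param manifest probe manifest (data.frame) from [generate_manifest()].
#' @param reference cell-type reference from [generate_reference()].
#' @param config a [simulation_config()].
#' @param clock a `clock_model`, or `NULL` to build one from the config
#'   (when `clock_probe_count > 0`).
#' @return list with `beta` (probes x samples), `sheet` (sample sheet
#'   data.frame) and `truth` (injected effects, true cell fractions, ages,
#'   clock, per-probe baseline means).
#' @export
generate_cohort <- function(manifest, reference, config, clock = NULL) {
  if (is.null(clock) && config$clock_probe_count > 0) {
    clock <- make_clock(manifest, config)
  }
  with_seed(str_seed(config$seed, "cohort"), {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    sample_id <- unlist(lapply(names(config$group_sizes), function(g) {
      sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]]))
    }), use.names = FALSE)
    ages <- runif(n, config$age_range[1], config$age_range[2])
    steroids <- rbinom(n, 1, 0.5)
    sheet <- data.frame(sample_id = sample_id, group = groups,
                        age = ages, steroids = steroids,
                        stringsAsFactors = FALSE)

    K <- length(reference$cell_types)
    if (!is.null(config$fixed_fractions)) {
      w <- config$fixed_fractions
      if (is.null(dim(w))) w <- matrix(w, K, n)
      stopifnot(nrow(w) == K, ncol(w) == n)
    } else {
      w <- matrix(NA_real_, K, n)
      for (g in unique(groups)) {
        alpha <- if (!is.null(config$group_alpha)) config$group_alpha[[g]] else
          .blood_alpha(reference$cell_types)
        sel <- groups == g
        w[, sel] <- .rdirichlet(sum(sel), alpha)
      }
    }
    rownames(w) <- reference$cell_types
    colnames(w) <- sample_id

    mix <- reference$means %*% w                       # probes x samples
    L <- .logit(mix)

    # clock probes: beta-linear age signal replaces the mixture baseline
    if (!is.null(clock)) {
      cp <- match(names(clock$coefficients), manifest$probe_id)
      f_age <- age_transform(ages, clock$adult_age)
      base_clock <- outer(clock$baseline, rep(1, n)) +
        outer(clock$slope, f_age)
      L[cp, ] <- .logit(pmin(pmax(base_clock, 1e-6), 1 - 1e-6))
    }

    injected <- data.frame(probe_id = character(0), delta = numeric(0),
                           group = character(0), stringsAsFactors = FALSE)
    for (eff in config$injected_effects) {
      idx <- .effect_probes(eff, manifest)
      sel <- groups == eff$group
      L[idx, sel] <- L[idx, sel] + eff$delta
      injected <- rbind(injected, data.frame(
        probe_id = manifest$probe_id[idx], delta = eff$delta,
        group = eff$group, stringsAsFactors = FALSE))
    }

    field <- .spatial_field(manifest$chromosome, n,
                            config$correlation_length, config$spatial_sd)
    noise <- if (config$noise_sd > 0) {
      matrix(rnorm(length(L), sd = config$noise_sd), nrow(L), ncol(L))
    } else 0

    beta <- .invlogit(L + field + noise)
    dimnames(beta) <- list(manifest$probe_id, sample_id)

    truth <- list(injected = injected, cell_fractions = w, ages = ages,
                  clock = clock, baseline_means = rowMeans(mix))
    list(beta = beta, sheet = sheet, truth = truth)
  })
}
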