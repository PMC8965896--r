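# Shared fixture builders. Everything is generated in code at test time;
# builders are deterministic under their seed arguments.

tiny_manifest <- function() {
  data.frame(
    probe_id = sprintf("cg%03d", 1:10),
    chromosome = c(rep("chr1", 4), rep("chr2", 4), rep("chrX", 2)),
    position = c(100, 250, 400, 900, 50, 60, 700, 1000, 10, 20),
    gene_symbol = c("A", "A", "", "B", "B", "B", "", "", "C", "C"),
    snp_associated = c(TRUE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 5)),
    cross_reactive = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    allosomal = c(rep(FALSE, 8), TRUE, TRUE),
    stringsAsFactors = FALSE)
}

tiny_beta <- function(manifest = tiny_manifest(), n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    b <- matrix(runif(nrow(manifest) * n_samples, 0.05, 0.95),
                nrow(manifest), n_samples,
                dimnames = list(manifest$probe_id,
                                sprintf("S%02d", seq_len(n_samples))))
    round(b, 6)  # exactly representable round-trip fixture
  })
}

# a small cohort shared across module tests (cheap to regenerate)
small_cohort <- function(n_probes = 2000, seed = 7, ...) {
  cfg <- simulation_config(n_probes = n_probes, seed = seed, ...)
  mf <- generate_manifest(cfg)
  ref <- generate_reference(mf$manifest, cfg$n_cell_types, seed = seed,
                            n_discriminating = min(300, n_probes %/% 4))
  clock <- if (cfg$clock_probe_count > 0) make_clock(mf$manifest, cfg) else NULL
  coh <- generate_cohort(mf$manifest, ref, cfg, clock)
  list(config = cfg, manifest = mf$manifest, genes = mf$genes,
       reference = ref, clock = clock, beta = coh$beta, sheet = coh$sheet,
       truth = coh$truth)
}
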