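#' Read and validate a methylation dataset
#'
#' Reads the three on-disk artifacts of a cohort — the probe manifest, the
#' beta-value matrix and the sample sheet — and validates them against each
#' other. The manifest and beta matrix are tab-separated; the sample sheet may
#' be comma- or tab-separated (the delimiter is sniffed from the header line).
#' Beta matrices are stored probes-as-rows, samples-as-columns; a file whose
#' columns do not match the sample sheet is rejected rather than transposed,
#' because silent transposition is a classic corruption source.
#'
#' @param manifest_path path to the tab-separated probe manifest with columns
#'   `probe_id`, `chromosome`, `position`, `gene_symbol`, `snp_associated`,
#'   `cross_reactive`, `allosomal`.
#' @param beta_path path to the tab-separated beta matrix; first column
#'   `probe_id`, remaining columns one per sample. Values are methylation
#'   fractions in \[0,1\]; empty cells are read as missing and propagated.
#' @param sheet_path path to the sample sheet with at least `sample_id`,
#'   `group` (one of `PSC_UC`, `UC`, `HC`), `age` and any further covariate
#'   columns (e.g. `steroids`).
#' @return a list with components `manifest` (data.frame), `beta` (numeric
#'   matrix with probe rownames and sample colnames) and `sheet` (data.frame).
#' @export
read_dataset <- function(manifest_path, beta_path, sheet_path) {
  manifest <- read_manifest(manifest_path)
  beta <- read_beta(beta_path)
  sheet <- read_sample_sheet(sheet_path)

  missing_probes <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing_probes) > 0) {
    stop_input("beta matrix contains %d probe(s) absent from the manifest (first: %s)",
               length(missing_probes), missing_probes[1])
  }
  extra <- setdiff(colnames(beta), sheet$sample_id)
  absent <- setdiff(sheet$sample_id, colnames(beta))
  if (length(extra) > 0 || length(absent) > 0) {
    stop_input(
      "sample mismatch between beta matrix and sheet: in beta only [%s]; in sheet only [%s]",
      paste(extra, collapse = ", "), paste(absent, collapse = ", "))
  }
  beta <- beta[, sheet$sample_id, drop = FALSE]
  list(manifest = manifest, beta = beta, sheet = sheet)
}

#' @rdname read_dataset
#' @export
read_manifest <- function(manifest_path) {
  stopifnot(file.exists(manifest_path))
  manifest <- as.data.frame(data.table::fread(manifest_path, sep = "\t"))
  required <- c("probe_id", "chromosome", "position", "gene_symbol",
                "snp_associated", "cross_reactive", "allosomal")
  miss <- setdiff(required, names(manifest))
  if (length(miss) > 0) {
    stop_input("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- manifest$probe_id[duplicated(manifest$probe_id)]
  if (length(dup) > 0) stop_input("duplicate probe_id in manifest: %s", dup[1])
  if (any(manifest$position < 1)) {
    stop_input("manifest positions must be 1-based (>= 1); offending probe: %s",
               manifest$probe_id[which(manifest$position < 1)[1]])
  }
  manifest$gene_symbol[is.na(manifest$gene_symbol)] <- ""
  for (fl in c("snp_associated", "cross_reactive", "allosomal")) {
    manifest[[fl]] <- as.logical(manifest[[fl]])
  }
  manifest
}

#' @rdname read_dataset
#' @export
read_beta <- function(beta_path) {
  stopifnot(file.exists(beta_path))
  tab <- data.table::fread(beta_path, sep = "\t")
  if (names(tab)[1] != "probe_id") {
    stop_input("beta matrix must have 'probe_id' as its first column (found '%s')",
               names(tab)[1])
  }
  ids <- tab$probe_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop_input("duplicate probe_id in beta matrix: %s", dup[1])
  beta <- as.matrix(tab[, -1, drop = FALSE])
  if (anyDuplicated(colnames(beta))) {
    stop_input("duplicate sample id in beta matrix: %s",
               colnames(beta)[duplicated(colnames(beta))][1])
  }
  storage.mode(beta) <- "double"
  rownames(beta) <- ids
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_input("beta value outside [0,1] at probe %s, sample %s (value %g)",
               ids[bad[1, 1]], colnames(beta)[bad[1, 2]], beta[bad[1, , drop = FALSE]])
  }
  beta
}

#' @rdname read_dataset
#' @export
read_sample_sheet <- function(sheet_path) {
  stopifnot(file.exists(sheet_path))
  header <- readLines(sheet_path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  sheet <- as.data.frame(data.table::fread(sheet_path, sep = sep))
  required <- c("sample_id", "group", "age")
  miss <- setdiff(required, names(sheet))
  if (length(miss) > 0) {
    stop_input("sample sheet is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) stop_input("duplicate sample_id in sheet: %s", dup[1])
  bad_group <- setdiff(unique(sheet$group), c("PSC_UC", "UC", "HC"))
  if (length(bad_group) > 0) {
    stop_input("unknown group label(s): %s (expected PSC_UC, UC, HC)",
               paste(bad_group, collapse = ", "))
  }
  if (any(!is.finite(sheet$age)) || any(sheet$age < 0)) {
    stop_input("ages must be finite and non-negative")
  }
  sheet
}

#' Write cohort artifacts and result tables
#'
#' Writers mirror the readers bit-exactly (numeric values are serialized with
#' round-trippable precision), so `write` then `read` is an identity on every
#' supported table type. DMP and gene-level tables are written as
#' tab-separated text with a fixed, documented column order; significant loci
#' can be exported as BED (0-based, half-open, width-1 intervals per CpG); run
#' summaries as JSON.
#'
#' @param manifest,beta,sheet the structures returned by [read_dataset()].
#' @param path output file path.
#' @name write_dataset
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("probe_id", "chromosome", "position", "gene_symbol",
            "snp_associated", "cross_reactive", "allosomal")
  data.table::fwrite(manifest[, cols], path, sep = "\t")
  invisible(path)
}

#' @rdname write_dataset
#' @export
write_beta <- function(beta, path) {
  tab <- data.table::data.table(probe_id = rownames(beta), beta)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dataset
#' @export
write_sample_sheet <- function(sheet, path, sep = ",") {
  data.table::fwrite(sheet, path, sep = sep)
  invisible(path)
}

# fixed column orders for the result-table serializers
.dmp_cols <- c("probe_id", "effect", "se", "t", "df", "p", "adj_p",
               "direction", "delta_beta")
.gene_cols <- c("gene_symbol", "n_probes", "x_obs", "b_draws", "exceed_count",
                "p_empirical", "adj_p")

#' Write a result table as tab-separated text
#'
#' @param results a DMP table (from [fit_probe_models()]) or gene-level test
#'   table (from [test_gene_set()]).
#' @param path output path.
#' @param format one of `"tsv"`, `"bed"`, `"json"`. BED export is only
#'   defined for DMP tables and requires `manifest`; positions are converted
#'   from the manifest's 1-based coordinates to BED's 0-based half-open
#'   intervals of width 1.
#' @param manifest probe manifest, required for `format = "bed"`.
#' @export
write_report <- function(results, path, format = c("tsv", "bed", "json"),
                         manifest = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- if ("gene_symbol" %in% names(results)) .gene_cols else .dmp_cols
    cols <- intersect(cols, names(results))
    data.table::fwrite(results[, cols, drop = FALSE], path, sep = "\t")
  } else if (format == "bed") {
    if (is.null(manifest)) stop_input("BED export requires the probe manifest")
    idx <- match(results$probe_id, manifest$probe_id)
    if (anyNA(idx)) {
      stop_input("probe %s not found in manifest", results$probe_id[which(is.na(idx))[1]])
    }
    bed <- data.table::data.table(
      chrom = manifest$chromosome[idx],
      start = manifest$position[idx] - 1L,
      end = manifest$position[idx],
      name = results$probe_id)
    data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
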