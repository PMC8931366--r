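#' Read a samples-by-features count table
#'
#' TSV tables are tab-separated with a `sample_id` first column, feature
#' ids in the header, and optional `#`-prefixed comment lines; BIOM tables
#' use the community-standard features-by-samples orientation and are
#' transposed on read, so both carriers round-trip to the identical matrix.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @return integer matrix (samples x features) with dimnames.
#' @export
read_counts <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("the biomformat package is required for BIOM input")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
  } else {
    fields <- utils::count.fields(path, sep = "\t", comment.char = "#",
                                  quote = "")
    if (length(unique(fields)) > 1) {
      bad <- which(fields != fields[1])[1]
      stopf("ragged TSV: line %d of %s has %d fields, expected %d",
            bad, path, fields[bad], fields[1])
    }
    df <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]])) stopf("duplicate sample ids in %s", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  if (!is.numeric(m)) {
    bad <- which(!apply(m, c(1, 2), function(v) is.numeric(v) ||
                          !is.na(suppressWarnings(as.numeric(v)))),
                 arr.ind = TRUE)
    stopf("non-numeric entry at row %d, column %d of %s",
          bad[1, 1], bad[1, 2], path)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)
    stopf("negative entry at row %d (%s), column %d (%s) of %s",
          bad[1, 1], rownames(m)[bad[1, 1]], bad[1, 2],
          colnames(m)[bad[1, 2]], path)
  }
  m
}

#' Write a samples-by-features table
#'
#' @param m matrix with sample ids as rownames.
#' @param path output path.
#' @param format `"tsv"` or `"biom"`.
#' @param header optional character vector of `#`-prefixed provenance
#'   comment lines (TSV only).
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("tsv", "biom"), header = NULL) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("the biomformat package is required for BIOM output")
    }
    biomformat::write_biom(biomformat::make_biom(t(m)), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to on-disk interchange formats
#'
#' Emits the subject metadata TSV, per-site count TSVs, immune composition
#' CSVs, the ground-truth TSV, and a YAML echo of the generator
#' configuration, each stamped with the seed and configuration hash.
#'
#' @param cohort a `codevel_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("codevel seed=%d config=%s", cohort$config$seed,
                 config_hash(cohort$config))
  write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"), hdr)
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"), hdr)
  for (site in c("nasal", "rectal")) {
    write_counts(cohort$features[[site]],
                 file.path(dir, paste0("counts_", site, ".tsv")),
                 header = hdr)
  }
  for (assay in c("immune_tphe", "immune_ics")) {
    m <- cohort$features[[assay]]
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(assay, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cohort$truth)) {
    write_tsv(truth_table(cohort), file.path(dir, "truth.tsv"), hdr)
  }
  yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

run_config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "codevel_out",
    simulate = list(),
    paths = list(),
    state_models = list(k_range = c(1L, 6L), min_prevalence = 0.05,
                        depth_nasal = 1200L, depth_rectal = 2250L,
                        depth_immune = 50000L),
    variance = list(var_threshold = 1e-4),
    associations = list(fdr_level = 0.10),
    dev_index = list(max_dol = 450L, min_taxa_prevalence = 0.03,
                     n_draws = 50L),
    outcome = list(n_draws = 50L, eval_folds = 20L),
    verbose = TRUE
  )
}

#' Load and validate a pipeline run configuration
#'
#' YAML configuration with sections `seed`, `out_dir`, `simulate` (generator
#' overrides; omit to read data from `paths`), `paths`, `state_models`,
#' `variance`, `associations`, `dev_index`, `outcome`, `verbose`. Unknown
#' keys are rejected; referenced paths must exist at load time.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (is.list(path)) path else yaml::read_yaml(path)
  defs <- run_config_defaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown) > 0) {
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  for (sec in intersect(names(raw), names(defs))) {
    if (is.list(defs[[sec]]) && is.list(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]),
                     c(names(defs[[sec]]),
                       if (sec == "simulate") names(formals(sim_config)),
                       if (sec == "paths") c("subjects", "samples",
                                             "counts_nasal", "counts_rectal",
                                             "immune_tphe", "immune_ics")))
    if (length(bad) > 0) {
      stopf("unknown config keys in %s: %s", sec, paste(bad, collapse = ", "))
    }
    }
  }
  cfg <- modifyList(defs, raw)
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stopf("configured path does not exist: %s", p)
  }
  structure(cfg, class = "run_config")
}
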