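#' Default pipeline configuration
#'
#' Every stage parameter has a default; a config round-trips unchanged
#' through JSON serialization ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param outdir Output directory for all stages.
#' @param overrides Named list of values overriding the defaults
#'   (unknown keys are rejected).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "splicestrata_out", overrides = list()) {
  cfg <- list(
    outdir = outdir,
    annotation = NULL, tpm = NULL, counts = NULL,
    gene_sets = NULL, query_genes = NULL, correlation_pairs = NULL,
    driver_gene_id = "DRIVER",
    seed = 1L,
    # simulate stage
    n_samples = 94L, n_genes = 300L, events_per_type = 10L,
    driver_means = c(2, 5, 8), driver_sd = 0.5,
    driver_weights = c(0.3, 0.4, 0.3),
    shifted_fraction = 0.5, delta_psi_effect = 0.3,
    psi_noise_sd = 0.05, libsize_range = c(2e6, 5e6),
    # psi stage
    min_total_tpm = 1, max_missing_frac = 0.2,
    # strata stage
    trim_m = 0.30, trim_a = 0.05, g_min = 1L, g_max = 5L, n_starts = 8L,
    # diffsplice / composition stages
    alpha = 0.05, min_dpsi = 0.1, min_per_group = 5L,
    require_both_tests = FALSE)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop2("config validation: ", msg)
  chk(cfg$min_total_tpm >= 0, "min_total_tpm must be >= 0")
  chk(cfg$max_missing_frac >= 0 && cfg$max_missing_frac <= 1,
      "max_missing_frac must lie in [0,1]")
  chk(cfg$trim_m >= 0 && cfg$trim_m < 0.5, "trim_m must lie in [0, 0.5)")
  chk(cfg$trim_a >= 0 && cfg$trim_a < 0.5, "trim_a must lie in [0, 0.5)")
  chk(cfg$g_min >= 1 && cfg$g_max >= cfg$g_min, "need 1 <= g_min <= g_max")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0,1)")
  chk(cfg$min_dpsi >= 0 && cfg$min_dpsi <= 1, "min_dpsi must lie in [0,1]")
  chk(cfg$min_per_group >= 1, "min_per_group must be >= 1")
  chk(nzchar(cfg$driver_gene_id), "driver_gene_id must be non-empty")
  invisible(TRUE)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- c("seed", "n_samples", "n_genes", "events_per_type", "g_min",
            "g_max", "n_starts", "min_per_group")
  for (k in intersect(ints, names(raw)))
    if (!is.null(raw[[k]])) raw[[k]] <- as.integer(raw[[k]])
  pipeline_config(outdir = raw$outdir %||% "splicestrata_out",
                  overrides = raw[setdiff(names(raw), "outdir")])
}

stage_names <- function() c("simulate", "events", "psi", "strata",
                            "diffsplice", "composition", "associate",
                            "report")

log_run <- function(cfg, stage, inputs) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  tf <- tempfile(); write_pipeline_config(cfg, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  sums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else "absent", "")
  entry <- data.frame(
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stage = stage,
    version = as.character(utils::packageVersion("spliceStrata")),
    seed = cfg$seed, config_md5 = cfg_hash,
    inputs = paste(sprintf("%s=%s", names(sums), sums), collapse = ";"),
    stringsAsFactors = FALSE)
  logp <- file.path(cfg$outdir, "run_log.tsv")
  utils::write.table(entry, logp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = !file.exists(logp),
                     append = file.exists(logp))
  invisible(logp)
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop2("missing input for stage: ", what, " (", path %||% "unset", ")")
  path
}

out_path <- function(cfg, name) file.path(cfg$outdir, name)

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic cohort: annotation, TPM, counts, truth),
#' `events` (GTF to event catalog), `psi` (catalog + TPM to filtered PSI
#' matrix), `strata` (counts to TMM-normalized driver strata),
#' `diffsplice` (PSI + strata to delta-PSI table), `composition`
#' (composition profiles, group comparison, event-type spectra),
#' `associate` (optional correlations and gene-set over-representation),
#' `report` (collated summary). Outputs are written atomically under
#' `cfg$outdir`; each invocation appends a run-log entry with the package
#' version, config hash, seed and input checksums. A stage never mutates
#' its inputs, so the pipeline can be re-entered from any completed stage.
#'
#' @param stage One of the stage names above.
#' @param cfg A `pipeline_config` (or path to its JSON form).
#' @return Named character vector of the stage's output paths, invisibly.
#' @export
run_stage <- function(stage, cfg) {
  stage <- match.arg(stage, stage_names())
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  validate_pipeline_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  switch(stage,
    simulate = stage_simulate(cfg),
    events = stage_events(cfg),
    psi = stage_psi(cfg),
    strata = stage_strata(cfg),
    diffsplice = stage_diffsplice(cfg),
    composition = stage_composition(cfg),
    associate = stage_associate(cfg),
    report = stage_report(cfg))
}

stage_simulate <- function(cfg) {
  log_run(cfg, "simulate", character())
  spec <- cohort_spec(
    n_samples = cfg$n_samples, n_genes = cfg$n_genes,
    events_per_type = cfg$events_per_type, driver_means = cfg$driver_means,
    driver_sd = cfg$driver_sd, driver_weights = cfg$driver_weights,
    shifted_fraction = cfg$shifted_fraction,
    delta_psi_effect = cfg$delta_psi_effect,
    psi_noise_sd = cfg$psi_noise_sd, libsize_range = cfg$libsize_range,
    seed = derive_seed(cfg$seed, "simulate"))
  ann <- generate_annotation(spec)
  coh <- generate_cohort(spec, ann)
  invisible(write_cohort(spec, ann, coh, cfg$outdir))
}

stage_inputs <- function(cfg, key, default) {
  cfg[[key]] %||% out_path(cfg, default)
}

stage_events <- function(cfg) {
  gtf <- need_file(stage_inputs(cfg, "annotation", "annotation.gtf"),
                   "annotation GTF")
  log_run(cfg, "events", c(annotation = gtf))
  catalog <- detect_events(read_gtf(gtf))
  p <- out_path(cfg, "event_catalog.tsv")
  write_event_catalog(catalog, p)
  invisible(c(event_catalog = p))
}

stage_psi <- function(cfg) {
  cat_p <- need_file(out_path(cfg, "event_catalog.tsv"), "event catalog")
  tpm_p <- need_file(stage_inputs(cfg, "tpm", "transcript_tpm.tsv"),
                     "transcript TPM matrix")
  log_run(cfg, "psi", c(catalog = cat_p, tpm = tpm_p))
  catalog <- read_event_catalog(cat_p)
  tpm <- read_abundance(tpm_p)
  psi <- filter_psi(compute_psi(catalog, tpm, cfg$min_total_tpm),
                    cfg$max_missing_frac)
  p <- out_path(cfg, "psi.tsv")
  write_psi_matrix(psi, p)
  invisible(c(psi = p))
}

stage_strata <- function(cfg) {
  cnt_p <- need_file(stage_inputs(cfg, "counts", "gene_counts.tsv"),
                     "gene count matrix")
  log_run(cfg, "strata", c(counts = cnt_p))
  counts <- read_matrix_tsv(cnt_p)
  if (!cfg$driver_gene_id %in% rownames(counts))
    stop2("driver gene ", cfg$driver_gene_id, " absent from count matrix")
  st <- stratify_by_driver(counts, cfg$driver_gene_id,
                           g_min = cfg$g_min, g_max = cfg$g_max,
                           n_starts = cfg$n_starts,
                           seed = derive_seed(cfg$seed, "strata"),
                           trim_m = cfg$trim_m, trim_a = cfg$trim_a)
  p <- out_path(cfg, "strata.tsv")
  write_strata(st, p)
  invisible(c(strata = p))
}

read_stage_psi_strata <- function(cfg) {
  psi <- read_psi_matrix(need_file(out_path(cfg, "psi.tsv"), "PSI matrix"))
  strata <- read_strata(need_file(out_path(cfg, "strata.tsv"),
                                  "strata table"))
  list(psi = psi, strata = strata)
}

stage_diffsplice <- function(cfg) {
  io <- read_stage_psi_strata(cfg)
  cat_p <- need_file(out_path(cfg, "event_catalog.tsv"), "event catalog")
  log_run(cfg, "diffsplice",
          c(psi = out_path(cfg, "psi.tsv"),
            strata = out_path(cfg, "strata.tsv"), catalog = cat_p))
  catalog <- read_event_catalog(cat_p)
  attr(io$psi, "event_type") <-
    stats::setNames(catalog$event_type, catalog$event_id)[rownames(io$psi)]
  res <- diff_psi(io$psi, io$strata, alpha = cfg$alpha,
                  min_dpsi = cfg$min_dpsi,
                  min_per_group = cfg$min_per_group)
  p <- out_path(cfg, "diff_splicing.tsv")
  write_diff_splicing(res, p)
  invisible(c(diff_splicing = p))
}

stage_composition <- function(cfg) {
  io <- read_stage_psi_strata(cfg)
  cat_p <- need_file(out_path(cfg, "event_catalog.tsv"), "event catalog")
  ds_p <- need_file(out_path(cfg, "diff_splicing.tsv"),
                    "differential splicing table")
  log_run(cfg, "composition",
          c(psi = out_path(cfg, "psi.tsv"),
            strata = out_path(cfg, "strata.tsv"), catalog = cat_p))
  catalog <- read_event_catalog(cat_p)
  prof <- relative_frequency(io$psi, catalog)
  comp <- compare_composition(prof, io$strata, alpha = cfg$alpha,
                              require_both = cfg$require_both_tests)
  ds <- read_tsv(ds_p)
  sig <- ds$event_id[which(as.logical(ds$significant))]
  paths <- c(composition = out_path(cfg, "composition.tsv"),
             comparison = out_path(cfg, "composition_comparison.tsv"),
             spectrum_all = out_path(cfg, "spectrum_all.tsv"),
             spectrum_significant = out_path(cfg, "spectrum_significant.tsv"))
  write_composition(prof, paths["composition"])
  write_tsv(comp, paths["comparison"],
            comments = "per-type relative-frequency comparison, high vs low stratum")
  write_tsv(event_type_spectrum(catalog,
                                intersect(catalog$event_id, rownames(io$psi))),
            paths["spectrum_all"],
            comments = "event-type spectrum: all quantified events")
  write_tsv(event_type_spectrum(catalog, intersect(sig, catalog$event_id)),
            paths["spectrum_significant"],
            comments = "event-type spectrum: significant events")
  invisible(paths)
}

stage_associate <- function(cfg) {
  cnt_p <- need_file(stage_inputs(cfg, "counts", "gene_counts.tsv"),
                     "gene count matrix")
  log_run(cfg, "associate", c(counts = cnt_p))
  counts <- read_matrix_tsv(cnt_p)
  norm <- tmm_normalize(counts, cfg$trim_m, cfg$trim_a)
  lg <- log2(norm$normalized + 1)
  paths <- character()
  if (!is.null(cfg$correlation_pairs)) {
    pairs <- as.matrix(read_tsv(need_file(cfg$correlation_pairs,
                                          "correlation pair table")))
    co <- correlate_genes(lg, pairs)
    paths["correlations"] <- out_path(cfg, "correlations.tsv")
    write_tsv(co, paths["correlations"],
              comments = paste("method:", attr(co, "method")))
  }
  if (!is.null(cfg$gene_sets) && !is.null(cfg$query_genes)) {
    sets <- read_gmt(need_file(cfg$gene_sets, "gene-set GMT"))
    query <- readLines(need_file(cfg$query_genes, "query gene list"))
    query <- query[nzchar(trimws(query))]
    ora <- hypergeometric_ora(query, sets, rownames(counts))
    paths["ora"] <- out_path(cfg, "ora.tsv")
    write_tsv(ora, paths["ora"],
              comments = "hypergeometric over-representation; gene_ratio = hits / in-universe set size")
  }
  if (length(paths) == 0L)
    warning("associate stage: no correlation pairs or gene sets configured")
  invisible(paths)
}

stage_report <- function(cfg) {
  log_run(cfg, "report", character())
  tables <- c("event_catalog.tsv", "psi.tsv", "strata.tsv",
              "diff_splicing.tsv", "composition.tsv",
              "composition_comparison.tsv", "spectrum_all.tsv",
              "spectrum_significant.tsv")
  present <- tables[file.exists(out_path(cfg, tables))]
  summary <- list(outputs = as.list(stats::setNames(
    out_path(cfg, present), present)))
  if ("strata.tsv" %in% present) {
    st <- read_strata(out_path(cfg, "strata.tsv"))
    summary$strata_sizes <- as.list(table(st$labels))
  }
  if ("diff_splicing.tsv" %in% present) {
    ds <- read_tsv(out_path(cfg, "diff_splicing.tsv"))
    summary$n_events_tested <- sum(!is.na(ds$adj_p))
    summary$n_events_significant <- sum(ds$significant %in% c(TRUE, "TRUE"))
  }
  p <- out_path(cfg, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(summary = p))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Convenience wrapper running simulate, events, psi, strata, diffsplice,
#' composition and report in order.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, the report stage's outputs.
#' @export
run_pipeline <- function(cfg) {
  for (s in c("simulate", "events", "psi", "strata", "diffsplice",
              "composition"))
    run_stage(s, cfg)
  run_stage("report", cfg)
}

#' Command-line entry point
#'
#' Invoked by the installed `splicestrata` script as
#' `splicestrata <stage> --config <file> [--seed N] [--outdir D]`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L || args[1] %in% c("-h", "--help")) {
    cat("usage: splicestrata <stage> [--config FILE] [--seed N] [--outdir D]\n",
        "stages:", paste(stage_names(), collapse = ", "), "\n")
    return(invisible(if (length(args) < 1L) 1L else 0L))
  }
  stage <- args[1]
  opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else NULL
  }
  cfg <- if (!is.null(opt("--config"))) read_pipeline_config(opt("--config"))
         else pipeline_config()
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--outdir"))) cfg$outdir <- opt("--outdir")
  run_stage(stage, cfg)
  invisible(0L)
}
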