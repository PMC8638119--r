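#' Specification of a synthetic splicing cohort
#'
#' Defines the stated world the generator emulates: a bulk RNA-seq cohort
#' of ~94 tumor samples whose driver splicing-factor expression follows a
#' 3-component equal-variance Gaussian mixture on the log2 scale, and
#' whose local splicing events shift between the high- and low-driver
#' strata with a type-dependent direction (more exon skipping and
#' alternative 3'/5' splice sites in the high stratum; more mutually
#' exclusive, alternative-first and alternative-last events in the low
#' stratum; retained introns neutral).
#'
#' @param n_samples Cohort size (default 94).
#' @param n_genes Total genes in the count matrix, including the driver
#'   and one gene per planted event (default 300).
#' @param events_per_type Events planted per type; a single number or a
#'   named vector over the 7 types (default 10 each).
#' @param driver_means Mixture component means, log2 per-million scale,
#'   strictly increasing (default c(2, 5, 8)).
#' @param driver_sd Shared component standard deviation (default 0.5).
#' @param driver_weights Component weights (default c(0.3, 0.4, 0.3)).
#' @param shifted_fraction Fraction of each type's events given a
#'   high-stratum PSI shift (default 0.5).
#' @param delta_psi_effect Absolute PSI shift of shifted events in the
#'   high stratum (default 0.3).
#' @param composition_bias Named signed map over the 7 types; the sign
#'   sets each type's shift direction (positive = higher PSI in the high
#'   stratum), zero = random direction per event.
#' @param psi_noise_sd Logit-scale sd of per-sample PSI noise
#'   (default 0.05).
#' @param libsize_range Sequencing library-size range in reads
#'   (default 2e6-5e6).
#' @param seed Master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 94L, n_genes = 300L,
                        events_per_type = 10L,
                        driver_means = c(2, 5, 8), driver_sd = 0.5,
                        driver_weights = c(0.3, 0.4, 0.3),
                        shifted_fraction = 0.5, delta_psi_effect = 0.3,
                        composition_bias = c(SE = 0.08, MX = -0.05,
                                             A5 = 0.05, A3 = 0.05, RI = 0,
                                             AF = -0.05, AL = -0.08),
                        psi_noise_sd = 0.05,
                        libsize_range = c(2e6, 5e6), seed = 1L) {
  if (length(events_per_type) == 1L)
    events_per_type <- stats::setNames(rep(as.integer(events_per_type), 7L),
                                       EVENT_TYPES)
  stopifnot(all(EVENT_TYPES %in% names(events_per_type)),
            all(diff(driver_means) > 0), driver_sd > 0,
            length(driver_weights) == length(driver_means),
            abs(sum(driver_weights) - 1) < 1e-9,
            shifted_fraction >= 0, shifted_fraction <= 1,
            delta_psi_effect >= 0, delta_psi_effect < 0.8,
            all(EVENT_TYPES %in% names(composition_bias)),
            psi_noise_sd > 0, libsize_range[1] > 0,
            libsize_range[2] >= libsize_range[1])
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 events_per_type = events_per_type[EVENT_TYPES],
                 driver_means = driver_means, driver_sd = driver_sd,
                 driver_weights = driver_weights,
                 shifted_fraction = shifted_fraction,
                 delta_psi_effect = delta_psi_effect,
                 composition_bias = composition_bias[EVENT_TYPES],
                 psi_noise_sd = psi_noise_sd,
                 libsize_range = libsize_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Two-isoform templates in transcription-space coordinates, one per event
# type. Each is a list of exon matrices per isoform; `incl` marks the
# isoform that carries the inclusion form under the catalog conventions.
event_templates <- function() {
  ex <- function(...) matrix(c(...), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("start", "end")))
  list(
    SE = list(iso = list(ex(101, 200, 301, 400, 501, 600),
                         ex(101, 200, 501, 600)), incl = 1L),
    MX = list(iso = list(ex(101, 200, 301, 400, 701, 800),
                         ex(101, 200, 501, 600, 701, 800)), incl = 1L),
    A5 = list(iso = list(ex(101, 250, 501, 600),
                         ex(101, 200, 501, 600)), incl = 1L),
    A3 = list(iso = list(ex(101, 200, 451, 600),
                         ex(101, 200, 501, 600)), incl = 1L),
    RI = list(iso = list(ex(101, 600, 801, 900),
                         ex(101, 200, 301, 600, 801, 900)), incl = 1L),
    AF = list(iso = list(ex(101, 200, 501, 600),
                         ex(301, 400, 501, 600)), incl = 1L),
    AL = list(iso = list(ex(101, 200, 301, 400),
                         ex(101, 200, 501, 600)), incl = 1L))
}

#' Generate a synthetic annotation with a planted event catalog
#'
#' Lays out one two-isoform gene per requested event on non-overlapping
#' windows of a synthetic chromosome, half of the genes on each strand
#' (minus-strand genes are coordinate-mirrored within their window), each
#' gene instantiating exactly one local splicing pattern. The returned
#' truth catalog is constructed from the templates, not from detection,
#' so `detect_events()` on the models must reproduce it exactly.
#'
#' @param spec A [cohort_spec()].
#' @return List with `models` (a [transcript_models]) and `truth` (an
#'   [event_catalog]).
#' @export
generate_annotation <- function(spec) {
  tpl <- event_templates()
  window <- 10000L
  models <- list(); rows <- list()
  g <- 0L
  for (ty in EVENT_TYPES) {
    n_ev <- spec$events_per_type[[ty]]
    if (n_ev < 0L) stop2("events_per_type must be >= 0")
    for (e in seq_len(n_ev)) {
      g <- g + 1L
      gene_id <- sprintf("G%s%03d", ty, e)
      strand <- if (g %% 2L == 0L) "-" else "+"
      off <- (g - 1L) * window
      t <- tpl[[ty]]
      tx_ids <- paste0(gene_id, ".t", seq_along(t$iso))
      exo <- lapply(t$iso, function(m) {
        if (strand == "+") m + off
        else {
          fl <- cbind(start = off + window - m[, 2],
                      end = off + window - m[, 1])
          fl[order(fl[, 1]), , drop = FALSE]
        }
      })
      for (i in seq_along(exo))
        models[[length(models) + 1L]] <-
          list(gene_id = gene_id, transcript_id = tx_ids[i], chrom = "chrS",
               strand = strand, exons = exo[[i]])
      rows[[length(rows) + 1L]] <- planted_event_row(
        gene_id, ty, strand, off, window, t, tx_ids)
    }
  }
  models <- transcript_models(models)
  truth <- new_event_catalog(do.call(rbind, c(rows, make.row.names = FALSE)))
  list(models = models, truth = truth)
}

# Truth-catalog row for one planted gene, using the template's known
# defining splice sites (in template tx-space) mapped to genomic.
planted_event_row <- function(gene_id, ty, strand, off, window, t, tx_ids) {
  sites <- switch(ty,
    SE = c(200, 301, 400, 501),
    MX = c(200, 301, 400, 701, 501, 600),
    A5 = c(250, 200, 501),
    A3 = c(200, 451, 501),
    RI = c(101, 200, 301, 600),
    AF = c(101, 200, 301, 400, 501),
    AL = c(200, 301, 400, 501, 600))
  gpos <- if (strand == "+") sites + off else off + window - sites
  sig <- paste(sort(gpos), collapse = "-")
  incl <- tx_ids[t$incl]
  data.frame(
    event_id = sprintf("%s;%s:chrS:%s:%s", gene_id, ty, sig, strand),
    gene_id = gene_id, event_type = ty,
    inclusion_transcripts = incl,
    total_transcripts = paste(sort(tx_ids), collapse = ","),
    defining_coords = sig, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with planted splicing structure
#'
#' Simulates, from one seed: (1) driver expression per sample from the
#' 3-component equal-variance log2 mixture, recording each sample's true
#' stratum; (2) per-event baseline PSI ~ Uniform(0.2, 0.8), a shifted
#' subset (fraction `shifted_fraction` per type, direction from the sign
#' of `composition_bias`, random for unbiased types) whose high-stratum
#' target is baseline +/- `delta_psi_effect` (kept inside [0.05, 0.95]);
#' (3) realized per-sample PSI as logit-normal noise of sd `psi_noise_sd`
#' around the stratum target; (4) transcript TPMs as gene expression split
#' between inclusion and exclusion isoforms according to realized PSI;
#' (5) a gene-level count matrix (driver + event genes + filler genes)
#' with Poisson sampling at library sizes drawn from `libsize_range`.
#'
#' @param spec A [cohort_spec()].
#' @param annotation Result of [generate_annotation()] for the same spec.
#' @return List with `tpm` (transcripts x samples), `counts` (genes x
#'   samples), `driver_gene_id` ("DRIVER"), and `truth` (list: `samples`,
#'   `events`, `catalog`, `psi_target` events x samples).
#' @export
generate_cohort <- function(spec, annotation) {
  set.seed(derive_seed(spec$seed, "cohort"))
  truth_cat <- annotation$truth
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  comp <- sample.int(length(spec$driver_weights), n, replace = TRUE,
                     prob = spec$driver_weights)
  driver_log2 <- stats::rnorm(n, spec$driver_means[comp], spec$driver_sd)
  stratum <- c("low", "intermediate", "high")[comp]

  n_ev <- nrow(truth_cat)
  baseline <- stats::runif(n_ev, 0.2, 0.8)
  shifted <- logical(n_ev); direction <- integer(n_ev)
  for (ty in EVENT_TYPES) {
    idx <- which(truth_cat$event_type == ty)
    ns <- round(spec$shifted_fraction * length(idx))
    if (ns == 0L) next
    sel <- if (length(idx) == 1L) idx else sample(idx, ns)
    shifted[sel] <- TRUE
    b <- spec$composition_bias[[ty]]
    direction[sel] <- if (b > 0) 1L else if (b < 0) -1L else
      sample(c(-1L, 1L), length(sel), replace = TRUE)
  }
  target_high <- baseline
  target_high[shifted] <- pmin(0.95, pmax(0.05,
    baseline[shifted] + direction[shifted] * spec$delta_psi_effect))

  psi_target <- matrix(rep(baseline, n), n_ev, n,
                       dimnames = list(truth_cat$event_id, samples))
  psi_target[, stratum == "high"] <- target_high
  noise <- matrix(stats::rnorm(n_ev * n, 0, spec$psi_noise_sd), n_ev, n)
  psi_real <- stats::plogis(stats::qlogis(psi_target) + noise)

  # transcript TPM: per-gene abundance split by realized PSI
  incl_tx <- lapply(truth_cat$inclusion_transcripts, split_ids)
  tot_tx <- lapply(truth_cat$total_transcripts, split_ids)
  all_tx <- sort(unique(unlist(tot_tx)))
  gene_base_tpm <- exp(stats::rnorm(n_ev, log(30), 0.5))
  tpm <- matrix(0, length(all_tx), n, dimnames = list(all_tx, samples))
  gene_tpm <- gene_base_tpm *
    matrix(exp(stats::rnorm(n_ev * n, 0, 0.2)), n_ev, n)
  for (i in seq_len(n_ev)) {
    inc <- incl_tx[[i]]
    exc <- setdiff(tot_tx[[i]], inc)
    tpm[inc, ] <- tpm[inc, , drop = FALSE] +
      rep(gene_tpm[i, ] * psi_real[i, ] / length(inc),
          each = length(inc))
    tpm[exc, ] <- tpm[exc, , drop = FALSE] +
      rep(gene_tpm[i, ] * (1 - psi_real[i, ]) / length(exc),
          each = length(exc))
  }

  # gene-level counts: driver + event genes + fillers, Poisson at sampled
  # library sizes; expression in per-million units so the driver's
  # normalized log2 value tracks its simulated mixture value
  event_genes <- unique(truth_cat$gene_id)
  n_fill <- max(0L, spec$n_genes - 1L - length(event_genes))
  genes <- c("DRIVER", event_genes, sprintf("FILL%04d", seq_len(n_fill)))
  expr <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  expr["DRIVER", ] <- pmax(2^driver_log2 - 1, 0)  # log2(cpm+1) inverse
  ge <- rowsum(gene_tpm, truth_cat$gene_id)  # per-gene TPM totals
  expr[rownames(ge), ] <- ge
  fill_base <- exp(stats::rnorm(n_fill, log(50), 1.5))
  expr[sprintf("FILL%04d", seq_len(n_fill)), ] <-
    fill_base * matrix(exp(stats::rnorm(n_fill * n, 0, 0.1)), n_fill, n)
  other <- setdiff(genes, "DRIVER")
  expr[other, ] <- sweep(expr[other, , drop = FALSE], 2,
                         (1e6 - expr["DRIVER", ]) /
                           colSums(expr[other, , drop = FALSE]), "*")
  lib <- stats::runif(n, spec$libsize_range[1], spec$libsize_range[2])
  counts <- matrix(stats::rpois(length(genes) * n,
                                sweep(expr, 2, lib / 1e6, "*")),
                   length(genes), n, dimnames = list(genes, samples))

  truth <- list(
    samples = data.frame(sample_id = samples, stratum = stratum,
                         driver_log2 = driver_log2,
                         stringsAsFactors = FALSE),
    events = data.frame(event_id = truth_cat$event_id,
                        event_type = truth_cat$event_type,
                        baseline_psi = baseline, target_high = target_high,
                        shifted = shifted, direction = direction,
                        stringsAsFactors = FALSE),
    catalog = truth_cat, psi_target = psi_target)
  list(tpm = tpm, counts = counts, driver_gene_id = "DRIVER", truth = truth)
}

#' Write a generated cohort to disk
#'
#' Emits the GTF annotation, transcript TPM TSV, gene count TSV, truth
#' tables and a JSON manifest recording the full spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @param annotation From [generate_annotation()].
#' @param cohort From [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(spec, annotation, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.gtf"),
    tpm = file.path(dir, "transcript_tpm.tsv"),
    counts = file.path(dir, "gene_counts.tsv"),
    truth_catalog = file.path(dir, "truth_catalog.tsv"),
    truth_samples = file.path(dir, "truth_samples.tsv"),
    truth_events = file.path(dir, "truth_events.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_gtf(annotation$models, paths["annotation"])
  write_abundance(cohort$tpm, paths["tpm"])
  write_matrix_tsv(cohort$counts, paths["counts"], "gene_id",
                   comments = "simulated gene-level counts")
  write_event_catalog(annotation$truth, paths["truth_catalog"])
  write_tsv(cohort$truth$samples, paths["truth_samples"])
  write_tsv(cohort$truth$events, paths["truth_events"])
  jsonlite::write_json(
    list(generator = "spliceStrata synthetic cohort",
         spec = unclass(spec)),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
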