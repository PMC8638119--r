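#' Per-sample splicing-event composition (relative frequency)
#'
#' For each sample, the relative frequency of event i is
#' `rf(i) = PSI(i) / sum_j PSI(j)`, the sum running over the sample's
#' non-missing events; missing events are excluded from numerator and
#' denominator. Per-type profiles aggregate `rf` over the events of each
#' of the seven types, so `rf_by_type` is an exact partition of
#' `rf_by_event` and both sum to 1 per sample. Samples whose PSI sum is
#' zero yield an all-`NA` profile.
#'
#' @param psi A `psi_matrix` (events x samples).
#' @param catalog An [event_catalog] covering every event in `psi`.
#' @return A `composition_profile` list: `rf_event` (events x samples) and
#'   `rf_type` (7 types x samples).
#' @export
relative_frequency <- function(psi, catalog) {
  if (nrow(psi) == 0L) stop2("empty PSI matrix")
  missing_ev <- setdiff(rownames(psi), catalog$event_id)
  if (length(missing_ev) > 0L)
    stop2("event(s) absent from catalog: ",
          paste(utils::head(missing_ev, 3), collapse = ", "))
  type <- catalog$event_type[match(rownames(psi), catalog$event_id)]
  denom <- colSums(psi, na.rm = TRUE)
  rf <- sweep(psi, 2, denom, "/")
  rf[, denom == 0] <- NA_real_
  rf0 <- rf
  rf0[is.na(rf0)] <- 0
  rf_type <- matrix(0, length(EVENT_TYPES), ncol(rf),
                    dimnames = list(EVENT_TYPES, colnames(rf)))
  agg <- rowsum(rf0, factor(type, levels = EVENT_TYPES))
  rf_type[rownames(agg), ] <- agg
  rf_type[, denom == 0] <- NA_real_
  structure(list(rf_event = rf, rf_type = rf_type),
            class = "composition_profile")
}

#' Compare splicing-event composition between strata
#'
#' For each of the seven event types, tests the per-sample relative
#' frequency (`rf_by_type`) between the high and low strata with a
#' two-sided rank-sum test and a two-sample Kolmogorov-Smirnov test. A
#' type is flagged significant when the rank-sum p-value is below `alpha`
#' (with `require_both = TRUE`, both tests must pass); no multiplicity
#' adjustment is applied across the 7 types by default
#' (`bh_across_types = TRUE` switches it on). Strata with fewer than 3
#' samples yield `NA` tests with a warning.
#'
#' @param profiles A `composition_profile` from [relative_frequency()].
#' @param strata A `strata_assignment` (or list with `labels`).
#' @param alpha Significance cutoff (default 0.05).
#' @param require_both Require both tests below `alpha` (default FALSE).
#' @param bh_across_types Apply BH across the 7 types (default FALSE).
#' @return data.frame with one row per event type: `event_type`,
#'   `mean_rf_high`, `mean_rf_low`, `wilcoxon_p`, `ks_p`, `significant`.
#' @export
compare_composition <- function(profiles, strata, alpha = 0.05,
                                require_both = FALSE,
                                bh_across_types = FALSE) {
  labels <- strata$labels
  rt <- profiles$rf_type
  common <- intersect(colnames(rt), names(labels))
  labels <- labels[common]
  hi <- common[labels == "high"]; lo <- common[labels == "low"]
  if (length(hi) == 0L || length(lo) == 0L)
    stop2("empty low or high stratum")
  small <- length(hi) < 3L || length(lo) < 3L
  if (small)
    warning("stratum with < 3 samples: composition tests reported as NA")
  out <- data.frame(event_type = EVENT_TYPES, mean_rf_high = NA_real_,
                    mean_rf_low = NA_real_, wilcoxon_p = NA_real_,
                    ks_p = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(EVENT_TYPES)) {
    x <- rt[EVENT_TYPES[i], hi]; y <- rt[EVENT_TYPES[i], lo]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) > 0L) out$mean_rf_high[i] <- mean(x)
    if (length(y) > 0L) out$mean_rf_low[i] <- mean(y)
    if (small || length(x) < 3L || length(y) < 3L) next
    out$wilcoxon_p[i] <- rank_sum_test(x, y)$p_value
    out$ks_p[i] <- suppressWarnings(stats::ks.test(x, y)$p.value)
  }
  wp <- out$wilcoxon_p; kp <- out$ks_p
  if (bh_across_types) {
    ok <- !is.na(wp); wp[ok] <- bh_adjust(wp[ok])
    ok <- !is.na(kp); kp[ok] <- bh_adjust(kp[ok])
  }
  out$significant <- if (require_both) wp < alpha & kp < alpha else wp < alpha
  out
}

#' Event-type spectrum of an event set
#'
#' Counts and percentages per event type over a designated subset of the
#' catalog — typically "all detected" versus "significantly different"
#' events, whose diverging spectra summarize how the splicing landscape
#' shifts with driver expression.
#'
#' @param catalog An [event_catalog].
#' @param event_subset Character vector of event ids (must be a subset of
#'   the catalog; default: all events).
#' @return data.frame with `event_type`, `count`, `percent` (percents sum
#'   to 100; all-`NA` for an empty subset).
#' @export
event_type_spectrum <- function(catalog, event_subset = catalog$event_id) {
  unknown <- setdiff(event_subset, catalog$event_id)
  if (length(unknown) > 0L)
    stop2("event(s) not in catalog: ",
          paste(utils::head(unknown, 3), collapse = ", "))
  type <- catalog$event_type[match(event_subset, catalog$event_id)]
  counts <- table(factor(type, levels = EVENT_TYPES))
  n <- sum(counts)
  data.frame(event_type = EVENT_TYPES, count = as.integer(counts),
             percent = if (n == 0L) NA_real_ else 100 * as.integer(counts) / n,
             stringsAsFactors = FALSE)
}

#' Write a per-sample composition table
#'
#' @param profiles A `composition_profile`.
#' @param path TSV path (samples x 7 event types).
#' @return `path`, invisibly.
#' @export
write_composition <- function(profiles, path) {
  write_matrix_tsv(t(profiles$rf_type), path, "sample_id",
                   comments = "per-sample relative frequency of each event type (unitless, rows sum to 1)")
}
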