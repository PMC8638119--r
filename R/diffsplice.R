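#' Two-sided rank-sum (Mann-Whitney) test, normal approximation
#'
#' Computes the Mann-Whitney U statistic and a two-sided p-value from the
#' normal approximation with tie correction and continuity correction.
#' Used per event for differential splicing and per event type for the
#' composition comparison; PSI and relative frequencies are bounded, so a
#' distribution-free location test is the appropriate default.
#'
#' @param x,y Numeric vectors (the two groups).
#' @return List with `statistic` (U for `x`) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(list(statistic = NA_real_, p_value = NA_real_))
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Implements the step-up procedure directly: with order statistics
#' p_(1) <= ... <= p_(m), adjusted p_(i) = min over j >= i of
#' min(1, m p_(j) / j).
#'
#' @param p_values Numeric vector of raw p-values, all in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop2("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Differential splicing between high and low strata
#'
#' For each event, computes delta-PSI (mean PSI in the high stratum minus
#' mean PSI in the low stratum, over non-missing samples) and a two-sided
#' rank-sum p-value, then applies Benjamini-Hochberg adjustment across all
#' tested events. Events with fewer than `min_per_group` non-missing
#' values in either stratum are excluded from testing and reported with
#' `NA` p-values. An event is flagged significant when its adjusted
#' p-value is below `alpha` and |delta-PSI| >= `min_dpsi`. Intermediate
#' samples are ignored.
#'
#' @param psi A `psi_matrix` (events x samples).
#' @param strata A `strata_assignment` (or list with `labels`) covering the
#'   PSI samples.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param min_dpsi Minimum |delta-PSI| for the significance flag
#'   (default 0.1).
#' @param min_per_group Minimum non-missing samples per stratum
#'   (default 5).
#' @return data.frame with columns `event_id`, `event_type`, `delta_psi`,
#'   `p_value`, `adj_p`, `n_high`, `n_low`, `significant`.
#' @export
diff_psi <- function(psi, strata, alpha = 0.05, min_dpsi = 0.1,
                     min_per_group = 5L) {
  labels <- strata$labels
  common <- intersect(colnames(psi), names(labels))
  labels <- labels[common]
  hi <- common[labels == "high"]; lo <- common[labels == "low"]
  if (length(hi) == 0L || length(lo) == 0L)
    stop2("empty low or high stratum")
  et <- attr(psi, "event_type")
  out <- data.frame(
    event_id = rownames(psi),
    event_type = if (is.null(et)) NA_character_ else
      unname(et[rownames(psi)]),
    delta_psi = NA_real_, p_value = NA_real_, adj_p = NA_real_,
    n_high = 0L, n_low = 0L, significant = FALSE,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(psi))) {
    x <- psi[i, hi]; y <- psi[i, lo]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    out$n_high[i] <- length(x); out$n_low[i] <- length(y)
    if (length(x) > 0L && length(y) > 0L)
      out$delta_psi[i] <- mean(x) - mean(y)
    if (length(x) >= min_per_group && length(y) >= min_per_group)
      out$p_value[i] <- rank_sum_test(x, y)$p_value
  }
  tested <- !is.na(out$p_value)
  if (any(tested)) out$adj_p[tested] <- bh_adjust(out$p_value[tested])
  out$significant <- !is.na(out$adj_p) & out$adj_p < alpha &
    !is.na(out$delta_psi) & abs(out$delta_psi) >= min_dpsi
  out
}

#' Write a differential-splicing results table
#'
#' One row per event; `neg_log10_adj_p` is added as a volcano-ready
#' column.
#'
#' @param res Result of [diff_psi()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_diff_splicing <- function(res, path) {
  res$neg_log10_adj_p <- -log10(res$adj_p)
  write_tsv(res, path,
            comments = c("differential splicing, high vs low stratum",
                         "delta_psi: mean PSI(high) - mean PSI(low), unitless"))
}
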