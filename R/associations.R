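#' Gene-gene rank correlations
#'
#' Spearman rank correlation with two-sided p-values for a list of gene
#' pairs on a normalized expression matrix, over pairwise-complete
#' samples. The p-value uses the exact permutation distribution for
#' n <= 9 without ties and the t-approximation otherwise; rank correlation
#' is used because it is invariant to the monotone transforms
#' (log, normalization) typical of expression scales.
#'
#' @param expr Numeric matrix (genes x samples).
#' @param pairs Two-column matrix or data.frame of (gene_a, gene_b) ids.
#' @return data.frame with `gene_a`, `gene_b`, `rho`, `p_value`, `n`, and
#'   a `method` attribute recording the statistic.
#' @export
correlate_genes <- function(expr, pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  out <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                    rho = NA_real_, p_value = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    for (g in pairs[i, ]) if (!g %in% rownames(expr))
      stop2("gene ", g, " absent from expression matrix")
    x <- expr[pairs[i, 1], ]; y <- expr[pairs[i, 2], ]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3L) stop2("pair ", pairs[i, 1], "/", pairs[i, 2],
                      ": fewer than 3 complete samples")
    ties <- anyDuplicated(x[ok]) > 0L || anyDuplicated(y[ok]) > 0L
    ct <- suppressWarnings(stats::cor.test(
      x[ok], y[ok], method = "spearman", exact = (n <= 9L && !ties)))
    out$rho[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
    out$n[i] <- n
  }
  attr(out, "method") <- "spearman rank correlation, two-sided"
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene ids per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop2("malformed GMT line (need name, description, >=1 gene)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Hypergeometric over-representation analysis with gene-ratio summary
#'
#' For each gene set, counts the hits of the query in the set (both
#' restricted to the universe) and computes the upper-tail hypergeometric
#' probability of at least that many hits, with Benjamini-Hochberg
#' adjustment across sets. The `gene_ratio` column is the hits over the
#' in-universe set size — the summary plotted per pathway in
#' gene-set dot plots.
#'
#' @param query_genes Character vector of query gene ids (subset of the
#'   universe; ids outside it are dropped with a warning).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @return data.frame with `set_name`, `hits`, `set_size`, `gene_ratio`,
#'   `p_value`, `adj_p`.
#' @export
hypergeometric_ora <- function(query_genes, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop2("empty universe")
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    hits <- length(intersect(query, s))
    p <- if (length(s) == 0L) 1 else
      stats::phyper(hits - 1, length(s), length(universe) - length(s),
                    length(query), lower.tail = FALSE)
    data.frame(set_name = nm, hits = hits, set_size = length(s),
               gene_ratio = if (length(s) == 0L) NA_real_ else hits / length(s),
               p_value = min(1, max(p, .Machine$double.xmin)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- if (nrow(out) > 0L) bh_adjust(out$p_value) else numeric()
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Immunohistochemistry combined score
#'
#' Semiquantitative H-score-like measure: the percentage of positive cells
#' is binned (0% = 0; (0,25] = 1; (25,50] = 2; (50,75] = 3; (75,100] = 4)
#' and multiplied by the staining intensity (none = 0, weak = 1,
#' moderate = 2, strong = 3), giving a score from 0 to 12.
#'
#' @param percent_positive Percentage of positive cells in `[0, 100]`
#'   (vectorized).
#' @param intensity Integer intensity grade in `{0, 1, 2, 3}` (vectorized).
#' @return Integer score(s) in `[0, 12]`.
#' @export
ihc_combined_score <- function(percent_positive, intensity) {
  p <- as.numeric(percent_positive); it <- as.numeric(intensity)
  if (anyNA(p) || any(p < 0 | p > 100))
    stop2("percent_positive must lie in [0, 100]")
  if (anyNA(it) || any(it != as.integer(it)) || any(it < 0 | it > 3))
    stop2("intensity must be an integer in {0, 1, 2, 3}")
  bin <- findInterval(p, c(0, 25, 50, 75), left.open = TRUE)
  as.integer(bin * it)
}
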