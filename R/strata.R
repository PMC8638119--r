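#' TMM normalization of a gene-level expression matrix
#'
#' Computes per-sample trimmed-mean-of-M-values scaling factors against a
#' reference sample (the one whose upper-quartile of library-scaled counts
#' is closest to the mean upper-quartile). For each sample, genes zero in
#' either the sample or the reference are removed, gene-wise log2 ratios
#' (M) and average log2 abundances (A) are double-trimmed (`trim_m` of the
#' M distribution from each tail, `trim_a` of A), and the factor is the
#' weighted mean of the surviving M values with inverse asymptotic-variance
#' weights. Factors are rescaled to geometric mean 1; the normalized matrix
#' is counts-per-million on the effective library size
#' (library sum x factor).
#'
#' @param expr Numeric matrix (genes x samples) of non-negative counts or
#'   abundances, >= 2 samples, each with a positive column sum.
#' @param trim_m Fraction of the M distribution trimmed from each tail
#'   (default 0.30).
#' @param trim_a Fraction of the A distribution trimmed from each tail
#'   (default 0.05).
#' @return List with `factors` (named per-sample factors, geometric mean 1),
#'   `normalized` (TMM-normalized per-million matrix) and `ref_sample`.
#' @export
tmm_normalize <- function(expr, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2L) stop2("TMM needs >= 2 samples")
  if (any(!is.finite(expr)) || any(expr < 0))
    stop2("expression values must be finite and non-negative")
  lib <- colSums(expr)
  if (any(lib <= 0)) stop2("sample(s) with zero library sum: ",
                           paste(colnames(expr)[lib <= 0], collapse = ", "))
  # genes zero in every sample carry no ratio information; dropping them
  # up front also makes the factors invariant to all-zero padding
  xx <- expr[rowSums(expr > 0) > 0L, , drop = FALSE]
  q75 <- apply(sweep(xx, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(xx)), function(k) {
    tmm_pair_factor(xx[, k], xx[, ref], lib[k], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(expr)
  eff <- lib * f
  normalized <- sweep(expr, 2, eff / 1e6, "/")
  list(factors = f, normalized = normalized,
       ref_sample = colnames(expr)[ref] %||% ref)
}

# One sample's TMM factor against the reference (Robinson-Oshlack).
tmm_pair_factor <- function(y, yr, n, nr, trim_m, trim_a) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0L) return(1)
  m <- log2((y / n) / (yr / nr))
  a <- 0.5 * log2((y / n) * (yr / nr))
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  if (max(abs(m)) < 1e-6) return(1)
  # rank-based double trim, as in the canonical implementation
  nn <- length(m)
  lo_m <- floor(nn * trim_m) + 1; hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * trim_a) + 1; hi_a <- nn + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  f <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(f)) 1 else f
}

#' Fit a univariate equal-variance Gaussian mixture with BIC selection
#'
#' For each number of components G in `g_min:g_max`, runs EM on the
#' one-dimensional equal-variance ("E"-type) Gaussian mixture from
#' `n_starts` deterministic initializations (quantile-spread means plus
#' seeded perturbations) and keeps the best log-likelihood; the returned
#' fit is the G minimizing BIC = -2 loglik + k log(n) with k = 2G free
#' parameters (G means, G-1 weights, one shared variance).
#'
#' @param values Numeric vector of per-sample expression values (typically
#'   log2 TMM-normalized per-million + 1).
#' @param g_min,g_max Component-count search range (defaults 1 and 5).
#' @param n_starts EM starts per G (default 8).
#' @param seed Integer seed controlling the perturbed starts.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return A `gmm_fit` list: `n_components`, `means` (sorted), `shared_sd`,
#'   `weights`, `loglik`, `bic`, `converged`, `bic_by_g`.
#' @export
fit_gmm_equal_variance <- function(values, g_min = 1L, g_max = 5L,
                                   n_starts = 8L, seed = 1L,
                                   max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x))) stop2("values must be finite, no NA")
  n <- length(x)
  n_distinct <- length(unique(x))
  if (g_min < 1L || g_max < g_min) stop2("need 1 <= g_min <= g_max")
  if (n_distinct < 2L) stop2("degenerate input: all values identical")
  if (n_distinct < g_min) stop2("fewer distinct values (", n_distinct,
                                ") than g_min components (", g_min, ")")
  fits <- list()
  for (G in seq(g_min, min(g_max, n_distinct))) {
    # short-run multistart (as in standard mixture software): each start
    # gets a capped EM, only the best is polished to full convergence
    best <- NULL
    for (s in seq_len(n_starts)) {
      init <- gmm_init(x, G, start = s, seed = seed)
      fit <- gmm_em(x, init, max_iter = min(75L, max_iter), tol = tol)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (!best$converged)
      best <- gmm_em(x, list(means = best$means, sd = best$shared_sd,
                             weights = best$weights),
                     max_iter = max_iter, tol = tol)
    best$bic <- -2 * best$loglik + (2 * G) * log(n)
    fits[[as.character(G)]] <- best
  }
  bics <- vapply(fits, `[[`, 0, "bic")
  out <- fits[[which.min(bics)]]
  out$bic_by_g <- bics
  structure(out, class = "gmm_fit")
}

gmm_init <- function(x, G, start, seed) {
  mu <- as.numeric(stats::quantile(x, probs = (seq_len(G) - 0.5) / G))
  if (start > 1L) {
    r <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
              else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
      set.seed(derive_seed(seed, paste0("gmm-start-", G, "-", start)))
      stats::rnorm(G)
    })
    mu <- mu + r * stats::sd(x) / 2
  }
  list(means = sort(mu), sd = stats::sd(x), weights = rep(1 / G, G))
}

gmm_em <- function(x, init, max_iter, tol) {
  n <- length(x); G <- length(init$means)
  mu <- init$means; sdev <- max(init$sd, 1e-6); w <- init$weights
  ll_old <- -Inf; converged <- FALSE
  resp <- matrix(1, n, 1)
  lc <- -0.5 * log(2 * pi)
  logd <- matrix(0, n, G)
  for (it in seq_len(max_iter)) {
    # log joint densities, n x G, via plain column arithmetic (hot loop)
    cst <- log(w) + lc - log(sdev)
    inv2 <- 0.5 / (sdev * sdev)
    for (g in seq_len(G)) {
      d <- x - mu[g]
      logd[, g] <- cst[g] - inv2 * (d * d)
    }
    mx <- logd[, 1L]
    if (G > 1L) for (g in 2:G) mx <- pmax.int(mx, logd[, g])
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    if (ll + 1e-9 < ll_old)
      stop2("EM log-likelihood decreased (internal error)")
    resp <- exp(logd - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
    nk <- pmax.int(.colSums(resp, n, G), 1e-12)
    mu <- .colSums(resp * x, n, G) / nk
    var_ <- 0
    for (g in seq_len(G)) {
      d <- x - mu[g]
      var_ <- var_ + sum(resp[, g] * d * d)
    }
    sdev <- sqrt(max(var_ / n, 1e-12))
    w <- nk / n
  }
  o <- order(mu)
  list(n_components = G, means = mu[o], shared_sd = sdev,
       weights = w[o] / sum(w), loglik = ll_old, converged = converged,
       responsibilities = resp[, o, drop = FALSE])
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("equal-variance Gaussian mixture: G = %d (BIC %.2f)\n",
              x$n_components, x$bic))
  cat("  means:", paste(sprintf("%.3f", x$means), collapse = ", "),
      " shared sd:", sprintf("%.3f", x$shared_sd),
      " weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Assign samples to expression strata from a mixture fit
#'
#' Each sample is assigned to its maximum-posterior component (posterior
#' ties broken toward the lower-mean component); the lowest-mean component
#' is labelled `low`, the highest-mean `high`, anything in between
#' `intermediate`. Downstream group tests use only the low and high strata.
#'
#' @param fit A `gmm_fit` with >= 2 components.
#' @param values Numeric vector of sample expression values; names (if any)
#'   become sample ids.
#' @return A `strata_assignment` list: `labels` (factor low/intermediate/
#'   high per sample), `component` (1-based, by increasing mean),
#'   `posterior` (samples x components) and `fit`.
#' @export
assign_strata <- function(fit, values) {
  if (fit$n_components < 2L) stop2("no strata separable: mixture has G = 1")
  x <- as.numeric(values)
  G <- fit$n_components
  logd <- vapply(seq_len(G), function(g)
    log(fit$weights[g]) + stats::dnorm(x, fit$means[g], fit$shared_sd,
                                       log = TRUE), numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  post <- exp(logd - apply(logd, 1, max))
  post <- post / rowSums(post)
  comp <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])
  lab <- rep("intermediate", length(x))
  lab[comp == 1L] <- "low"
  lab[comp == G] <- "high"
  labels <- factor(lab, levels = c("low", "intermediate", "high"))
  names(labels) <- names(values)
  rownames(post) <- names(values)
  if (!any(labels == "low") || !any(labels == "high"))
    warning("empty low or high stratum in assignment")
  structure(list(labels = labels, component = comp, posterior = post,
                 fit = fit), class = "strata_assignment")
}

#' @export
print.strata_assignment <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

#' Write/read a strata assignment table
#'
#' TSV columns: `sample_id`, `label`, then one posterior column per
#' component (`posterior_1` = lowest mean, upwards).
#'
#' @param strata A `strata_assignment`.
#' @param path TSV path.
#' @return `path` invisibly, or for the reader a list with `labels` and
#'   `posterior` (the mixture fit itself is not serialized).
#' @export
write_strata <- function(strata, path) {
  post <- strata$posterior
  colnames(post) <- paste0("posterior_", seq_len(ncol(post)))
  df <- data.frame(sample_id = names(strata$labels),
                   label = as.character(strata$labels), post,
                   stringsAsFactors = FALSE, check.names = FALSE)
  write_tsv(df, path,
            comments = "driver-expression strata; posteriors per mixture component (ascending mean)")
}

#' @rdname write_strata
#' @export
read_strata <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop2("strata table ", path, " lacks sample_id/label columns")
  bad <- setdiff(unique(df$label), c("low", "intermediate", "high"))
  if (length(bad) > 0L) stop2("unknown stratum label(s): ",
                              paste(bad, collapse = ", "))
  labels <- factor(df$label, levels = c("low", "intermediate", "high"))
  names(labels) <- df$sample_id
  pc <- grep("^posterior_", names(df))
  post <- as.matrix(df[, pc, drop = FALSE])
  rownames(post) <- df$sample_id
  list(labels = labels, posterior = post)
}

#' Stratify samples by a driver gene's normalized expression
#'
#' Convenience wrapper chaining [tmm_normalize()], a `log2(x + 1)`
#' transform of the driver gene's per-million expression,
#' [fit_gmm_equal_variance()] and [assign_strata()].
#'
#' @param expr Gene-level matrix (genes x samples).
#' @param driver_gene_id Row name of the driver gene.
#' @param g_min,g_max,n_starts,seed Passed to [fit_gmm_equal_variance()].
#' @param trim_m,trim_a Passed to [tmm_normalize()].
#' @return A `strata_assignment`; the driver's normalized values are
#'   attached as attribute `driver_values`.
#' @export
stratify_by_driver <- function(expr, driver_gene_id, g_min = 1L, g_max = 5L,
                               n_starts = 8L, seed = 1L,
                               trim_m = 0.30, trim_a = 0.05) {
  if (!driver_gene_id %in% rownames(expr))
    stop2("driver gene ", driver_gene_id, " absent from expression matrix")
  norm <- tmm_normalize(expr, trim_m = trim_m, trim_a = trim_a)
  v <- log2(norm$normalized[driver_gene_id, ] + 1)
  fit <- fit_gmm_equal_variance(v, g_min = g_min, g_max = g_max,
                                n_starts = n_starts, seed = seed)
  if (fit$n_components < 2L)
    stop2("no strata separable: BIC selected a single component")
  st <- assign_strata(fit, v)
  attr(st, "driver_values") <- v
  st
}
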