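typed_catalog <- function(types) {
  new_cat <- data.frame(
    event_id = paste0("e", seq_along(types)),
    gene_id = paste0("g", seq_along(types)),
    event_type = types,
    inclusion_transcripts = "t1", total_transcripts = "t1,t2",
    defining_coords = as.character(seq_along(types)),
    stringsAsFactors = FALSE)
  structure(new_cat, class = c("event_catalog", "data.frame"))
}

psi_mat <- function(values, types, n_samples = 1,
                    samples = paste0("S", seq_len(n_samples))) {
  m <- matrix(values, length(types), length(samples),
              dimnames = list(paste0("e", seq_along(types)), samples))
  class(m) <- c("psi_matrix", class(m))
  m
}

test_that("relative frequency implements PSI / sum(PSI)", {
  cat2 <- typed_catalog(c("SE", "RI"))
  pr <- relative_frequency(psi_mat(c(0.2, 0.8), c("SE", "RI")), cat2)
  expect_equal(unname(pr$rf_event[, 1]), c(0.2, 0.8))  # denominator is 1
  # equal PSI -> uniform composition
  cat4 <- typed_catalog(rep("SE", 4))
  pr2 <- relative_frequency(psi_mat(rep(0.3, 4), rep("SE", 4)), cat4)
  expect_equal(unname(pr2$rf_event[, 1]), rep(0.25, 4))
  # hand evaluation of the printed formula with per-type aggregation
  cat_h <- typed_catalog(c("SE", "SE", "RI", "AL"))
  pr3 <- relative_frequency(psi_mat(c(0.5, 0.5, 1.0, 0),
                                    c("SE", "SE", "RI", "AL")), cat_h)
  expect_equal(unname(pr3$rf_type[c("SE", "RI", "AL"), 1]), c(0.5, 0.5, 0))
  other <- typed_catalog(c("SE", "RI"))
  other$event_id <- c("x1", "x2")
  expect_error(relative_frequency(psi_mat(0.5, "SE"), other), "absent")
})

test_that("composition profiles conserve mass and partition by type", {
  set.seed(4)
  types <- sample(event_types(), 30, TRUE)
  m <- psi_mat(runif(30 * 12), types, n_samples = 12)
  m[sample(length(m), 40)] <- NA
  pr <- relative_frequency(m, typed_catalog(types))
  sums <- colSums(pr$rf_event, na.rm = TRUE)
  expect_equal(unname(sums), rep(1, 12), tolerance = 1e-9)
  expect_equal(unname(colSums(pr$rf_type)), rep(1, 12), tolerance = 1e-9)
  # rf_by_type is an exact partition of rf_by_event
  for (ty in unique(types)) {
    expect_equal(
      unname(pr$rf_type[ty, ]),
      unname(colSums(pr$rf_event[types == ty, , drop = FALSE], na.rm = TRUE)),
      tolerance = 1e-12)
  }
  # all-zero PSI sample yields an all-missing profile
  m0 <- psi_mat(rep(0, 3), c("SE", "MX", "RI"), n_samples = 2)
  m0[, 2] <- 0.5
  pr0 <- relative_frequency(m0, typed_catalog(c("SE", "MX", "RI")))
  expect_true(all(is.na(pr0$rf_event[, 1])))
  expect_false(anyNA(pr0$rf_event[, 2]))
})

test_that("removing an event rescales remaining rf proportionally", {
  set.seed(5)
  types <- rep(event_types(), 2)
  m <- psi_mat(runif(14 * 6, 0.1, 0.9), types, n_samples = 6)
  pr_full <- relative_frequency(m, typed_catalog(types))
  m2 <- m[-1, , drop = FALSE]
  class(m2) <- class(m)
  cat2 <- typed_catalog(types)[-1, ]
  pr_red <- relative_frequency(m2, cat2)
  scale <- 1 - pr_full$rf_event[1, ]
  expect_equal(pr_red$rf_event,
               sweep(pr_full$rf_event[-1, ], 2, scale, "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("compare_composition: identical strata profiles are never called", {
  types <- rep(event_types(), 3)
  set.seed(6)
  half <- matrix(runif(21 * 8, 0.1, 0.9), 21, 8)
  m <- psi_mat(cbind(half, half), types, samples = paste0("S", 1:16))
  st <- list(labels = factor(setNames(rep(c("high", "low"), each = 8),
                                      colnames(m)),
                             levels = c("low", "intermediate", "high")))
  res <- compare_composition(relative_frequency(m, typed_catalog(types)), st)
  expect_true(all(res$wilcoxon_p >= 0.05))
  expect_false(any(res$significant))
  expect_equal(res$mean_rf_high, res$mean_rf_low)
})

test_that("tiny strata yield NA tests with a warning", {
  types <- event_types()
  set.seed(7)
  m <- psi_mat(runif(7 * 42, 0.1, 0.9), types, n_samples = 42)
  st <- list(labels = factor(setNames(c(rep("high", 2), rep("low", 40)),
                                      colnames(m)),
                             levels = c("low", "intermediate", "high")))
  expect_warning(
    res <- compare_composition(relative_frequency(m, typed_catalog(types)), st),
    "< 3 samples")
  expect_true(all(is.na(res$wilcoxon_p)))
  expect_true(all(is.na(res$ks_p)))
})

test_that("permuted labels are called at ~alpha rate (permutation null)", {
  set.seed(12)
  types <- rep(event_types(), 4)
  m <- psi_mat(runif(28 * 60, 0.1, 0.9), types, n_samples = 60)
  pr <- relative_frequency(m, typed_catalog(types))
  x <- pr$rf_type["SE", ]
  hits <- 0L
  for (b in 1:1000) {
    idx <- sample(60, 30)
    hits <- hits + (rank_sum_test(x[idx], x[-idx])$p_value < 0.05)
  }
  expect_gte(hits / 1000, 0.03)
  expect_lte(hits / 1000, 0.07)
})

test_that("event_type_spectrum counts and percents", {
  types <- c(rep("SE", 4), "MX", "A5", "A3", "RI", "AF", "AL")
  cat10 <- typed_catalog(types)
  sp <- event_type_spectrum(cat10)
  expect_equal(sp$count[sp$event_type == "SE"], 4L)
  expect_equal(sp$percent[sp$event_type == "SE"], 40)
  expect_equal(sum(sp$percent), 100, tolerance = 1e-6)
  sub <- event_type_spectrum(cat10, cat10$event_id[1:2])
  expect_equal(sum(sub$count), 2L)
  empty <- event_type_spectrum(cat10, character())
  expect_equal(sum(empty$count), 0L)
  expect_true(all(is.na(empty$percent)))
  expect_error(event_type_spectrum(cat10, "nope"), "not in catalog")
})
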