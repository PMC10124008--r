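tbl <- function(...) {
  vals <- list(...)
  out <- tibble::tibble(sample_id = paste0("s", seq_along(vals[[1]])))
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}

test_that("log2/quotient normalization matches hand-computed values", {
  # constant feature maps to ones: log2(4,4,4) = (2,2,2), mean 2
  out <- normalize_abundance(tbl(a = c(4, 4, 4)),
                             pseudocount_policy = "fixed", pseudocount = 0)
  expect_equal(out$a, c(1, 1, 1))
  # (1,2,4): logs (0,1,2), mean 1
  out <- normalize_abundance(tbl(a = c(1, 2, 4)),
                             pseudocount_policy = "fixed", pseudocount = 0)
  expect_equal(out$a, c(0, 1, 2))
})

test_that("normalization stays finite with zeros under half_min_nonzero", {
  out <- normalize_abundance(tbl(a = c(0, 2, 4), b = c(1, 1, 2)))
  expect_true(all(is.finite(as.matrix(out[-1]))))
  expect_error(normalize_abundance(tbl(a = c(0, 0, 0), b = c(1, 2, 3))),
               "all-zero")
  expect_error(
    normalize_abundance(tbl(a = c(0, 2, 4)),
                        pseudocount_policy = "fixed", pseudocount = 0),
    "pseudocount"
  )
})

test_that("doubling a feature adds exactly 1 to every pre-quotient log", {
  withr::local_seed(5)
  x <- runif(20, 0.5, 4)
  base <- log2(x)
  doubled <- log2(2 * x)
  expect_equal(doubled, base + 1)
  # and the quotient output equals the hand-derived rescaling
  out2 <- normalize_abundance(tbl(a = 2 * x),
                              pseudocount_policy = "fixed", pseudocount = 0)
  expect_equal(out2$a, (base + 1) / abs(mean(base + 1)))
})

test_that("normalization preserves each feature's orientation", {
  # relative-abundance logs are negative; larger abundance must still map
  # to a larger normalized value
  x <- c(1e-4, 1e-3, 1e-2)
  out <- normalize_abundance(tbl(a = x),
                             pseudocount_policy = "fixed", pseudocount = 0)
  expect_true(all(diff(out$a) > 0))
})

test_that("quotient-then-log order is available and monotone", {
  x <- c(1, 2, 4)
  out <- normalize_abundance(tbl(a = x), pseudocount_policy = "fixed",
                             pseudocount = 0, log_first = FALSE)
  expect_equal(out$a, log2(x / mean(x)))
})

test_that("prevalence filter applies the per-group conjunction rule", {
  d <- tbl(
    f1 = c(1, 1, 0, 0, 1, 1, 0, 0),   # 2/4 in each group: kept at 0.5
    f2 = c(1, 1, 1, 1, 1, 0, 0, 0),   # 4/4 in A but 1/4 in B: dropped
    f3 = rep(1, 8)                    # everywhere
  )
  g <- rep(c("A", "B"), each = 4)
  out <- suppressMessages(filter_prevalence(d, g, min_fraction = 0.5))
  expect_equal(names(out)[-1], c("f1", "f3"))
  rep_tbl <- prevalence_report(out)
  expect_equal(nrow(rep_tbl), 6)
  expect_false(rep_tbl$kept[rep_tbl$feature_id == "f2"][1])
  expect_error(suppressMessages(filter_prevalence(d, rep("A", 7))),
               "every sample")
})

test_that("min_fraction = 1 keeps exactly the all-nonzero features", {
  withr::local_seed(11)
  m <- matrix(rbinom(200, 1, 0.8) * runif(200), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  d <- tibble::add_column(tibble::as_tibble(m),
                          sample_id = paste0("s", 1:20), .before = 1)
  g <- rep(c("A", "B"), each = 10)
  out <- suppressMessages(filter_prevalence(d, g, min_fraction = 1))
  expect_setequal(names(out)[-1], colnames(m)[colSums(m > 0) == 20])
})

test_that("prevalence filter is idempotent", {
  co <- tiny_cohort(seed = 4, n_taxa = 25)
  ab <- co$abundance
  ab[2:11] <- lapply(ab[2:11], function(x) ifelse(x < median(x), 0, x))
  g <- co$metadata$subject_id
  once <- suppressMessages(filter_prevalence(ab, g))
  twice <- suppressMessages(filter_prevalence(once, g))
  expect_equal(names(twice), names(once))
  expect_identical(as.matrix(twice[-1]), as.matrix(once[-1]))
})

test_that("horizon transform centers on the median with MAD band width", {
  h <- horizon_transform(c(1, 2, 3, 4, 5))
  expect_equal(h$centered, c(-2, -1, 0, 1, 2))
  expect_equal(h$band_width, 1)
  hc <- horizon_transform(rep(3, 5))
  expect_equal(hc$centered, rep(0, 5))
  expect_equal(hc$band_width, 0)
  # shift invariance and exact zero median
  withr::local_seed(6)
  x <- rnorm(15)
  h1 <- horizon_transform(x)
  h2 <- horizon_transform(x + 17.3)
  expect_equal(h2$centered, h1$centered)
  expect_equal(h2$band_width, h1$band_width)
  expect_equal(median(h1$centered), 0)
  expect_error(horizon_transform(1), "length")
})

test_that("horizon_panel centers per subject when metadata is given", {
  co <- tiny_cohort(seed = 5, n_taxa = 10)
  long <- horizon_panel(co$panel, co$metadata)
  meds <- long |>
    dplyr::group_by(.data$factor, .data$subject_id) |>
    dplyr::summarise(m = median(centered), .groups = "drop")
  expect_true(all(abs(meds$m) < 1e-12))
})
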