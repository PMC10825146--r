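make_records <- function() {
  data.frame(
    sample_id = paste0("s", 1:5),
    condition = c("c1", "c2", "c3", "c4", "c5"),
    n_replicates = c(4, 3, 6, 5, 4),
    n_passed_qc = c(2, 3, 3, 3, 4),
    is_outlier = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    tas = c(0.30, 0.9, 0.8, 0.9, 0.29),
    stringsAsFactors = FALSE)
}

test_that("replicate/QC/TAS filtering keeps exactly the qualifying records", {
  recs <- make_records()
  # independent enumeration of the stated predicate
  expected <- recs$n_replicates >= 4 &
    recs$n_passed_qc >= ceiling(recs$n_replicates / 2) &
    !recs$is_outlier & recs$tas >= 0.3
  kept <- filter_l1000(recs)
  expect_identical(kept$sample_id, recs$sample_id[expected])
  expect_identical(sum(expected), 2L)   # s1 (boundary TAS) and s3
  # boundary: TAS exactly at the threshold is retained, just below is not
  expect_true("s1" %in% kept$sample_id)    # tas = 0.30
  expect_false("s5" %in% kept$sample_id)   # tas = 0.29
})

test_that("exemplar selection keeps only the max-TAS technical replicate", {
  recs <- data.frame(sample_id = c("a", "b", "c"),
                     condition = c("c1", "c1", "c2"),
                     n_replicates = 4, n_passed_qc = 4, is_outlier = FALSE,
                     tas = c(0.5, 0.8, 0.4))
  kept <- filter_l1000(recs)
  expect_identical(kept$sample_id, c("b", "c"))
})

test_that("filtering is idempotent and controls skip the TAS rule", {
  recs <- make_records()
  once <- filter_l1000(recs)
  expect_identical(filter_l1000(once), once)
  recs$is_control <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  kept <- filter_l1000(recs)
  expect_true("s5" %in% kept$sample_id)  # control retained despite tas 0.29
})

test_that("missing TAS raises an error naming the sample", {
  recs <- make_records()
  recs$tas[2] <- NA
  expect_error(filter_l1000(recs), "s2")
})

test_that("count log transform is exact, monotone and invertible", {
  x <- matrix(c(0, 9, 99, 999), 2, 2)
  expect_equal(log_transform_counts(x), matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(log_transform_counts(matrix(-1)), "non-negative")
  set.seed(1)
  counts <- matrix(rpois(50, 20), 10, 5)
  lt <- log_transform_counts(counts)
  expect_equal(inv_log_transform_counts(lt), counts, tolerance = 1e-10)
  ord <- order(counts)
  expect_identical(order(lt), ord)  # monotone
})

test_that("serology preprocessing standardizes per feature", {
  set.seed(2)
  X <- matrix(rnorm(60, mean = 3), 20, 3)
  Z <- preprocess_serology(X, mode = "human")
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-9)
})

test_that("NHP serology preprocessing matches the three-step formula", {
  mfi <- matrix(c(0, 9, 99,
                  9, 99, 999), 3, 2)
  controls <- matrix(c(0, 9, 9, 99), 2, 2)
  out <- preprocess_serology(mfi, controls, mode = "nhp")
  # independent evaluation: log10(x+1), subtract control medians, z-score
  ref <- log10(mfi + 1)
  ref <- sweep(ref, 2, apply(log10(controls + 1), 2, median))
  ref <- scale(ref)
  expect_equal(out, ref, ignore_attr = TRUE, tolerance = 1e-12)
  # MFI = 0 maps to 0 before centering
  expect_equal(log10(0 + 1), 0)
})

test_that("zero-variance features are rejected by name", {
  X <- cbind(f_ok = rnorm(10), f_flat = rep(2, 10))
  expect_error(preprocess_serology(X, mode = "human"), "f_flat")
})

test_that("pair index enumerates exactly the cross-system same-condition pairs", {
  m <- matrix(0, 2, 2)
  meta <- data.frame(sample_id = c("x", "y"), system = c("A", "B"),
                     perturbagen = "drugA", dose = "1uM", time = "24h")
  ds <- omics_dataset(rbind(m, m)[1:2, ], meta)
  pi1 <- build_pair_index(ds)
  expect_identical(nrow(pi1$positive_pairs), 1L)

  # no shared conditions: empty pairs and an all-zero mask
  meta2 <- data.frame(sample_id = c("x", "y"), system = c("A", "B"),
                      condition = c("c1", "c2"))
  pi2 <- build_pair_index(omics_dataset(matrix(0, 2, 2), meta2))
  expect_identical(nrow(pi2$positive_pairs), 0L)
  expect_true(all(pair_mask(pi2) == 0))
})

test_that("pair count equals the product count over shared keys", {
  meta <- data.frame(
    sample_id = paste0("s", 1:7),
    system = c("A", "A", "A", "B", "B", "B", "B"),
    condition = c("c1", "c2", "c3", "c1", "c2", "c2", "c9"))
  ds <- omics_dataset(matrix(0, 7, 2), meta)
  pi <- build_pair_index(ds)
  # brute-force enumeration oracle
  n_expected <- 0L
  for (i in 1:7) for (j in 1:7) {
    if (i < j && meta$system[i] != meta$system[j] &&
        meta$condition[i] == meta$condition[j]) n_expected <- n_expected + 1L
  }
  expect_identical(nrow(pi$positive_pairs), n_expected)
  expect_identical(n_expected, 3L)  # c1: 1x1, c2: 1x2
})

test_that("pairing is symmetric under system relabeling", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     system = c("A", "A", "A", "B", "B", "B"),
                     condition = c("c1", "c2", "c3", "c1", "c2", "c4"))
  ds <- omics_dataset(matrix(0, 6, 2), meta)
  m1 <- pair_mask(build_pair_index(ds))
  meta$system <- ifelse(meta$system == "A", "B", "A")
  m2 <- pair_mask(build_pair_index(omics_dataset(matrix(0, 6, 2), meta)))
  expect_equal(m1, m2)           # mask is symmetric in the labels
  expect_equal(m1, t(m1))        # and in the pair ordering
  expect_true(all(diag(m1) == 0))
})

test_that("condition keys normalize case and whitespace but not units", {
  expect_identical(condition_key("DrugA", " 1uM", "24h"),
                   condition_key("druga", "1um ", "24H"))
  expect_false(condition_key("d", "1uM", "24h") ==
                 condition_key("d", "1000nM", "24h"))
})
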