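test_that("signature extraction cuts 100-sample windows at clean peaks", {
  x <- matrix(rnorm(56 * 300), 56)
  rec <- structure(list(samples = x, sampling_rate_hz = 30000, t0_s = 0,
                        referenced = TRUE, event_peaks = integer(0),
                        snr_db = NULL), class = "multichannel_recording")
  sigs <- extract_signatures(rec, c(50L, 150L))
  expect_length(sigs, 2L)
  expect_equal(dim(sigs[[1]]), c(56L, 100L))
  # peak at sample 50 gives the window [1, 100]
  expect_equal(sigs[[1]], x[, 1:100])
  # 49 samples before, 50 after the peak
  expect_equal(sigs[[2]], x[, (150 - 49):(150 + 50)])
  # an event too close to the edge is skipped with a warning
  expect_warning(short <- extract_signatures(rec, c(30L, 150L)), "skipped 1")
  expect_length(short, 1L)
})

test_that("dataset normalization scales to a global max magnitude of exactly 1", {
  arr <- array(rnorm(56 * 100 * 9), dim = c(56, 100, 9))
  ds <- signature_dataset(arr, rep(c("tibial", "peroneal", "sural"), 3))
  nds <- normalize_dataset(ds)
  expect_equal(max(abs(nds$signatures)), 1, tolerance = 1e-12)
  expect_gte(min(nds$signatures), -1)
  expect_equal(nds$normalization_constant, max(abs(arr)))
  # scale equivariance: scaling the raw data leaves the output unchanged
  ds5 <- signature_dataset(5 * arr, ds$labels)
  expect_equal(normalize_dataset(ds5)$signatures, nds$signatures)
  # an already-normalized dataset passes through with constant 1
  again <- normalize_dataset(nds)
  expect_equal(again$normalization_constant, 1)
  expect_equal(again$signatures, nds$signatures)
  zero <- signature_dataset(arr * 0, ds$labels)
  expect_error(normalize_dataset(zero), "all-zero")
})

test_that("channel reordering is the documented slot-major permutation", {
  p_sp <- reorder_permutation("spatial")
  expect_equal(p_sp, 1:56)
  p_tm <- reorder_permutation("temporal")
  expect_equal(sort(p_tm), 1:56) # bijection on rows
  # raw row (r, s) [0-based] must land at position s * 7 + r
  for (r in 0:6) {
    for (s in 0:7) {
      expect_equal(p_tm[s * 7 + r + 1], r * 8 + s + 1)
    }
  }
  sig <- matrix(seq_len(5600), 56, 100)
  tm <- reorder_signature(sig, "temporal")
  # row multiset preserved; applying the inverse permutation restores
  expect_equal(tm[order(p_tm), ], sig)
  expect_false(isTRUE(all.equal(reorder_signature(tm, "temporal"), sig)))
  expect_error(reorder_signature(sig, "backwards"))
})

test_that("fold assignment is stratified, disjoint, exhaustive and seeded", {
  labels <- rep(c("tibial", "peroneal", "sural"), each = 100)
  f1 <- assign_folds(labels, 5L, seed = 9L)
  f2 <- assign_folds(labels, 5L, seed = 9L)
  f3 <- assign_folds(labels, 5L, seed = 10L)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_equal(sort(unique(f1)), 1:5)
  # every fold holds the same count from each class
  tab <- table(labels, f1)
  expect_true(all(tab == 20))
  expect_error(assign_folds(rep(c("a", "b"), c(3, 100)), 5L, 1L),
               "at least")
})

test_that("interpolated datasets are exact at the endpoints and convex between", {
  ds_a <- micro_dataset(-5, fill = 0)
  ds_b <- micro_dataset(-5, fill = 1)
  expect_equal(interpolate_datasets(ds_a, ds_b, 0)$signatures,
               ds_a$signatures)
  expect_equal(interpolate_datasets(ds_a, ds_b, 1)$signatures,
               ds_b$signatures)
  half <- interpolate_datasets(ds_a, ds_b, 0.5)
  expect_equal(half$signatures, (ds_a$signatures + ds_b$signatures) / 2)
  lo <- pmin(ds_a$signatures, ds_b$signatures)
  hi <- pmax(ds_a$signatures, ds_b$signatures)
  for (alpha in c(0.25, 0.75)) {
    mid <- interpolate_datasets(ds_a, ds_b, alpha)$signatures
    expect_true(all(mid >= lo - 1e-12 & mid <= hi + 1e-12))
  }
  # labels and folds inherited; mismatches rejected
  expect_identical(half$labels, ds_a$labels)
  expect_identical(half$folds, ds_a$folds)
  ds_c <- dataset_subset(ds_b, seq_len(n_signatures(ds_b) - 3L))
  expect_error(interpolate_datasets(ds_a, ds_c, 0.5), "correspond")
  expect_error(interpolate_datasets(ds_a, ds_b, 1.5), "\\[0, 1\\]")
})

test_that("generated time-point datasets correspond one-to-one across fills", {
  ds_a <- micro_dataset(-5, fill = 0)
  ds_b <- micro_dataset(-5, fill = 1)
  expect_identical(as.character(ds_a$labels), as.character(ds_b$labels))
  expect_identical(ds_a$folds, ds_b$folds)
  expect_equal(dim(ds_a$signatures), dim(ds_b$signatures))
  # stratified folds at the micro scale: 9 per class per fold
  expect_true(all(table(ds_a$labels, ds_a$folds) == 9))
})

test_that("dataset summaries tabulate classes by fold with the dataset tags", {
  ds <- micro_dataset(-5)
  s <- dataset_summary(ds)
  expect_equal(sum(s$n), n_signatures(ds))
  expect_true(all(s$n[s$fold %in% 1:5] == 9))
  expect_equal(unique(s$timepoint_id), ds$timepoint_id)
  path <- tempfile(fileext = ".csv")
  dataset_summary(ds, path)
  expect_equal(utils::read.csv(path)$n, s$n)
})
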