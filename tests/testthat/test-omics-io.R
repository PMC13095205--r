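test_that("reading a delimited table records missing cells and round-trips", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.txt")
  writeLines(c("SAMPLE_ID\tf1\tf2",
               "S1\t1.5\t2",
               "S2\tNA\t0.25",
               "S3\t3\t4"), path)
  m <- read_omics_table(path, "CNA")
  expect_s3_class(m, "omics_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m$missing_mask), 1L)
  expect_true(m$missing_mask["S2", "f1"])
  expect_true(is.na(m$values["S2", "f1"]))

  # bit-exact write -> read round trip
  set.seed(42)
  toy <- toy_matrix(4, 5, seed = 1)
  toy$values[2, 3] <- NA
  toy$missing_mask[2, 3] <- TRUE
  p2 <- file.path(dir, "rt.txt")
  write_omics_table(toy, p2)
  back <- read_omics_table(p2, "CNA")
  expect_identical(back$values, toy$values)
  expect_identical(back$missing_mask, toy$missing_mask)
})

test_that("reader rejects degenerate or corrupt input", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.txt")
  file.create(empty)
  expect_error(read_omics_table(empty, "CNA"), "empty")
  bad <- file.path(dir, "bad.txt")
  writeLines(c("SAMPLE_ID\tf1", "S1\toops"), bad)
  expect_error(read_omics_table(bad, "CNA"), "non-numeric")
  dup <- file.path(dir, "dup.txt")
  writeLines(c("SAMPLE_ID\tf1\tf1", "S1\t1\t2"), dup)
  expect_error(read_omics_table(dup, "CNA"), "duplicate feature")
})

test_that("sample-id truncation keeps 12 characters and flags collisions", {
  expect_equal(truncate_sample_ids("TCGA-CS-4938-01"), "TCGA-CS-4938")
  expect_equal(truncate_sample_ids("ABC"), "ABC")
  expect_error(truncate_sample_ids(c("TCGA-CS-4938-01", "TCGA-CS-4938-06")),
               "collide")
})

test_that("deduplication keeps the last occurrence", {
  v <- matrix(1:8, 4, 2, dimnames = list(c("A", "B", "A", "C"), c("f1", "f2")))
  m <- structure(list(values = v, modality = "CNA",
                      missing_mask = matrix(FALSE, 4, 2)),
                 class = "omics_matrix")
  out <- dedup_samples(m)
  expect_equal(rownames(out$values), c("B", "A", "C"))
  expect_equal(out$values["A", "f1"], 3)  # last occurrence retained
})

test_that("missing/zero filter cascade matches hand-enumerated fractions", {
  # 100-sample feature with 11 missing (11% > 10%) is dropped
  set.seed(5)
  v <- matrix(rnorm(100 * 2) + 10, 100, 2,
              dimnames = list(sprintf("S%03d", 1:100), c("f_drop", "f_keep")))
  v[1:11, 1] <- NA
  out <- filter_and_impute(omics_matrix(v, "MET"))
  expect_equal(colnames(out$values), "f_keep")
  expect_identical(out$values[, "f_keep"], v[, "f_keep"])

  # 10-sample toy, hand-enumerated fractions:
  #  f1: 2/10 missing (0.2 > 0.1) -> dropped by the missing filter
  #  f2: 1/10 missing (kept), 2/10 zeros elsewhere -> imputation makes
  #      3/10 zeros, 0.3 > 0.1 -> dropped by the zero filter
  #  f3: clean -> kept
  v2 <- matrix(1, 10, 3,
               dimnames = list(sprintf("S%02d", 1:10), c("f1", "f2", "f3")))
  v2[1:2, 1] <- NA
  v2[1, 2] <- NA
  v2[2:3, 2] <- 0
  out2 <- filter_and_impute(omics_matrix(v2, "CNA"))
  expect_equal(colnames(out2$values), "f3")
  cnt <- attr(out2, "filter_counts")
  expect_equal(unname(cnt["dropped_missing"]), 1)
  expect_equal(unname(cnt["dropped_zero"]), 1)

  # boundary: exactly 10% missing (1/10) and 10% zeros is retained
  v3 <- matrix(2, 10, 1, dimnames = list(sprintf("S%02d", 1:10), "f1"))
  v3[1, 1] <- NA
  out3 <- filter_and_impute(omics_matrix(v3, "CNA"))
  expect_equal(ncol(out3$values), 1L)
  expect_equal(out3$values[1, 1], 0)  # imputed with zero

  # everything filtered is an error
  v4 <- matrix(0, 10, 1, dimnames = list(sprintf("S%02d", 1:10), "f1"))
  expect_error(filter_and_impute(omics_matrix(v4, "CNA")), "all")
})

test_that("filter_and_impute is idempotent", {
  set.seed(11)
  m <- toy_matrix(20, 15, seed = 11)
  m$values[sample(length(m$values), 25)] <- NA
  m$missing_mask <- is.na(m$values)
  once <- filter_and_impute(m)
  twice <- filter_and_impute(once)
  expect_identical(twice$values, once$values)
})

test_that("sample alignment keeps the labeled intersection, sorted", {
  ids_all <- sprintf("TCGA-AA-%04d", 1:7)
  mk <- function(ids, modality) {
    v <- matrix(seq_along(ids), length(ids), 1,
                dimnames = list(ids, paste0(modality, "_f1")))
    omics_matrix(v, modality)
  }
  # 5 shared ids; CNA has one extra, MET another extra
  mats <- list(CNA = mk(ids_all[c(5, 1:4, 6)], "CNA"),
               MET = mk(ids_all[c(1:5, 7)], "MET"),
               mRNA = mk(ids_all[1:5], "mRNA"),
               RPPA = mk(ids_all[1:5], "RPPA"))
  clinical <- data.frame(PATIENT_ID = ids_all,
                         SUBTYPE = c("L1", "L2", "", "L1", "L2", "L1", "L1"))
  ds <- align_samples(mats, clinical)
  # id 3 has empty SUBTYPE; ids 6,7 miss modalities -> 4 survivors, sorted
  expect_equal(ds$sample_ids, ids_all[c(1, 2, 4, 5)])
  expect_equal(as.character(ds$labels), c("L1", "L2", "L1", "L2"))
  for (m in ds$omics) expect_equal(sample_ids(m), ds$sample_ids)

  # no overlap at all is an error
  mats2 <- mats
  mats2$RPPA <- mk("TCGA-ZZ-9999", "RPPA")
  expect_error(align_samples(mats2, clinical), "no samples")
})

test_that("clinical survival columns are parsed with event semantics", {
  ids <- sprintf("P%02d", 1:4)
  mk <- function(modality) {
    v <- matrix(rnorm(4), 4, 1, dimnames = list(ids, paste0(modality, "_f")))
    omics_matrix(v, modality)
  }
  clinical <- data.frame(PATIENT_ID = ids, SUBTYPE = "A",
                         OS_MONTHS = c("12.5", "3", "[Not Available]", "8"),
                         OS_STATUS = c("1:DECEASED", "0:LIVING", "DECEASED", "1"))
  ds <- align_samples(list(CNA = mk("CNA")), clinical)
  expect_equal(ds$survival$time, c(12.5, 3, NA, 8))
  expect_equal(ds$survival$event, c(1, 0, NA, 1))
})

test_that("stratified folds balance classes and partition the cohort", {
  labels <- factor(rep(c("a", "b"), each = 5))
  sp <- make_splits(labels, n_folds = 5, seed = 1)
  tab <- table(labels, sp$fold_of)
  expect_true(all(tab == 1))  # one of each class per fold

  labels2 <- factor(rep(c("a", "b", "c"), times = c(30, 20, 10)))
  sp2 <- make_splits(labels2, n_folds = 5, seed = 2)
  tab2 <- table(labels2, sp2$fold_of)
  expect_true(all(tab2["a", ] == 6))
  expect_true(all(tab2["b", ] == 4))
  expect_true(all(tab2["c", ] == 2))
  # partition: every sample in exactly one fold
  expect_equal(sum(tabulate(sp2$fold_of, 5)), 60L)

  # determinism
  expect_identical(make_splits(labels2, 5, seed = 2)$fold_of, sp2$fold_of)
  expect_false(identical(make_splits(labels2, 5, seed = 3)$fold_of, sp2$fold_of))

  expect_error(make_splits(factor(c("a", "b")), n_folds = 5), "exceeds")
})

test_that("holdout mode yields a stratified 75/25 split", {
  labels <- factor(rep(c("a", "b"), times = c(40, 20)))
  sp <- make_splits(labels, seed = 4, mode = "holdout")
  expect_equal(sp$test_folds, 1L)
  expect_equal(sum(sp$fold_of == 1), 15)  # 25% of 60
  expect_equal(sum(sp$fold_of == 1 & labels == "a"), 10)
  expect_equal(sum(sp$fold_of == 1 & labels == "b"), 5)
})

test_that("feature standardisation uses training statistics only", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
              dimnames = list(c("S1", "S2", "S3"), c("f1", "f2")))
  z <- standardize_features(v)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(z[, "f1"]), c(-1, 0, 1))  # sd(1,2,3) = 1
  expect_equal(unname(z[, "f2"]), c(0, 0, 0))   # constant -> 0
  # applied to new data with train statistics
  new <- matrix(c(4, 6), 1, 2, dimnames = list("S9", c("f1", "f2")))
  z2 <- standardize_features(v, new)
  expect_equal(unname(z2[1, ]), c((4 - 2) / 1, 0))
})

test_that("dataset bundles round-trip through the on-disk format", {
  ds <- small_cohort(n = 24, seed = 9, missing_rate = 0)
  dir <- withr::local_tempdir()
  write_dataset_bundle(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_dataset_bundle(dir)
  expect_equal(back$sample_ids, ds$sample_ids)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$omics$mRNA$values, ds$omics$mRNA$values)
  expect_equal(back$survival$time, ds$survival$time, tolerance = 1e-12)
  expect_equal(back$survival$event, ds$survival$event)
})
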