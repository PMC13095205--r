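# Reading, cleaning and aligning multi-omics cohorts (cBioPortal-style
# delimited exports): id truncation and dedup, the missing/zero feature
# filter cascade, cross-omics sample alignment, fold assignment and
# per-fold feature standardisation.

MISSING_TOKENS <- c("", "NA", "NaN", "[Not Available]")

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read one omics matrix from a delimited text file
#'
#' Reads a cBioPortal-style numeric table (tab- or comma-delimited, header row
#' plus an id column). Cells equal to the recognised missing tokens (empty,
#' `NA`, `NaN`, `[Not Available]`) become missing; they are recorded in the
#' `missing_mask` and left as `NA` in `values` until [filter_and_impute()].
#'
#' @param path Path to the file.
#' @param modality Modality label for the resulting matrix.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`
#'   (the cBioPortal `data_*.txt` convention); the matrix is returned
#'   samples-by-features either way.
#' @return An [omics_matrix()].
#' @export
read_omics_table <- function(path, modality,
                             sep = NULL,
                             orientation = c("samples_in_rows", "features_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) stop("no data rows/columns in ", path)
  ids <- df[[1]]
  hdr <- colnames(df)[-1]   # before subsetting: `[.data.frame` mangles dups
  body <- as.matrix(df[, -1, drop = FALSE])
  colnames(body) <- hdr
  miss <- matrix(is.na(body) | body %in% MISSING_TOKENS,
                 nrow(body), ncol(body))
  num <- suppressWarnings(array(as.numeric(body), dim(body)))
  bad <- !miss & is.na(num)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell \"%s\" at row %d, column \"%s\" of %s",
                 body[i[1], i[2]], i[1], colnames(body)[i[2]], path))
  }
  num[miss] <- NA_real_
  rownames(num) <- ids
  colnames(num) <- colnames(body)
  if (orientation == "features_in_rows") num <- t(num)
  if (anyDuplicated(colnames(num)))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(colnames(num)[duplicated(colnames(num))]), collapse = ", "))
  omics_matrix(num, modality)
}

#' Write one omics matrix to a delimited text file
#'
#' Inverse of [read_omics_table()] (samples in rows); originally-missing cells
#' are written as `NA`. Values are written with 17 significant digits so a
#' write-read round trip is bit-exact.
#'
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_omics_table <- function(x, path, sep = "\t") {
  v <- x$values
  chr <- matrix(formatC(v, digits = 17, format = "g"), nrow(v), ncol(v))
  chr[x$missing_mask | is.na(v)] <- "NA"
  out <- cbind(SAMPLE_ID = rownames(v), chr)
  colnames(out) <- c("SAMPLE_ID", colnames(v))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Truncate sample identifiers to their first 12 characters
#'
#' TCGA-style barcodes carry sample/portion suffixes; truncation to 12
#' characters maps them to patient-level ids (e.g. `TCGA-CS-4938-01` to
#' `TCGA-CS-4938`). Ids shorter than 12 characters are unchanged. Duplicate
#' ids after truncation are an error (dedup with [dedup_samples()] upstream).
#'
#' @param ids Character vector of sample ids.
#' @return Character vector of truncated ids.
#' @export
truncate_sample_ids <- function(ids) {
  out <- substr(ids, 1L, 12L)
  if (anyDuplicated(out)) {
    dup <- unique(out[duplicated(out)])
    stop("sample ids collide after truncation: ", paste(dup, collapse = ", "))
  }
  out
}

#' Drop duplicated samples, retaining the last occurrence
#'
#' @param x An [omics_matrix()].
#' @param ids Optional ids to deduplicate on (default the matrix's row names);
#'   useful to dedup on truncated ids before applying [truncate_sample_ids()].
#' @return An [omics_matrix()] with duplicates removed (last kept).
#' @export
dedup_samples <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- rownames(x$values)
  keep <- !duplicated(ids, fromLast = TRUE)
  omics_matrix(x$values[keep, , drop = FALSE], x$modality,
               x$missing_mask[keep, , drop = FALSE])
}

#' Filter features by missingness and zero-fraction, imputing the remainder
#'
#' Applies the preprocessing cascade in fixed order: (1) drop features whose
#' missing fraction strictly exceeds `missing_frac`; (2) impute remaining
#' missing cells with zero; (3) drop features whose post-imputation fraction
#' of zero values strictly exceeds `zero_frac` (such features carry little
#' variability). Exactly 10% missing or zero is retained. The operation is
#' idempotent.
#'
#' @param x An [omics_matrix()].
#' @param missing_frac Maximum tolerated missing fraction, in `(0, 1]`
#'   (default 0.10).
#' @param zero_frac Maximum tolerated zero fraction, in `(0, 1]`
#'   (default 0.10).
#' @return An [omics_matrix()] with no missing values; surviving feature
#'   order is preserved. Attribute `filter_counts` records how many features
#'   each step removed.
#' @export
filter_and_impute <- function(x, missing_frac = 0.10, zero_frac = 0.10) {
  stopifnot(missing_frac > 0, missing_frac <= 1, zero_frac > 0, zero_frac <= 1)
  v <- x$values
  mask <- x$missing_mask | is.na(v)
  fm <- colMeans(mask)
  keep1 <- fm <= missing_frac
  v <- v[, keep1, drop = FALSE]
  mask <- mask[, keep1, drop = FALSE]
  v[mask] <- 0
  fz <- colMeans(v == 0)
  keep2 <- fz <= zero_frac
  v <- v[, keep2, drop = FALSE]
  mask <- mask[, keep2, drop = FALSE]
  if (ncol(v) == 0)
    stop(sprintf("all %s features removed by the missing/zero filters",
                 x$modality))
  out <- omics_matrix(v, x$modality, mask)
  attr(out, "filter_counts") <- c(
    input = ncol(x$values),
    dropped_missing = sum(!keep1),
    dropped_zero = sum(!keep2),
    retained = ncol(v))
  out
}

parse_os_status <- function(status) {
  s <- trimws(as.character(status))
  ifelse(is.na(s) | s %in% MISSING_TOKENS, NA_real_,
         ifelse(grepl("DECEASED", s, ignore.case = TRUE) | s %in% c("1", "1.0"),
                1, 0))
}

#' Align omics matrices with clinical subtype labels
#'
#' Keeps the intersection of samples present in every omics matrix and having
#' a non-missing `SUBTYPE` in the clinical table (samples lacking any modality
#' or a subtype annotation are excluded), then sorts samples
#' lexicographically so every component shares one consistent order.
#' Overall-survival columns (`OS_MONTHS`, `OS_STATUS`), when present, are
#' attached; `OS_STATUS` values containing `DECEASED` (or equal to 1) count
#' as events.
#'
#' @param matrices Named list of [omics_matrix()] objects with truncated,
#'   deduplicated sample ids.
#' @param clinical `data.frame` with columns `PATIENT_ID`, `SUBTYPE` and
#'   optionally `OS_MONTHS`, `OS_STATUS`. Empty strings, `NA`, `NaN` and
#'   `[Not Available]` count as missing subtypes.
#' @return A [multiomics_dataset()].
#' @export
align_samples <- function(matrices, clinical) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            all(c("PATIENT_ID", "SUBTYPE") %in% names(clinical)))
  clin <- clinical[!duplicated(clinical$PATIENT_ID, fromLast = TRUE), , drop = FALSE]
  subtype <- trimws(as.character(clin$SUBTYPE))
  labeled <- !(is.na(clin$SUBTYPE) | subtype %in% MISSING_TOKENS)
  clin <- clin[labeled, , drop = FALSE]
  ids <- Reduce(intersect, lapply(matrices, sample_ids))
  ids <- intersect(ids, clin$PATIENT_ID)
  if (length(ids) == 0)
    stop("no samples shared by all omics matrices and the labeled clinical table")
  ids <- sort(ids, method = "radix")
  omics <- lapply(matrices, function(m)
    omics_matrix(m$values[ids, , drop = FALSE], m$modality,
                 m$missing_mask[ids, , drop = FALSE]))
  clin <- clin[match(ids, clin$PATIENT_ID), , drop = FALSE]
  labels <- factor(trimws(as.character(clin$SUBTYPE)))
  survival <- NULL
  if (all(c("OS_MONTHS", "OS_STATUS") %in% names(clin))) {
    time <- suppressWarnings(as.numeric(as.character(clin$OS_MONTHS)))
    event <- parse_os_status(clin$OS_STATUS)
    bad <- is.na(time) | time <= 0 | is.na(event)
    time[bad] <- NA_real_
    event[bad] <- NA_real_
    survival <- data.frame(time = time, event = event)
  }
  multiomics_dataset(omics, labels, survival)
}

#' Assign samples to cross-validation folds or a holdout split
#'
#' Deterministic given `seed`. In stratified mode each class is shuffled and
#' dealt round-robin, so per-class fold counts differ by at most one sample;
#' classes with fewer samples than folds simply miss some folds. `"holdout"`
#' mode produces a single stratified 75/25 train/test split instead
#' (fold 1 = test).
#'
#' @param labels A factor of per-sample labels, or a [multiomics_dataset()].
#' @param n_folds Number of folds (default 5; ignored in holdout mode).
#' @param seed Integer seed.
#' @param stratified Stratify folds by label (default `TRUE`).
#' @param mode `"cv"` (default) or `"holdout"`.
#' @param test_frac Test fraction for holdout mode (default 0.25).
#' @return An object of class `"split_plan"`: a list with `fold_of` (named
#'   integer vector; in cv mode fold `f` is the test set of run `f`, in
#'   holdout mode 1 = test, 2 = train), `test_folds`, `n_folds`,
#'   `stratified`, `mode` and `seed`.
#' @export
make_splits <- function(labels, n_folds = 5, seed = 1, stratified = TRUE,
                        mode = c("cv", "holdout"), test_frac = 0.25) {
  mode <- match.arg(mode)
  if (inherits(labels, "multiomics_dataset")) labels <- labels$labels
  labels <- as.factor(labels)
  n <- length(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (mode == "cv") {
    stopifnot(n_folds >= 2)
    if (n_folds > n) stop("n_folds exceeds the number of samples")
  }
  set.seed(stage_seed(seed, paste0("splits_", mode)))
  fold_of <- integer(n)
  if (mode == "cv") {
    if (stratified) {
      off <- 0L
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- ((seq_along(idx) - 1L + off) %% n_folds) + 1L
        off <- (off + length(idx)) %% n_folds
      }
    } else {
      idx <- sample.int(n)
      fold_of[idx] <- ((seq_len(n) - 1L) %% n_folds) + 1L
    }
    test_folds <- seq_len(n_folds)
  } else {
    n_folds <- 2L
    fold_of[] <- 2L
    if (stratified) {
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        n_test <- round(length(idx) * test_frac)
        fold_of[idx[sample.int(length(idx))][seq_len(n_test)]] <- 1L
      }
    } else {
      fold_of[sample.int(n)[seq_len(round(n * test_frac))]] <- 1L
    }
    test_folds <- 1L
  }
  if (any(tabulate(fold_of, n_folds) == 0))
    stop("a fold is empty; reduce n_folds")
  names(fold_of) <- ids
  structure(list(fold_of = fold_of, n_folds = as.integer(n_folds),
                 test_folds = test_folds, stratified = stratified,
                 mode = mode, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s, %d folds%s, seed %d\n", x$mode, x$n_folds,
              if (x$stratified) " (stratified)" else "", x$seed))
  print(table(fold = x$fold_of))
  invisible(x)
}

#' Z-score features using training-fold statistics
#'
#' Each feature is centred and scaled by the mean and standard deviation
#' computed on `train` only, preventing test-fold statistics from leaking
#' into preprocessing. Constant features (sd 0) map to 0.
#'
#' @param train [omics_matrix()] (or plain matrix) providing the statistics.
#' @param apply_to Matrix to transform (default `train`); must share
#'   `train`'s feature ids.
#' @return The transformed object, same type as `apply_to`.
#' @export
standardize_features <- function(train, apply_to = train) {
  tv <- if (inherits(train, "omics_matrix")) train$values else train
  av <- if (inherits(apply_to, "omics_matrix")) apply_to$values else apply_to
  if (!identical(colnames(tv), colnames(av)))
    stop("`train` and `apply_to` must share feature ids")
  mu <- colMeans(tv)
  sdv <- apply(tv, 2, stats::sd)
  z <- sweep(av, 2, mu, "-")
  ok <- sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2, sdv[ok], "/")
  z[, !ok] <- 0
  if (inherits(apply_to, "omics_matrix"))
    omics_matrix(z, apply_to$modality, apply_to$missing_mask)
  else z
}

#' Write an aligned dataset to a directory bundle
#'
#' Writes one tab-delimited matrix per modality (`data_<modality>.txt`,
#' samples in rows), a clinical table (`clinical.txt` with `PATIENT_ID`,
#' `SUBTYPE`, `OS_MONTHS`, `OS_STATUS`) and a `manifest.json` with shapes and
#' any filter provenance counts. [generate_cohort()] output written this way
#' is a drop-in stand-in for a downloaded cohort.
#'
#' @param dataset A [multiomics_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(dataset$omics))
    write_omics_table(dataset$omics[[nm]], file.path(dir, paste0("data_", nm, ".txt")))
  surv <- dataset$survival
  clin <- data.frame(PATIENT_ID = dataset$sample_ids,
                     SUBTYPE = as.character(dataset$labels),
                     OS_MONTHS = if (is.null(surv)) NA else surv$time,
                     OS_STATUS = if (is.null(surv)) NA else
                       ifelse(is.na(surv$event), "NA",
                              ifelse(surv$event == 1, "1:DECEASED", "0:LIVING")))
  utils::write.table(clin, file.path(dir, "clinical.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    n_samples = length(dataset$sample_ids),
    modalities = lapply(dataset$omics, function(m)
      list(features = ncol(m$values),
           filter_counts = as.list(attr(m, "filter_counts")))),
    classes = as.list(table(dataset$labels)),
    has_survival = !is.null(surv))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset_bundle()]
#'
#' @param dir Bundle directory.
#' @return A [multiomics_dataset()].
#' @export
read_dataset_bundle <- function(dir) {
  files <- list.files(dir, pattern = "^data_.*\\.txt$", full.names = TRUE)
  if (length(files) == 0) stop("no data_*.txt matrices in ", dir)
  mods <- sub("^data_(.*)\\.txt$", "\\1", basename(files))
  matrices <- Map(read_omics_table, files, mods)
  names(matrices) <- mods
  std <- intersect(omics_modalities(), mods)
  matrices <- matrices[c(std, setdiff(mods, std))]
  clinical <- utils::read.table(file.path(dir, "clinical.txt"), header = TRUE,
                                sep = "\t", check.names = FALSE,
                                colClasses = "character")
  align_samples(matrices, clinical)
}
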