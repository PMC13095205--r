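#' Omics modality names understood by the package
#'
#' @return Character vector of the four modality codes: copy-number
#'   alteration, DNA methylation, mRNA expression and protein array.
#' @export
omics_modalities <- function() c("CNA", "MET", "mRNA", "RPPA")

#' Construct a single-modality omics matrix
#'
#' Wraps a numeric samples-by-features matrix together with its modality and
#' an optional mask of originally-missing cells. Row names are sample ids,
#' column names are feature ids; both must be unique.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   unique row and column names. Missing cells may be `NA`.
#' @param modality One of [omics_modalities()], or another single string for
#'   non-standard layers.
#' @param missing_mask Optional logical matrix of the same shape; `TRUE` marks
#'   a cell that was missing in the source data. Defaults to `is.na(values)`.
#' @return An object of class `"omics_matrix"`.
#' @export
omics_matrix <- function(values, modality, missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  if (!identical(dim(missing_mask), dim(values)))
    stop("`missing_mask` shape must match `values`")
  structure(list(values = values,
                 modality = as.character(modality)[1],
                 missing_mask = missing_mask),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d samples x %d features (%d missing cells)\n",
              x$modality, nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample ids carried by a container
#'
#' @param x An [omics_matrix()], [multiomics_dataset()], [affinity_graph()]
#'   or [latent_embedding()].
#' @return Character vector of sample ids, in storage order.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.omics_matrix <- function(x) rownames(x$values)
#' @export
sample_ids.multiomics_dataset <- function(x) x$sample_ids
#' @export
sample_ids.affinity_graph <- function(x) rownames(x$weights)
#' @export
sample_ids.latent_embedding <- function(x) rownames(x$values)

#' Construct an aligned multi-omics dataset
#'
#' Bundles one [omics_matrix()] per modality with per-sample subtype labels
#' and optional overall-survival data. All components must carry identical
#' sample ids in identical order.
#'
#' @param omics Named list of [omics_matrix()] objects (typically the four
#'   modalities of [omics_modalities()]).
#' @param labels Factor (or coercible) of subtype labels, one per sample, in
#'   the shared sample order.
#' @param survival Optional `data.frame` with columns `time` (positive,
#'   months) and `event` (0/1), one row per sample.
#' @return An object of class `"multiomics_dataset"`.
#' @export
multiomics_dataset <- function(omics, labels, survival = NULL) {
  if (!is.list(omics) || length(omics) < 1)
    stop("`omics` must be a non-empty list of omics_matrix objects")
  if (is.null(names(omics)) || anyDuplicated(names(omics)))
    stop("`omics` must be a uniquely named list")
  ids <- sample_ids(omics[[1]])
  for (m in omics) {
    if (!inherits(m, "omics_matrix")) stop("every element of `omics` must be an omics_matrix")
    if (!identical(sample_ids(m), ids))
      stop("all omics matrices must share identical sample ids in identical order")
  }
  labels <- as.factor(labels)
  if (length(labels) != length(ids)) stop("one label per sample required")
  if (anyNA(labels)) stop("every sample must have a subtype label")
  names(labels) <- ids
  if (!is.null(survival)) {
    if (!all(c("time", "event") %in% names(survival)))
      stop("`survival` needs `time` and `event` columns")
    if (nrow(survival) != length(ids)) stop("one survival row per sample required")
    ok <- !is.na(survival$time)
    if (any(survival$time[ok] <= 0)) stop("survival times must be positive")
    if (!all(survival$event[!is.na(survival$event)] %in% c(0, 1)))
      stop("survival events must be 0/1")
    rownames(survival) <- ids
  }
  structure(list(omics = omics, labels = labels, survival = survival,
                 sample_ids = ids),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  dims <- vapply(x$omics, function(m) ncol(m$values), integer(1))
  cat(sprintf("<multiomics_dataset> %d samples, %d classes (%s)\n",
              length(x$sample_ids), nlevels(x$labels),
              paste(table(x$labels), collapse = "/")))
  cat("  modalities:",
      paste(sprintf("%s[%d]", names(x$omics), dims), collapse = " "), "\n")
  if (!is.null(x$survival))
    cat(sprintf("  survival: %d events / %d samples\n",
                sum(x$survival$event, na.rm = TRUE), nrow(x$survival)))
  invisible(x)
}

#' Construct a patient-patient affinity graph
#'
#' @param weights Symmetric non-negative numeric matrix with sample ids as
#'   dimnames.
#' @param k Neighbour count used to build the graph.
#' @param modality Modality label, or `"fused"` for an SNF consensus graph.
#' @return An object of class `"affinity_graph"`.
#' @export
affinity_graph <- function(weights, k, modality) {
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-10,
                        check.attributes = FALSE)))
    stop("`weights` must be symmetric")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be finite and non-negative")
  if (is.null(rownames(weights))) stop("`weights` must carry sample ids as dimnames")
  colnames(weights) <- rownames(weights)
  structure(list(weights = weights, k = as.integer(k),
                 modality = as.character(modality)[1]),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  w <- x$weights; diag(w) <- 0
  cat(sprintf("<affinity_graph> %s: %d nodes, %d edges (k = %d)\n",
              x$modality, nrow(w), sum(w[upper.tri(w)] > 0), x$k))
  invisible(x)
}

#' Construct a latent embedding
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids).
#' @param source Short tag recording which stage produced the embedding,
#'   e.g. `"AE"`, `"JK_mRNA"`, `"JK_patient"` or `"final"`.
#' @return An object of class `"latent_embedding"`.
#' @export
latent_embedding <- function(values, source) {
  if (!is.matrix(values) || !is.numeric(values)) stop("`values` must be a numeric matrix")
  if (any(!is.finite(values))) stop("embedding values must be finite")
  if (is.null(rownames(values))) stop("`values` must have sample ids as rownames")
  structure(list(values = values, source = as.character(source)[1]),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("<latent_embedding> %s: %d samples x %d dims\n",
              x$source, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.latent_embedding <- function(x) dim(x$values)
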