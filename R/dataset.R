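#' Construct a multi-modal dataset
#'
#' Bundles two or more feature-by-sample numeric matrices measured on the same
#' ordered set of samples into a single object, together with an observation
#' mask. Missing entries are encoded as `NA` in the matrices (equivalently,
#' zeros in the mask); a whole modality may be missing for a subject.
#'
#' @param modalities a list of numeric matrices, each with features in rows
#'   and samples in columns. All matrices must have the same number of
#'   columns; column names, when present, must agree across modalities.
#' @param sample_ids optional character vector of sample identifiers; defaults
#'   to the shared column names or `s1, s2, ...`.
#' @param mask optional binary matrix with `sum(nrow)` rows (modalities
#'   stacked in declared order) and `n` columns; entries equal to 0 are set to
#'   `NA` in the data. By default the mask is derived from `NA` entries.
#'
#' @return An object of class `"multimodal_dataset"`: a list with elements
#'   `modalities` (matrices with `NA` at unobserved entries), `mask`,
#'   `sample_ids`, `feature_ids`, `block_sizes` and `offsets` (0-based row
#'   offset of each modality in the stacked matrix).
#'
#' @details Samples with no observed entry in any modality are rejected: no
#'   posterior over the latent factors exists for them. A single-modality
#'   dataset is permitted (the model then reduces to factor analysis), but
#'   multi-modal use expects at least two modalities.
#'
#' @examples
#' x1 <- matrix(rnorm(6), 2, 3)
#' x2 <- matrix(rnorm(9), 3, 3)
#' x2[1, 2] <- NA
#' md <- multimodal_dataset(list(a = x1, b = x2))
#' md$block_sizes
#' @export
multimodal_dataset <- function(modalities, sample_ids = NULL, mask = NULL) {
  if (!is.list(modalities) || length(modalities) < 1L)
    stop("'modalities' must be a non-empty list of matrices")
  modalities <- lapply(modalities, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  ns <- vapply(modalities, ncol, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all modalities must share the same number of samples (columns); got: ",
         paste(ns, collapse = ", "))
  n <- ns[[1L]]
  if (any(vapply(modalities, nrow, integer(1)) < 1L))
    stop("every modality must have at least one feature")

  cn <- lapply(modalities, colnames)
  has_cn <- !vapply(cn, is.null, logical(1))
  if (any(has_cn)) {
    ref <- cn[[which(has_cn)[1L]]]
    for (i in which(has_cn))
      if (!identical(cn[[i]], ref))
        stop("sample (column) names disagree between modalities ",
             which(has_cn)[1L], " and ", i)
    if (is.null(sample_ids)) sample_ids <- ref
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(sample_ids) != n)
    stop("'sample_ids' must have length ", n)

  if (is.null(names(modalities)))
    names(modalities) <- paste0("modality", seq_along(modalities))
  block_sizes <- vapply(modalities, nrow, integer(1))
  m <- sum(block_sizes)
  offsets <- cumsum(c(0L, block_sizes[-length(block_sizes)]))
  names(offsets) <- names(modalities)

  feature_ids <- lapply(seq_along(modalities), function(r) {
    rn <- rownames(modalities[[r]])
    if (is.null(rn)) rn <- paste0(names(modalities)[r], "_f", seq_len(block_sizes[r]))
    rn
  })
  names(feature_ids) <- names(modalities)

  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == c(m, n)))
      stop("'mask' must be ", m, " x ", n)
    if (!all(mask %in% c(0, 1)))
      stop("'mask' entries must be 0 or 1")
    for (r in seq_along(modalities)) {
      rows <- offsets[r] + seq_len(block_sizes[r])
      modalities[[r]][mask[rows, , drop = FALSE] == 0] <- NA_real_
    }
  }
  stacked <- do.call(rbind, modalities)
  if (any(!is.finite(stacked) & !is.na(stacked)))
    stop("data values must be finite or NA")
  mask <- (!is.na(stacked)) * 1L
  empty <- which(colSums(mask) == 0L)
  if (length(empty))
    stop("sample(s) with no observed entry in any modality: ",
         paste(sample_ids[empty], collapse = ", "))
  for (r in seq_along(modalities)) {
    colnames(modalities[[r]]) <- sample_ids
    rownames(modalities[[r]]) <- feature_ids[[r]]
  }

  structure(
    list(modalities = modalities, mask = mask, sample_ids = sample_ids,
         feature_ids = feature_ids, block_sizes = block_sizes,
         offsets = offsets),
    class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  n <- length(x$sample_ids)
  cat("multimodal_dataset:", length(x$modalities), "modalities,",
      sum(x$block_sizes), "features,", n, "samples\n")
  for (r in seq_along(x$modalities)) {
    obs <- mean(x$mask[x$offsets[r] + seq_len(x$block_sizes[r]), , drop = FALSE])
    cat(sprintf("  %s: %d features, %.1f%% observed\n",
                names(x$modalities)[r], x$block_sizes[r], 100 * obs))
  }
  invisible(x)
}

#' Stack the modalities of a dataset into one matrix
#'
#' @param x a [multimodal_dataset()].
#' @return The `m x n` stacked data matrix (modalities in declared order),
#'   with `NA` at unobserved entries.
#' @export
stacked_data <- function(x) {
  stopifnot(inherits(x, "multimodal_dataset"))
  do.call(rbind, x$modalities)
}

#' Coerce a single matrix to a multimodal dataset
#'
#' Convenience wrapper treating one matrix as a one-modality dataset (the
#' model then coincides with probabilistic factor analysis).
#'
#' @param x a numeric feature-by-sample matrix; `NA` marks missing entries.
#' @param name modality name.
#' @return A [multimodal_dataset()] with a single modality.
#' @export
as_multimodal <- function(x, name = "modality1") {
  md <- list(as.matrix(x))
  names(md) <- name
  multimodal_dataset(md)
}

# internal: split a stacked m x n matrix back into per-modality matrices
split_blocks <- function(mat, template) {
  out <- lapply(seq_along(template$block_sizes), function(r) {
    rows <- template$offsets[r] + seq_len(template$block_sizes[r])
    b <- mat[rows, , drop = FALSE]
    rownames(b) <- template$feature_ids[[r]]
    colnames(b) <- template$sample_ids
    b
  })
  names(out) <- names(template$modalities)
  out
}
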