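#' Read modality matrices from delimited text files
#'
#' Each file holds one modality: rows are features, columns are samples, the
#' first column carries feature identifiers and the header row carries sample
#' identifiers. TSV/CSV is autodetected from the header line. All files must
#' share an identical header (same samples, same order). The tokens in `na`
#' (and empty fields) mark missing entries.
#'
#' @param paths character vector of file paths, one per modality; names, when
#'   given, become the modality names.
#' @param na character tokens interpreted as missing.
#' @return A [multimodal_dataset()].
#' @export
read_modalities <- function(paths, na = c("NA", "", "NaN")) {
  if (length(paths) < 1L) stop("at least one modality file is required")
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- paste0("modality", seq_along(paths))
  header <- NULL
  mods <- vector("list", length(paths))
  names(mods) <- names(paths)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop("file not found: ", p)
    first <- readLines(p, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    df <- utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                            na.strings = na, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    if (is.null(header)) {
      header <- colnames(df)
    } else if (!identical(colnames(df), header)) {
      stop("sample header of '", p, "' does not match '", paths[[1L]], "'")
    }
    for (j in seq_along(df)) {
      if (!is.numeric(df[[j]])) {
        bad <- which(!is.na(df[[j]]))
        stop("non-numeric value in '", p, "', column '", colnames(df)[j],
             "', row '", ids[bad[1L]], "': ", df[[j]][bad[1L]])
      }
    }
    mat <- as.matrix(df)
    rownames(mat) <- ids
    mods[[i]] <- mat
  }
  multimodal_dataset(mods, sample_ids = header)
}

#' Write the modalities of a dataset as TSV files
#'
#' One file per modality, in the same layout accepted by
#' [read_modalities()]: features in rows (first column `feature_id`), samples
#' in columns, missing entries written as `NA`.
#'
#' @param x a [multimodal_dataset()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_modalities <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "multimodal_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(x$modalities))
  for (r in seq_along(x$modalities)) {
    paths[r] <- file.path(dir, paste0(prefix, names(x$modalities)[r], ".tsv"))
    # 17 significant digits so that doubles survive the round trip bit-exactly
    chr <- matrix(sprintf("%.17g", x$modalities[[r]]),
                  nrow(x$modalities[[r]]),
                  dimnames = list(NULL, x$sample_ids))
    chr[is.na(x$modalities[[r]])] <- "NA"
    df <- data.frame(feature_id = x$feature_ids[[r]], chr, check.names = FALSE)
    utils::write.table(df, paths[r], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' Write an embedding as TSV
#'
#' Samples in rows, factors in columns (`factor_1 ... factor_d`).
#'
#' @param embedding a `d x n` matrix (samples in columns) or a fitted
#'   `"gpcca"` model.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_embedding <- function(embedding, path) {
  if (inherits(embedding, "gpcca")) embedding <- embedding$embedding
  df <- data.frame(sample_id = colnames(embedding), t(embedding),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model as JSON
#'
#' Serializes the fitted parameters (loading matrix, mean vector, error
#' covariance blocks, block structure) and the fitting configuration as a
#' plain-text JSON container of named numeric arrays, at full precision.
#'
#' @param object a fitted `"gpcca"` model.
#' @param path file path.
#' @return `gpcca_save` invisibly returns `path`; `gpcca_load` returns a
#'   `"gpcca"` object (without embedding; recompute with [gpcca_embed()]).
#' @export
gpcca_save <- function(object, path) {
  stopifnot(inherits(object, "gpcca"))
  p <- object$params
  payload <- list(
    format = "gpcca-model-1",
    d = p$d,
    block_sizes = unname(as.integer(p$block_sizes)),
    block_names = names(p$Psi),
    covariance = p$covariance,
    W = p$W, mu = p$mu,
    Psi = lapply(p$Psi, unname),
    config = object$config,
    loglik = object$loglik,
    objective = object$objective,
    n_iter = object$n_iter,
    converged = object$converged)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname gpcca_save
#' @export
gpcca_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "gpcca-model-1"))
    stop("'", path, "' is not a saved gpcca model")
  bs <- as.integer(j$block_sizes)
  template <- list(block_sizes = bs,
                   offsets = cumsum(c(0L, bs[-length(bs)])),
                   modalities = stats::setNames(vector("list", length(bs)),
                                                j$block_names))
  Psi <- lapply(j$Psi, as.matrix)
  names(Psi) <- j$block_names
  params <- new_gpcca_params(as.matrix(j$W), as.numeric(j$mu), Psi, template,
                             covariance = j$covariance)
  structure(
    list(params = params, embedding = NULL,
         loglik = as.numeric(j$loglik), objective = as.numeric(j$objective),
         n_iter = as.integer(j$n_iter), converged = isTRUE(j$converged),
         config = j$config),
    class = "gpcca")
}
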