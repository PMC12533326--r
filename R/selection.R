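#' Louvain clustering of a latent embedding
#'
#' Builds a shared-nearest-neighbor (SNN) graph over the embedding columns
#' (Euclidean k-nearest neighbors, Jaccard edge weights, weak edges pruned)
#' and partitions it by Louvain modularity optimization at the given
#' resolution.
#'
#' @param embedding a `d x n` matrix with samples in columns (as returned by
#'   [gpcca_embed()]).
#' @param resolution Louvain resolution parameter; larger values yield more
#'   communities. Default 0.8.
#' @param k number of nearest neighbors for the SNN graph; clamped (with a
#'   warning) when fewer than `k + 1` samples are available.
#' @param prune SNN edges with Jaccard weight below this value are removed.
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return An integer vector of cluster labels (values arbitrary but
#'   partition-equivalent across identical calls).
#' @export
cluster_embedding <- function(embedding, resolution = 0.8, k = 15L,
                              prune = 1/15, seed = 1L) {
  embedding <- as.matrix(embedding)
  n <- ncol(embedding)
  if (n < 2L) stop("need at least 2 samples to cluster")
  k <- as.integer(k)
  if (k > n - 1L) {
    warning("k = ", k, " neighbors requested but only ", n - 1L,
            " available; clamping")
    k <- n - 1L
  }
  dmat <- as.matrix(stats::dist(t(embedding)))
  nb <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(dmat[i, ], decreasing = FALSE)
    ord <- ord[ord != i][seq_len(k)]
    nb[i, ord] <- 1L
  }
  diag(nb) <- 1L # a point shares itself with its neighbors (Seurat convention)
  shared <- tcrossprod(nb)
  jac <- shared / (2 * (k + 1L) - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(igraph::membership(cl))
}

#' Consensus matrix of repeated clusterings
#'
#' Entry (i, j) is the fraction of the provided clustering results in which
#' subjects i and j are assigned to the same cluster.
#'
#' @param labels an `n x B` integer matrix, one column per clustering.
#' @return A symmetric `n x n` matrix with unit diagonal and entries in
#'   `[0, 1]`.
#' @export
consensus_matrix <- function(labels) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  B <- ncol(labels)
  if (B < 1L) stop("need at least one clustering")
  C <- matrix(0, n, n)
  for (b in seq_len(B))
    C <- C + connectivity_matrix(labels[, b])
  C / B
}

#' Connectivity matrix of a single partition
#'
#' @param labels an integer vector of cluster assignments.
#' @return A binary symmetric co-membership matrix with unit diagonal.
#' @export
connectivity_matrix <- function(labels) {
  outer(labels, labels, "==") * 1
}

#' Consensus score
#'
#' `H = sum_{i<j} C_ij * log2(C_ij)` with the convention `0 * log2(0) = 0`.
#' The score is at most 0, with equality exactly when every off-diagonal
#' entry is 0 or 1, i.e. when all aggregated clusterings agree on every pair.
#'
#' @param C a consensus matrix (entries in `[0, 1]`).
#' @return A scalar `<= 0`.
#' @export
consensus_score <- function(C) {
  C <- as.matrix(C)
  v <- C[upper.tri(C)]
  if (any(v < -1e-12 | v > 1 + 1e-12))
    stop("consensus matrix entries must lie in [0, 1]")
  v <- pmin(pmax(v, 0), 1)
  v <- v[v > 0]
  sum(v * log2(v))
}

#' Best initialization by connectivity RMSE
#'
#' For each clustering (column of `labels`), computes the root mean squared
#' difference between its binary connectivity matrix and the consensus matrix
#' over the `n(n-1)/2` subject pairs, and returns the index of the smallest
#' (ties broken by lowest index).
#'
#' @param labels an `n x B` integer label matrix.
#' @param C optional consensus matrix; computed from `labels` when omitted.
#' @return A list with `best` (column index) and `rmse` (length-`B` vector).
#' @export
best_initialization <- function(labels, C = NULL) {
  labels <- as.matrix(labels)
  if (is.null(C)) C <- consensus_matrix(labels)
  n <- nrow(labels)
  ut <- upper.tri(C)
  rmse <- vapply(seq_len(ncol(labels)), function(b) {
    Cb <- connectivity_matrix(labels[, b])
    sqrt(sum((Cb[ut] - C[ut])^2) * 2 / (n * (n - 1)))
  }, numeric(1))
  list(best = which.min(rmse), rmse = rmse)
}

#' Select the number of latent factors by consensus
#'
#' For each candidate latent dimension, fits the model from `B` distinct
#' random initializations, Louvain-clusters each embedding, aggregates the
#' `B` partitions into a consensus matrix and scores its stability with
#' [consensus_score()]. The selected dimension is the candidate with the
#' largest (closest to 0) consensus score, ties broken towards the smaller
#' dimension; within the winning candidate the initialization whose
#' connectivity matrix is closest to the consensus (smallest RMSE) provides
#' the final model and cluster labels.
#'
#' @param x a [multimodal_dataset()].
#' @param candidates increasing vector of latent dimensions to try; all must
#'   be at most the smallest modality dimension.
#' @param B number of initializations per candidate (>= 2).
#' @param lambda,covariance,schedule,max_iter,tol,init_scale passed to
#'   [gpcca_fit()].
#' @param resolution,k_neighbors passed to [cluster_embedding()].
#' @param seed master seed; all fit and clustering seeds derive from it.
#' @return An object of class `"gpcca_select"`: list with `d` (selected),
#'   `summary` (data frame of candidate, consensus score, best-init RMSE),
#'   `states` (per candidate: `labels` matrix, `consensus`, `score`, `rmse`,
#'   `best_init`, the best initialization's fitted `model` and its `labels`),
#'   `model` and `labels` of the winning candidate/initialization.
#' @export
gpcca_select_d <- function(x, candidates, B = 10L, lambda = 1/2,
                           covariance = c("block", "diagonal"),
                           schedule = c("ecm", "literal"),
                           max_iter = 100L, tol = 1e-5, init_scale = 0.1,
                           resolution = 0.8, k_neighbors = 15L, seed = 1L) {
  stopifnot(inherits(x, "multimodal_dataset"))
  covariance <- match.arg(covariance)
  schedule <- match.arg(schedule)
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 0L) stop("no candidate dimensions given")
  if (any(candidates > min(x$block_sizes)))
    stop("candidate d exceeds the smallest modality dimension (",
         min(x$block_sizes), ")")
  B <- as.integer(B)
  if (B < 2L) stop("'B' must be at least 2")
  n <- length(x$sample_ids)

  states <- vector("list", length(candidates))
  names(states) <- paste0("d", candidates)
  for (ci in seq_along(candidates)) {
    d <- candidates[ci]
    labels <- matrix(NA_integer_, n, B)
    models <- vector("list", B)
    ok <- logical(B)
    for (b in seq_len(B)) {
      sb <- derive_seed(seed, ci * 131L + b)
      fit <- tryCatch(
        suppressWarnings(gpcca_fit(x, d = d, lambda = lambda,
                                   covariance = covariance, schedule = schedule,
                                   max_iter = max_iter, tol = tol,
                                   init_scale = init_scale, seed = sb)),
        error = function(e) {
          warning("fit failed for d = ", d, ", initialization ", b, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      labels[, b] <- cluster_embedding(fit$embedding, resolution = resolution,
                                       k = k_neighbors, seed = sb)
      models[[b]] <- fit
      ok[b] <- TRUE
    }
    if (!any(ok)) stop("all initializations failed for candidate d = ", d)
    labels <- labels[, ok, drop = FALSE]
    models <- models[ok]
    C <- consensus_matrix(labels)
    bi <- best_initialization(labels, C)
    states[[ci]] <- list(d = d, labels = labels, consensus = C,
                         score = consensus_score(C),
                         rmse = bi$rmse, best_init = bi$best,
                         model = models[[bi$best]],
                         labels_best = labels[, bi$best])
  }
  scores <- vapply(states, `[[`, numeric(1), "score")
  win <- which.max(scores) # candidates ascending: ties go to the smaller d
  structure(
    list(d = candidates[win],
         summary = data.frame(
           d = candidates,
           consensus_score = unname(scores),
           best_rmse = vapply(states, function(s) min(s$rmse), numeric(1)),
           best_init = vapply(states, `[[`, integer(1), "best_init"),
           row.names = NULL),
         states = states,
         model = states[[win]]$model,
         labels = states[[win]]$labels_best),
    class = "gpcca_select")
}

#' @export
print.gpcca_select <- function(x, ...) {
  cat("gpcca consensus selection: d =", x$d, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# deterministic seed stream derived from a master seed (kept below 2^31)
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 7919 + as.double(stream) * 104729) %%
               2147483587) + 1L
}
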