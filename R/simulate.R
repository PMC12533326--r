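#' First-order autoregressive correlation matrix
#'
#' @param size matrix dimension.
#' @param rho AR(1) parameter, `|rho| < 1`. Entry (i, j) equals
#'   `rho^|i - j|`; the matrix is symmetric positive definite.
#' @return A `size x size` correlation matrix.
#' @export
ar1_correlation <- function(size, rho) {
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be positive")
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  idx <- seq_len(size)
  rho^abs(outer(idx, idx, "-"))
}

#' Covariance matrix of informative features
#'
#' `Sigma = D %*% AR1(rho) %*% D` where `D = diag(sigma)` and each `sigma_i`
#' is drawn from `4 * Beta(1, 1)` (i.e. uniform on `[0, 4]`, floored at a
#' small positive constant so the result stays positive definite).
#'
#' @param m_info number of informative features.
#' @param rho AR(1) parameter.
#' @param sigma optional vector of feature standard deviations overriding the
#'   random draw (useful for reproducible checks).
#' @param seed integer seed for the random draw (ignored when `sigma` given).
#' @return A list with `Sigma` (covariance matrix) and `sigma` (the standard
#'   deviations used).
#' @export
informative_covariance <- function(m_info, rho, sigma = NULL, seed = 1L) {
  m_info <- as.integer(m_info)
  if (m_info < 1L) stop("'m_info' must be positive")
  if (is.null(sigma)) {
    set.seed(as.integer(seed))
    sigma <- 4 * stats::rbeta(m_info, 1, 1)
  }
  sigma <- pmax(sigma, 1e-3)
  D <- diag(sigma, nrow = m_info)
  list(Sigma = D %*% ar1_correlation(m_info, rho) %*% D, sigma = sigma)
}

#' Mask entries completely at random
#'
#' Each entry of each modality is masked independently with the given
#' probability. Columns that would lose every observed entry across all
#' modalities have their masks resampled (with a message), so no subject ends
#' up fully unobserved.
#'
#' @param x a [multimodal_dataset()] (or list of matrices).
#' @param rate missing probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A [multimodal_dataset()] with `NA` at masked entries.
#' @export
introduce_mcar <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("'rate' must be in [0, 1)")
  if (!inherits(x, "multimodal_dataset")) x <- multimodal_dataset(x)
  if (rate == 0) return(x)
  X <- stacked_data(x)
  m <- nrow(X); n <- ncol(X)
  set.seed(as.integer(seed))
  drop <- matrix(stats::runif(m * n) < rate, m, n)
  empty <- which(colSums(!drop) == 0L)
  guard <- 0L
  while (length(empty) > 0L && guard < 100L) {
    message("resampling MCAR mask for ", length(empty),
            " fully-masked column(s)")
    drop[, empty] <- stats::runif(m * length(empty)) < rate
    empty <- which(colSums(!drop) == 0L)
    guard <- guard + 1L
  }
  X[drop] <- NA_real_
  multimodal_dataset(split_blocks(X, x), sample_ids = x$sample_ids)
}

# cluster-to-distribution assignment: which clusters use the "u" component in
# each modality (the complementary clusters use "v")
cluster_pattern <- function() {
  matrix(c("u", "v", "u", "v", "v", "u",   # modality 1
           "u", "v", "v", "u", "u", "v",   # modality 2
           "u", "u", "u", "v", "u", "v"),  # modality 3
         nrow = 6, ncol = 3,
         dimnames = list(paste0("cluster", 1:6), paste0("modality", 1:3)))
}

#' Generate synthetic multi-modal data
#'
#' Simulates a clustered three-modality dataset for validating integrative
#' clustering: six clusters, modalities of 60/120/180 features by default,
#' one informative feature in five (the rest pure noise), and within-modality
#' AR(1)-structured covariance among the informative features. Four designs
#' are available:
#'
#' * **Case A** - multivariate normal informative features, entries missing
#'   completely at random at `missing_rate`.
#' * **Case B** - as A but every distribution replaced by a multivariate (or
#'   univariate, for the noise) t with 3 degrees of freedom, keeping the same
#'   location and scatter.
#' * **Case C** - complete data as in A, then modality-wise missingness
#'   driven by a hidden standard-normal variable `H_k`: a subject drops an
#'   entire modality with probability `mnar_p` when `H_k >= 0` and `2 *
#'   mnar_p` otherwise, independently per modality (subjects that would lose
#'   all modalities are redrawn).
#' * **Case D** - as A, except that a sixth of the within-modality
#'   correlation entries (among informative features) are swapped with
#'   zero-valued between-modality entries, creating cross-modality residual
#'   correlation; the diagonal is jittered upward in powers of 10 if needed
#'   to restore positive definiteness.
#'
#' Within each modality, half of the clusters draw their informative features
#' from component `u` (mean entries uniform on `[1, 2]`) and the other half
#' from component `v` (mean entries uniform on `[-2, -1]`), with cluster
#' assignment to components varying across modalities so that no single
#' modality separates all six clusters. Noisy features are standard normal
#' (t3 in Case B) independently of cluster membership.
#'
#' @param case one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param rho AR(1) correlation parameter in `(0, 1)`.
#' @param missing_rate MCAR rate for cases A, B, D.
#' @param mnar_p base modality-drop probability for case C.
#' @param n_per_cluster samples per cluster (6 clusters).
#' @param modality_dims feature counts of the three modalities; each must be
#'   a multiple of 5 (one fifth informative).
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `"gpcca_sim"`: list with `data` (a
#'   [multimodal_dataset()] with missingness applied), `labels` (true cluster
#'   assignment), and `truth` (complete pre-masking modalities, stacked
#'   informative covariance, component means, informative row indices, the
#'   hidden `H` for case C, and the generator settings).
#' @export
simulate_multimodal <- function(case = c("A", "B", "C", "D"),
                                rho = 0.7, missing_rate = 0.2, mnar_p = 0.1,
                                n_per_cluster = 100L,
                                modality_dims = c(60L, 120L, 180L),
                                seed = 1L) {
  case <- match.arg(case)
  if (rho <= 0 || rho >= 1) stop("'rho' must be in (0, 1)")
  modality_dims <- as.integer(modality_dims)
  if (length(modality_dims) != 3L || any(modality_dims %% 5L != 0L))
    stop("'modality_dims' must be three multiples of 5")
  n_per_cluster <- as.integer(n_per_cluster)
  n_clusters <- 6L
  n <- n_clusters * n_per_cluster
  m_info <- modality_dims %/% 5L
  pattern <- cluster_pattern()

  set.seed(as.integer(seed))

  # component means and within-modality covariances of informative features
  mu_u <- lapply(m_info, function(mm) stats::runif(mm, 1, 2))
  mu_v <- lapply(m_info, function(mm) stats::runif(mm, -2, -1))
  covs <- lapply(seq_len(3L), function(r) {
    sigma <- pmax(4 * stats::rbeta(m_info[r], 1, 1), 1e-3)
    D <- diag(sigma, nrow = m_info[r])
    list(Sigma = D %*% ar1_correlation(m_info[r], rho) %*% D, sigma = sigma)
  })

  # stacked covariance over all informative features (block diagonal unless D)
  mtot <- sum(m_info)
  Sigma <- matrix(0, mtot, mtot)
  ioff <- cumsum(c(0L, m_info[-3L]))
  for (r in 1:3) {
    idx <- ioff[r] + seq_len(m_info[r])
    Sigma[idx, idx] <- covs[[r]]$Sigma
  }
  swap_info <- NULL
  if (case == "D") {
    sw_res <- swap_cross_modality(Sigma, m_info, ioff)
    Sigma <- sw_res$Sigma
    swap_info <- sw_res[c("moved_corr", "jitter", "within_idx", "across_idx")]
  }

  L <- t(chol(Sigma)) # lower-triangular factor, shared by all clusters

  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  Xinfo <- matrix(0, mtot, n)
  for (cl in seq_len(n_clusters)) {
    mu_c <- unlist(lapply(1:3, function(r)
      if (pattern[cl, r] == "u") mu_u[[r]] else mu_v[[r]]))
    cols <- which(labels == cl)
    Zc <- matrix(stats::rnorm(mtot * length(cols)), mtot, length(cols))
    Xc <- L %*% Zc
    if (case == "B") {
      # multivariate t3: scatter-Cholesky times normal over sqrt(chisq_3 / 3)
      wc <- sqrt(stats::rchisq(length(cols), df = 3) / 3)
      Xc <- sweep(Xc, 2, wc, "/")
    }
    Xinfo[, cols] <- Xc + mu_c
  }

  modalities <- vector("list", 3L)
  info_rows <- vector("list", 3L)
  for (r in 1:3) {
    m_noise <- modality_dims[r] - m_info[r]
    noise <- if (case == "B") {
      matrix(stats::rt(m_noise * n, df = 3), m_noise, n)
    } else {
      matrix(stats::rnorm(m_noise * n), m_noise, n)
    }
    modalities[[r]] <- rbind(Xinfo[ioff[r] + seq_len(m_info[r]), , drop = FALSE],
                             noise)
    info_rows[[r]] <- seq_len(m_info[r])
    rownames(modalities[[r]]) <- paste0("m", r, "_f", seq_len(modality_dims[r]))
  }
  names(modalities) <- paste0("modality", 1:3)
  for (r in 1:3) colnames(modalities[[r]]) <- paste0("s", seq_len(n))
  complete <- multimodal_dataset(modalities)

  H <- NULL
  if (case == "C") {
    masked <- introduce_mnar_modality(complete, mnar_p,
                                      seed = derive_seed(seed, 17L))
    data <- masked$data
    H <- masked$H
  } else {
    data <- introduce_mcar(complete, missing_rate,
                           seed = derive_seed(seed, 17L))
  }

  structure(
    list(data = data, labels = labels,
         truth = list(complete = modalities,
                      Sigma_informative = Sigma,
                      mu_u = mu_u, mu_v = mu_v,
                      sigma = lapply(covs, `[[`, "sigma"),
                      info_rows = info_rows,
                      pattern = pattern,
                      H = H, swap = swap_info,
                      settings = list(case = case, rho = rho,
                                      missing_rate = missing_rate,
                                      mnar_p = mnar_p,
                                      n_per_cluster = n_per_cluster,
                                      modality_dims = modality_dims,
                                      seed = seed))),
    class = "gpcca_sim")
}

#' @export
print.gpcca_sim <- function(x, ...) {
  s <- x$truth$settings
  cat("gpcca_sim: case", s$case, "| rho =", s$rho,
      "|", length(x$labels), "samples in", length(unique(x$labels)),
      "clusters\n")
  print(x$data)
  invisible(x)
}

# swap 1/6 of within-modality (strictly lower-triangular, informative-block)
# correlation entries with zero cross-modality entries, symmetrically; repair
# positive definiteness with the smallest power-of-10 diagonal jitter
swap_cross_modality <- function(Sigma, m_info, ioff, target_eig = 1e-6) {
  sds <- sqrt(diag(Sigma))
  Corr <- Sigma / tcrossprod(sds)
  mtot <- nrow(Corr)
  block_id <- rep(seq_along(m_info), m_info)
  low <- which(lower.tri(Corr), arr.ind = TRUE)
  within <- low[block_id[low[, 1]] == block_id[low[, 2]], , drop = FALSE]
  across <- low[block_id[low[, 1]] != block_id[low[, 2]], , drop = FALSE]
  nswap <- round(nrow(within) / 6)
  wi <- within[sample.int(nrow(within), nswap), , drop = FALSE]
  ai <- across[sample.int(nrow(across), nswap), , drop = FALSE]
  vals <- Corr[wi]
  Corr[wi] <- 0
  Corr[ai] <- vals
  Corr[upper.tri(Corr)] <- 0
  Corr <- Corr + t(Corr)
  diag(Corr) <- 1
  Sigma2 <- Corr * tcrossprod(sds)
  jitter <- 0
  ev <- min(eigen(Sigma2, symmetric = TRUE, only.values = TRUE)$values)
  j <- -8
  while (ev < target_eig && j <= 2) {
    jitter <- 10^j
    ev <- min(eigen(Sigma2 + jitter * diag(mtot), symmetric = TRUE,
                    only.values = TRUE)$values)
    j <- j + 1
  }
  if (ev < target_eig) stop("could not repair positive definiteness")
  if (jitter > 0) Sigma2 <- Sigma2 + jitter * diag(mtot)
  list(Sigma = Sigma2, moved_corr = vals, jitter = jitter,
       within_idx = wi, across_idx = ai)
}

# modality-wise missingness driven by a hidden standard-normal variable: a
# subject loses one entire (uniformly chosen) modality with probability p when
# H >= 0 and 2p when H < 0. At most one modality is dropped per subject; this
# keeps the mechanism well defined for any p <= 1/2 (a per-modality
# independent drop with probability 2p would wipe out every modality of every
# H < 0 subject at p = 1/2).
introduce_mnar_modality <- function(x, p, seed = 1L) {
  if (p <= 0 || p > 0.5) stop("'mnar_p' must be in (0, 0.5]")
  n <- length(x$sample_ids)
  R <- length(x$modalities)
  set.seed(as.integer(seed))
  H <- stats::rnorm(n)
  pk <- ifelse(H >= 0, p, 2 * p)
  drop_subject <- stats::runif(n) < pk
  which_modality <- sample.int(R, n, replace = TRUE)
  drop <- matrix(FALSE, n, R)
  drop[cbind(seq_len(n), which_modality)] <- drop_subject
  mods <- x$modalities
  for (r in seq_len(R))
    mods[[r]][, drop[, r]] <- NA_real_
  list(data = multimodal_dataset(mods, sample_ids = x$sample_ids),
       H = H, dropped = drop)
}
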