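# small multi-modal instances built in code for the unit tests

# random dataset with optional MCAR missingness
make_test_dataset <- function(n = 30, dims = c(3, 4, 5), miss = 0.25,
                              seed = 7, mu_sd = 1.5, noise_corr = 0.4) {
  set.seed(seed)
  mods <- lapply(dims, function(mr) {
    mu <- rnorm(mr, sd = mu_sd)
    A <- matrix(rnorm(mr * mr, sd = noise_corr), mr)
    L <- t(chol(crossprod(A) + diag(mr)))
    mu + L %*% matrix(rnorm(mr * n), mr, n)
  })
  x <- multimodal_dataset(mods)
  if (miss > 0) x <- introduce_mcar(x, miss, seed = seed + 1)
  x
}

# parameters with genuinely correlated (non-diagonal) Psi blocks, to exercise
# the blockwise partial-observation algebra
make_corr_params <- function(x, d = 2, seed = 3) {
  p <- gpcca_init(x, d = d, seed = seed)
  set.seed(seed + 100)
  p$Psi <- lapply(p$Psi, function(B) {
    mr <- nrow(B)
    A <- matrix(rnorm(mr * mr, sd = 0.3), mr)
    crossprod(A) + diag(mr)
  })
  names(p$Psi) <- names(x$modalities)
  p
}

# data generated from the GPCCA model itself, with known parameters
make_model_data <- function(n, dims = c(8, 10, 12), d = 3, seed = 1,
                            psi_corr = 0.3) {
  set.seed(seed)
  m <- sum(dims)
  W <- matrix(rnorm(m * d), m, d)
  mu <- rnorm(m, sd = 2)
  Psi <- lapply(dims, function(mr) {
    A <- matrix(rnorm(mr * mr, sd = psi_corr), mr)
    crossprod(A) + diag(mr)
  })
  Z <- matrix(rnorm(d * n), d, n)
  E <- do.call(rbind, lapply(Psi, function(B)
    t(chol(B)) %*% matrix(rnorm(nrow(B) * n), nrow(B), n)))
  X <- W %*% Z + mu + E
  off <- cumsum(c(0, dims[-length(dims)]))
  mods <- lapply(seq_along(dims), function(r)
    X[off[r] + seq_len(dims[r]), , drop = FALSE])
  list(data = multimodal_dataset(mods), W = W, mu = mu, Psi = Psi, Z = Z)
}

# split a stacked matrix into per-modality matrices following a template
split_blocks_for_test <- function(mat, template) {
  lapply(seq_along(template$block_sizes), function(r) {
    rows <- template$offsets[r] + seq_len(template$block_sizes[r])
    mat[rows, , drop = FALSE]
  })
}

# largest principal angle (radians) between the column spaces of two matrices
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s))))
}
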