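# brute-force dense reference for the E-step: per subject, the marginal
# covariance of the observed rows (W~ W~' + Psi~) is inverted directly (no
# Woodbury, no blockwise algebra) and the conditional-Gaussian moment
# formulas are evaluated from it. Independent of the package's code path.
dense_estep_oracle <- function(params, x) {
  X <- stacked_data(x)
  O <- x$mask
  m <- nrow(X); n <- ncol(X); d <- params$d
  Psi <- matrix(0, m, m)
  for (r in seq_along(params$Psi)) {
    rows <- params$offsets[r] + seq_len(params$block_sizes[r])
    Psi[rows, rows] <- params$Psi[[r]]
  }
  W <- params$W
  mu <- params$mu
  ll <- 0
  Ez <- matrix(0, d, n); Ex <- matrix(0, m, n)
  Ezz <- array(0, c(d, d, n)); M <- array(0, c(d, d, n))
  Exz <- array(0, c(m, d, n))
  for (k in seq_len(n)) {
    o <- which(O[, k] == 1)
    Wo <- W[o, , drop = FALSE]
    Sig <- Wo %*% t(Wo) + Psi[o, o]
    Si <- solve(Sig)
    r <- X[o, k] - mu[o]
    ll <- ll - 0.5 * (length(o) * log(2 * pi) +
                        as.numeric(determinant(Sig)$modulus) +
                        as.numeric(t(r) %*% Si %*% r))
    ez <- as.numeric(t(Wo) %*% Si %*% r)
    Mt <- diag(d) - t(Wo) %*% Si %*% Wo
    Ez[, k] <- ez
    M[, , k] <- Mt
    Ezz[, , k] <- Mt + tcrossprod(ez)
    Ex[, k] <- X[, k]
    mi <- which(O[, k] == 0)
    Ex[mi, k] <- W[mi, , drop = FALSE] %*% ez + mu[mi]
    exzk <- Ex[, k] %*% t(ez)
    exzk[mi, ] <- exzk[mi, , drop = FALSE] + W[mi, , drop = FALSE] %*% Mt
    Exz[, , k] <- exzk
  }
  list(loglik = ll, Ez = Ez, Ex = Ex, Ezz = Ezz, M = M, Exz = Exz)
}

# within-block second moments E(X_ik X_jk | x~) per the conditional formulas,
# dense route, for one subject
dense_second_moments_block <- function(params, x, k, r) {
  orc <- dense_estep_oracle(params, x)
  rows <- params$offsets[r] + seq_len(params$block_sizes[r])
  O <- x$mask[rows, k]
  ex <- orc$Ex[rows, k]
  Mt <- orc$M[, , k]
  Wr <- params$W[rows, , drop = FALSE]
  S <- tcrossprod(ex)
  mi <- which(O == 0)
  if (length(mi) > 0)
    S[mi, mi] <- S[mi, mi] +
      Wr[mi, , drop = FALSE] %*% Mt %*% t(Wr[mi, , drop = FALSE]) +
      params$Psi[[r]][mi, mi]
  S
}
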