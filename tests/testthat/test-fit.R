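test_that("initialization follows the documented scheme and is deterministic", {
  x1 <- matrix(5, 3, 8) # constant feature values
  x2 <- matrix(rnorm(16), 2, 8)
  md <- multimodal_dataset(list(x1, x2))
  p <- gpcca_init(md, d = 2, seed = 42)
  expect_equal(p$mu[1:3], rep(5, 3))
  expect_equal(diag(p$Psi[[1]]), rep(1e-6, 3)) # zero variance hits the floor
  p2 <- gpcca_init(md, d = 2, seed = 42)
  expect_identical(p, p2)
  p3 <- gpcca_init(md, d = 2, seed = 43)
  expect_false(identical(p$W, p3$W))
  expect_error(gpcca_init(md, d = 3), "smallest modality")
})

test_that("initialization at full simulation scale has the right shapes", {
  sim <- simulate_multimodal("A", rho = 0.7, missing_rate = 0,
                             n_per_cluster = 5, seed = 1)
  p <- gpcca_init(sim$data, d = 6, seed = 1)
  expect_equal(dim(p$W), c(360L, 6L))
  expect_equal(vapply(p$Psi, nrow, integer(1)),
               c(modality1 = 60L, modality2 = 120L, modality3 = 180L))
})

test_that("a feature with no observed entries is reported by name", {
  x <- matrix(rnorm(12), 3, 4)
  x[2, ] <- NA
  x <- rbind(x, 1)
  md <- multimodal_dataset(list(mod = x))
  expect_error(gpcca_init(md, d = 1), "mod_f2")
})

test_that("EM is monotone where the updates are exact EM steps", {
  # complete data (any covariance mode) and diagonal mode are exact EM at
  # lambda = 1; the trace may not decrease beyond numerical slack
  cases <- list(list(miss = 0, cov = "block"),
                list(miss = 0, cov = "diagonal"),
                list(miss = 0.25, cov = "diagonal"))
  for (cs in cases) {
    for (seed in c(1, 5, 9)) {
      x <- make_test_dataset(n = 30, miss = cs$miss, seed = seed)
      f <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1,
                                      covariance = cs$cov,
                                      max_iter = 80, tol = 1e-10, seed = seed))
      steps <- diff(f$objective)
      slack <- 1e-8 * abs(f$objective[-length(f$objective)])
      expect_true(all(steps >= -slack))
    }
  }
})

test_that("fitting is deterministic given the seed", {
  x <- make_test_dataset(n = 25, miss = 0.2, seed = 14)
  f1 <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1 / 2, max_iter = 40,
                                   seed = 99))
  f2 <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1 / 2, max_iter = 40,
                                   seed = 99))
  expect_identical(f1$params$W, f2$params$W)
  expect_identical(f1$embedding, f2$embedding)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the cached complete-data path equals the general path", {
  x <- make_test_dataset(n = 30, miss = 0, seed = 16)
  fa <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 2 / 3, max_iter = 30,
                                   seed = 1, use_cache = TRUE))
  fb <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 2 / 3, max_iter = 30,
                                   seed = 1, use_cache = FALSE))
  expect_equal(fa$loglik, fb$loglik, tolerance = 1e-10)
  expect_equal(fa$params$W, fb$params$W, tolerance = 1e-8)
})

test_that("the model recovers self-generated structure", {
  md <- make_model_data(n = 400, dims = c(8, 10, 12), d = 3, seed = 2)
  f <- suppressWarnings(gpcca_fit(md$data, d = 3, lambda = 1, max_iter = 300,
                                  tol = 1e-8, seed = 7))
  block_diag <- function(blocks) {
    m <- sum(vapply(blocks, nrow, integer(1)))
    out <- matrix(0, m, m)
    at <- 0L
    for (B in blocks) {
      idx <- at + seq_len(nrow(B))
      out[idx, idx] <- B
      at <- at + nrow(B)
    }
    out
  }
  C_true <- tcrossprod(md$W) + block_diag(md$Psi)
  C_hat <- tcrossprod(f$params$W) + block_diag(f$params$Psi)
  relerr <- norm(C_hat - C_true, "F") / norm(C_true, "F")
  expect_lt(relerr, 0.25)
  expect_lt(principal_angle(f$params$W, md$W), 0.2)
})

test_that("loading-subspace error shrinks as the sample size grows", {
  angs <- sapply(c(60, 500), function(n) {
    mean(sapply(1:3, function(s) {
      md <- make_model_data(n = n, dims = c(6, 8), d = 2, seed = s)
      f <- suppressWarnings(gpcca_fit(md$data, d = 2, lambda = 1,
                                      max_iter = 200, tol = 1e-7, seed = s))
      principal_angle(f$params$W, md$W)
    }))
  })
  expect_lt(angs[2], angs[1])
})

test_that("subjects at the fitted mean embed at the origin", {
  x <- make_test_dataset(n = 20, miss = 0, seed = 31)
  f <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1, max_iter = 30, seed = 3))
  mu_cols <- matrix(f$params$mu, nrow(stacked_data(x)), 2)
  xnew <- multimodal_dataset(split_blocks_for_test(mu_cols, x))
  emb <- gpcca_embed(f, xnew)
  expect_equal(emb, matrix(0, 2, 2, dimnames = dimnames(emb)),
               tolerance = 1e-12)
  # identical subjects embed identically
  expect_identical(emb[, 1], emb[, 2])
})

test_that("imputation preserves observed entries and completes the rest", {
  x <- make_test_dataset(n = 25, miss = 0.3, seed = 18)
  f <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1 / 2, max_iter = 60,
                                  seed = 2))
  done <- gpcca_impute(f, x)
  Xd <- stacked_data(done)
  X <- stacked_data(x)
  obs <- x$mask == 1
  expect_identical(Xd[obs], X[obs])
  expect_true(all(is.finite(Xd)))
  expect_true(all(done$mask == 1L))
  # complete input comes back unchanged
  xc <- make_test_dataset(n = 10, miss = 0, seed = 19)
  fc <- suppressWarnings(gpcca_fit(xc, d = 2, lambda = 1, max_iter = 20,
                                   seed = 2))
  expect_identical(stacked_data(gpcca_impute(fc, xc)), stacked_data(xc))
})

test_that("model-based imputation beats the per-feature mean on masked truth", {
  md <- make_model_data(n = 150, dims = c(6, 8), d = 2, seed = 4)
  truth <- stacked_data(md$data)
  x <- introduce_mcar(md$data, 0.25, seed = 5)
  f <- suppressWarnings(gpcca_fit(x, d = 2, lambda = 1, max_iter = 150,
                                  seed = 4))
  hole <- x$mask == 0
  imp <- stacked_data(gpcca_impute(f, x))
  mean_imp <- matrix(rowMeans(stacked_data(x), na.rm = TRUE),
                     nrow(truth), ncol(truth))
  rmse <- function(a) sqrt(mean((a[hole] - truth[hole])^2))
  expect_lt(rmse(imp), rmse(mean_imp))
})

test_that("non-convergence is a warning, not an error", {
  x <- make_test_dataset(n = 15, miss = 0.1, seed = 23)
  expect_warning(gpcca_fit(x, d = 2, lambda = 1, max_iter = 2, seed = 1),
                 "did not converge")
})
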