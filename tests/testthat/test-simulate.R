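test_that("AR(1) correlation matrix has the closed form and is PD", {
  expect_equal(ar1_correlation(3, 0.5),
               matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3))
  expect_equal(ar1_correlation(4, 0), diag(4))
  for (rho in c(0.3, 0.7, 0.95)) {
    ev <- eigen(ar1_correlation(25, rho), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(ar1_correlation(3, 1), "rho")
})

test_that("informative covariance is D %*% AR1 %*% D", {
  ic <- informative_covariance(5, 0.6, sigma = rep(1, 5))
  expect_equal(ic$Sigma, ar1_correlation(5, 0.6))
  ic2 <- informative_covariance(6, 0.4, seed = 3)
  expect_equal(diag(ic2$Sigma), ic2$sigma^2)
  expect_equal(stats::cov2cor(ic2$Sigma), ar1_correlation(6, 0.4),
               tolerance = 1e-12)
  expect_true(all(ic2$sigma >= 1e-3 & ic2$sigma <= 4))
})

test_that("case A produces the declared layout and missing rate", {
  sim <- simulate_multimodal("A", rho = 0.7, missing_rate = 0.2,
                             n_per_cluster = 100, seed = 1)
  X <- stacked_data(sim$data)
  expect_equal(dim(X), c(360L, 600L))
  expect_equal(unname(table(sim$labels)), rep(100L, 6), ignore_attr = TRUE)
  expect_equal(mean(sim$data$mask == 0), 0.2, tolerance = 0.01)
  # pre-masking truth is complete
  expect_false(anyNA(do.call(rbind, sim$truth$complete)))
  # informative counts are one fifth of each modality
  expect_equal(lengths(sim$truth$info_rows), c(12L, 24L, 36L))
})

test_that("MCAR masking hits its rate and never empties a column", {
  x <- make_test_dataset(n = 50, dims = c(20, 20), miss = 0, seed = 2)
  y <- introduce_mcar(x, 0.4, seed = 3)
  expect_equal(mean(y$mask == 0), 0.4, tolerance = 0.03)
  expect_true(all(colSums(y$mask) > 0))
  expect_identical(introduce_mcar(x, 0, seed = 1), x)
  y2 <- introduce_mcar(x, 0.4, seed = 3)
  expect_identical(stacked_data(y), stacked_data(y2))
  expect_error(introduce_mcar(x, 1), "rate")
})

test_that("generators are bit-reproducible under a fixed seed", {
  for (case in c("A", "B", "C", "D")) {
    s1 <- simulate_multimodal(case, rho = 0.5, missing_rate = 0.2,
                              mnar_p = 0.1, n_per_cluster = 10,
                              modality_dims = c(10, 15, 20), seed = 8)
    s2 <- simulate_multimodal(case, rho = 0.5, missing_rate = 0.2,
                              mnar_p = 0.1, n_per_cluster = 10,
                              modality_dims = c(10, 15, 20), seed = 8)
    expect_identical(stacked_data(s1$data), stacked_data(s2$data))
    expect_identical(s1$labels, s2$labels)
  }
})

test_that("per-cluster informative sample covariance approaches its target", {
  sim <- simulate_multimodal("A", rho = 0.7, missing_rate = 0,
                             n_per_cluster = 2000,
                             modality_dims = c(30, 30, 30), seed = 4)
  r <- 1
  rows <- sim$truth$info_rows[[r]]
  target <- sim$truth$Sigma_informative[seq_along(rows), seq_along(rows)]
  emp <- stats::cov(t(sim$truth$complete[[r]][rows, sim$labels == 1]))
  expect_lt(norm(emp - target, "F") / norm(target, "F"), 0.1)
})

test_that("case B informative features are heavy-tailed", {
  simB <- simulate_multimodal("B", rho = 0.5, missing_rate = 0,
                              n_per_cluster = 400,
                              modality_dims = c(20, 20, 20), seed = 5)
  kurt <- function(v) mean((v - mean(v))^4) / stats::var(v)^2
  # pooled excess kurtosis within one cluster, first informative feature
  v <- simB$truth$complete[[1]][1, simB$labels == 1]
  expect_gt(kurt(v), 4) # Gaussian would concentrate near 3
})

test_that("case C drops whole modalities at H-dependent rates", {
  drops_lo <- 0; drops_hi <- 0; n_lo <- 0; n_hi <- 0
  multi_drop <- 0
  for (s in 1:5) {
    sim <- simulate_multimodal("C", rho = 0.5, mnar_p = 0.15,
                               n_per_cluster = 100, seed = s)
    H <- sim$truth$H
    dropped <- sapply(seq_along(sim$data$modalities), function(r)
      colSums(!is.na(sim$data$modalities[[r]])) == 0)
    per_subject <- rowSums(dropped)
    multi_drop <- multi_drop + sum(per_subject > 1)
    drops_lo <- drops_lo + sum(per_subject[H < 0])
    drops_hi <- drops_hi + sum(per_subject[H >= 0])
    n_lo <- n_lo + sum(H < 0); n_hi <- n_hi + sum(H >= 0)
  }
  ratio <- (drops_lo / n_lo) / (drops_hi / n_hi)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
  expect_equal(multi_drop, 0) # at most one modality lost per subject
})

test_that("case D moves within-modality correlation across modalities", {
  sim <- simulate_multimodal("D", rho = 0.8, missing_rate = 0,
                             n_per_cluster = 10,
                             modality_dims = c(20, 25, 30), seed = 6)
  S <- sim$truth$Sigma_informative
  sw <- sim$truth$swap
  m_info <- c(4L, 5L, 6L)
  block_id <- rep(1:3, m_info)
  cross <- outer(block_id, block_id, "!=")
  expect_gt(sum(abs(S[cross]) > 0), 0)
  # swapped values preserved exactly (covariance = moved corr times both sds)
  sds <- sqrt(diag(S) - sw$jitter)
  got <- S[sw$across_idx]
  want <- sw$moved_corr * sds[sw$across_idx[, 1]] * sds[sw$across_idx[, 2]]
  expect_equal(got, want, tolerance = 1e-12)
  # vacated within-modality positions are exactly zero
  expect_equal(unname(S[sw$within_idx]), rep(0, nrow(sw$within_idx)))
  # count: one sixth of the strictly-lower within-modality entries
  expect_identical(nrow(sw$within_idx),
                   as.integer(round(sum(m_info * (m_info - 1) / 2) / 6)))
  # the matrix used for sampling is positive definite
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("cluster/component assignment follows the design table", {
  sim <- simulate_multimodal("A", rho = 0.5, missing_rate = 0,
                             n_per_cluster = 300,
                             modality_dims = c(10, 10, 10), seed = 7)
  pat <- sim$truth$pattern
  for (r in 1:3) {
    rows <- sim$truth$info_rows[[r]]
    mu_u <- mean(sim$truth$mu_u[[r]])
    mu_v <- mean(sim$truth$mu_v[[r]])
    for (cl in 1:6) {
      emp <- mean(sim$truth$complete[[r]][rows, sim$labels == cl])
      want <- if (pat[cl, r] == "u") mu_u else mu_v
      expect_equal(emp, want, tolerance = 0.35)
    }
  }
})
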