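#' Initialize GPCCA parameters
#'
#' Standard factor-analysis style initialization: per-feature observed means
#' for the mean vector, small i.i.d. Gaussian entries for the loading matrix,
#' and a diagonal error covariance holding the per-feature observed variances
#' (floored at a small positive constant so every block is positive definite).
#'
#' @param x a [multimodal_dataset()].
#' @param d number of latent factors, `1 <= d <= min(block_sizes)`.
#' @param init_scale standard deviation of the Gaussian loading entries.
#' @param seed integer seed making the initialization deterministic.
#' @param var_floor lower bound on the diagonal of the error covariance.
#' @return An object of class `"gpcca_params"`: list with `W` (`m x d`), `mu`
#'   (length `m`), `Psi` (list of per-modality covariance blocks), `d`,
#'   `block_sizes`, `offsets` and `covariance` mode.
#' @export
gpcca_init <- function(x, d, init_scale = 0.1, seed = 1L, var_floor = 1e-6) {
  stopifnot(inherits(x, "multimodal_dataset"))
  d <- as.integer(d)
  if (d < 1L || d > min(x$block_sizes))
    stop("'d' must be between 1 and the smallest modality dimension (",
         min(x$block_sizes), ")")
  X <- stacked_data(x)
  nobs <- rowSums(!is.na(X))
  if (any(nobs == 0L)) {
    bad <- unlist(x$feature_ids)[nobs == 0L]
    stop("feature(s) with no observed entries: ", paste(bad, collapse = ", "))
  }
  mu <- rowMeans(X, na.rm = TRUE)
  v <- apply(X, 1L, stats::var, na.rm = TRUE)
  v[!is.finite(v)] <- 0
  v <- pmax(v, var_floor)
  set.seed(as.integer(seed))
  W <- matrix(stats::rnorm(nrow(X) * d, sd = init_scale), nrow(X), d)
  Psi <- lapply(seq_along(x$block_sizes), function(r) {
    rows <- x$offsets[r] + seq_len(x$block_sizes[r])
    diag(v[rows], nrow = x$block_sizes[r])
  })
  names(Psi) <- names(x$modalities)
  new_gpcca_params(W, mu, Psi, x)
}

new_gpcca_params <- function(W, mu, Psi, template,
                             covariance = c("block", "diagonal")) {
  covariance <- match.arg(covariance)
  structure(
    list(W = W, mu = as.numeric(mu), Psi = Psi, d = ncol(W),
         block_sizes = template$block_sizes, offsets = template$offsets,
         covariance = covariance),
    class = "gpcca_params")
}

#' @export
print.gpcca_params <- function(x, ...) {
  cat("gpcca_params: m =", nrow(x$W), ", d =", x$d,
      ", blocks =", paste(x$block_sizes, collapse = "/"),
      ", covariance =", x$covariance, "\n")
  invisible(x)
}

check_params_data <- function(params, x) {
  if (!identical(unname(as.integer(params$block_sizes)),
                 unname(as.integer(x$block_sizes))))
    stop("parameter block sizes (", paste(params$block_sizes, collapse = "/"),
         ") do not match the dataset (", paste(x$block_sizes, collapse = "/"), ")")
}

# penalized objective's penalty term: (n(1-lambda)/2) tr(R^-1), where R is the
# error correlation matrix. tr(R^-1) = sum_i (Psi^-1)_ii * Psi_ii, blockwise.
ridge_penalty <- function(params, lambda, n) {
  if (lambda >= 1) return(0)
  tr <- sum(vapply(params$Psi, function(P) {
    sum(diag(solve(P)) * diag(P))
  }, numeric(1)))
  0.5 * n * (1 - lambda) * tr
}

#' E-step conditional expectations
#'
#' Computes, for every subject, the conditional expectations of the latent
#' factors and of the missing data entries given the observed sub-vector:
#' `E(z_k | x~_k)`, `E(z_k z_k' | x~_k)`, the completed data vector
#' `E(X_.k | x~_k)`, the cross-moments `E(X_.k z_k' | x~_k)` and the
#' per-subject Woodbury matrix, together with the accumulated sufficient
#' statistics consumed by [gpcca_mstep()]. Within-modality second moments are
#' accumulated blockwise only (all off-block entries are discarded by the
#' block-diagonal M-step), so the full `m x m` moment matrix is never formed.
#'
#' @param params a `"gpcca_params"` object.
#' @param x a [multimodal_dataset()] with matching block structure.
#' @param subject_moments if `TRUE`, also return per-subject arrays `M`
#'   (`d x d x n` Woodbury matrices), `Ezz` and `Exz`; intended for small
#'   problems and diagnostics, as the arrays grow with `m * d * n`.
#' @param use_cache share factorizations across subjects through per-iteration
#'   caching of full-block inverses (results are independent of caching; the
#'   flag exists to validate that contract).
#' @return A list with `Ez` (`d x n`), `Ex` (`m x n` completed data),
#'   `loglik` (observed-data log-likelihood at `params`), sufficient
#'   statistics `Sx`, `Sz`, `Szz`, `Sxz`, `Sxx` (per-block list) and,
#'   optionally, the per-subject arrays.
#' @export
gpcca_estep <- function(params, x, subject_moments = FALSE, use_cache = TRUE) {
  stopifnot(inherits(params, "gpcca_params"), inherits(x, "multimodal_dataset"))
  check_params_data(params, x)
  X <- stacked_data(x)
  X[is.na(X)] <- 0
  res <- cpp_estep(X, x$mask, as.integer(x$block_sizes), params$W, params$mu,
                   params$Psi, use_cache, subject_moments)
  res$n <- ncol(X)
  res
}

#' M-step parameter updates
#'
#' Updates the mean vector, loading matrix and block-diagonal error
#' covariance from the E-step sufficient statistics, then applies the ridge
#' correction `Psi_ridge = Psi_hat + (1/lambda - 1) diag(Psi_hat)`, which is
#' equivalent to shrinking the error correlation matrix towards the identity:
#' `R_ridge = lambda * R_hat + (1 - lambda) * I`.
#'
#' @param moments output of [gpcca_estep()].
#' @param params parameters at which the moments were computed.
#' @param lambda ridge weight in `(0, 1]`; `lambda = 1` gives the unpenalized
#'   maximum-likelihood update.
#' @param schedule `"ecm"` updates `(mu, W)` by their joint closed-form
#'   maximizer and then `Psi` at the fresh values (a conditional-maximization
#'   step, guaranteeing a monotone objective); `"literal"` computes all three
#'   updates simultaneously from the previous iteration's parameters.
#' @param covariance `"block"` keeps within-modality covariances;
#'   `"diagonal"` truncates each block to its diagonal before the ridge step.
#' @param var_floor lower bound applied to the updated error variances.
#' @return A new `"gpcca_params"` object.
#' @export
gpcca_mstep <- function(moments, params, lambda = 1,
                        schedule = c("ecm", "literal"),
                        covariance = c("block", "diagonal"),
                        var_floor = 1e-6) {
  schedule <- match.arg(schedule)
  covariance <- match.arg(covariance)
  if (lambda <= 0 || lambda > 1) stop("'lambda' must be in (0, 1]")
  n <- moments$n
  d <- params$d
  Sx <- moments$Sx; Sz <- moments$Sz
  Szz <- moments$Szz; Sxz <- moments$Sxz

  if (schedule == "ecm") {
    # joint maximizer over (W, mu): augment z with a constant coordinate
    Baug <- rbind(cbind(Szz, Sz), c(Sz, n))
    sol <- tryCatch(t(solve(Baug, t(cbind(Sxz, Sx)))),
                    error = function(e)
                      stop("singular latent second-moment matrix; ",
                           "consider a smaller d", call. = FALSE))
    W_new <- sol[, seq_len(d), drop = FALSE]
    mu_new <- sol[, d + 1L]
    W_psi <- W_new; mu_psi <- mu_new
  } else {
    mu_new <- as.numeric(Sx - params$W %*% Sz) / n
    W_new <- tryCatch(t(solve(Szz, t(Sxz - params$mu %*% t(Sz)))),
                      error = function(e)
                        stop("singular latent second-moment matrix; ",
                             "consider a smaller d", call. = FALSE))
    W_psi <- params$W; mu_psi <- params$mu
  }

  Psi_new <- vector("list", length(params$block_sizes))
  for (r in seq_along(Psi_new)) {
    rows <- params$offsets[r] + seq_len(params$block_sizes[r])
    Wr <- W_psi[rows, , drop = FALSE]
    mur <- mu_psi[rows]
    Sxr <- Sx[rows]
    Sxzr <- Sxz[rows, , drop = FALSE]
    WSz <- as.numeric(Wr %*% Sz)
    P <- (moments$Sxx[[r]] -
            tcrossprod(Sxr, mur) - tcrossprod(mur, Sxr) -
            tcrossprod(Sxzr, Wr) - tcrossprod(Wr, Sxzr) +
            Wr %*% Szz %*% t(Wr) +
            tcrossprod(WSz, mur) + tcrossprod(mur, WSz)) / n +
      tcrossprod(mur, mur)
    P <- (P + t(P)) / 2
    if (covariance == "diagonal")
      P <- diag(diag(P), nrow = nrow(P))
    P <- P + (1 / lambda - 1) * diag(diag(P), nrow = nrow(P))
    diag(P) <- pmax(diag(P), var_floor)
    Psi_new[[r]] <- P
  }
  names(Psi_new) <- names(params$Psi)
  out <- params
  out$W <- W_new
  out$mu <- as.numeric(mu_new)
  out$Psi <- Psi_new
  out$covariance <- covariance
  out
}

#' Fit the GPCCA model by EM
#'
#' Estimates the loading matrix, mean vector and block-diagonal error
#' covariance of the generalized probabilistic CCA model from a multi-modal
#' dataset with arbitrary (entry-wise or modality-wise) missingness,
#' alternating the conditional expectations of [gpcca_estep()] with the
#' ridge-regularized updates of [gpcca_mstep()] until the monitored objective
#' (observed-data log-likelihood, penalized when `lambda < 1`) stabilizes.
#'
#' @inheritParams gpcca_init
#' @param lambda ridge weight in `(0, 1]`; the error correlation matrix is
#'   shrunk as `lambda * R + (1 - lambda) * I` at every M-step. `1/2` and
#'   `2/3` are robust defaults.
#' @param covariance `"block"` (within-modality residual correlations
#'   allowed) or `"diagonal"` (strictly diagonal error covariance).
#' @param max_iter maximum number of EM iterations.
#' @param tol relative convergence tolerance on the monitored objective.
#' @param schedule M-step schedule, see [gpcca_mstep()].
#' @param init optional `"gpcca_params"` starting point overriding
#'   [gpcca_init()].
#' @param use_cache see [gpcca_estep()].
#' @param verbose print the objective every 10 iterations.
#' @return An object of class `"gpcca"`: list with `params`, `embedding`
#'   (`d x n` posterior latent means at the final parameters), `loglik`
#'   (trace of the observed-data log-likelihood), `objective` (penalized
#'   trace; equal to `loglik` when `lambda = 1`), `n_iter`, `converged`, and
#'   the fitting configuration in `config`.
#' @examples
#' sim <- simulate_multimodal("A", rho = 0.5, missing_rate = 0.1,
#'                            n_per_cluster = 20, modality_dims = c(10, 15, 20),
#'                            seed = 1)
#' fit <- gpcca_fit(sim$data, d = 3, lambda = 2/3, max_iter = 50, seed = 1)
#' dim(fit$embedding)
#' @export
gpcca_fit <- function(x, d, lambda = 1/2,
                      covariance = c("block", "diagonal"),
                      max_iter = 500L, tol = 1e-6,
                      init_scale = 0.1, seed = 1L,
                      schedule = c("ecm", "literal"),
                      init = NULL, var_floor = 1e-6,
                      use_cache = TRUE, verbose = FALSE) {
  stopifnot(inherits(x, "multimodal_dataset"))
  covariance <- match.arg(covariance)
  schedule <- match.arg(schedule)
  if (lambda <= 0 || lambda > 1) stop("'lambda' must be in (0, 1]")
  if (tol <= 0) stop("'tol' must be positive")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("'max_iter' must be at least 1")

  params <- if (is.null(init)) {
    p <- gpcca_init(x, d, init_scale = init_scale, seed = seed,
                    var_floor = var_floor)
    p$covariance <- covariance
    p
  } else {
    check_params_data(init, x)
    init
  }
  n <- length(x$sample_ids)

  ll_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  iter <- 0L
  small_steps <- 0L
  for (t in 0:max_iter) {
    es <- gpcca_estep(params, x, subject_moments = FALSE, use_cache = use_cache)
    ll_trace <- c(ll_trace, es$loglik)
    obj <- es$loglik - ridge_penalty(params, lambda, n)
    obj_trace <- c(obj_trace, obj)
    if (verbose && t %% 10L == 0L)
      message(sprintf("iter %3d  objective %.6f", t, obj))
    if (t > 0L) {
      prev <- obj_trace[t]
      # two consecutive small steps guard against a single near-stationary
      # step early in the run (the ridge iteration is not strictly monotone)
      if (abs(obj - prev) < tol * (abs(prev) + .Machine$double.eps)) {
        small_steps <- small_steps + 1L
      } else {
        small_steps <- 0L
      }
      if (small_steps >= 2L) {
        converged <- TRUE
        break
      }
    }
    if (t == max_iter) break
    params <- gpcca_mstep(es, params, lambda = lambda, schedule = schedule,
                          covariance = covariance, var_floor = var_floor)
    iter <- t + 1L
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations (tol = ", tol, ")")

  embedding <- es$Ez
  rownames(embedding) <- paste0("factor_", seq_len(params$d))
  colnames(embedding) <- x$sample_ids

  structure(
    list(params = params, embedding = embedding,
         loglik = ll_trace, objective = obj_trace,
         n_iter = iter, converged = converged,
         config = list(d = params$d, lambda = lambda, covariance = covariance,
                       max_iter = max_iter, tol = tol, seed = seed,
                       init_scale = init_scale, schedule = schedule,
                       var_floor = var_floor)),
    class = "gpcca")
}

#' @export
print.gpcca <- function(x, ...) {
  cat("gpcca fit: d =", x$params$d,
      ", lambda =", format(x$config$lambda),
      ", iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  final log-likelihood:", format(x$loglik[length(x$loglik)]), "\n")
  invisible(x)
}

#' Observed-data log-likelihood
#'
#' Sum over subjects of the log-density of the observed sub-vector under the
#' marginal Gaussian `N(mu~, W~ W~' + Psi~)` restricted to the observed rows,
#' evaluated with the Woodbury/determinant-lemma form.
#'
#' @param params a `"gpcca_params"` object (or a fitted `"gpcca"` model).
#' @param x a [multimodal_dataset()].
#' @return A scalar log-likelihood.
#' @export
gpcca_loglik <- function(params, x) {
  if (inherits(params, "gpcca")) params <- params$params
  gpcca_estep(params, x)$loglik
}

#' Project subjects onto the latent factors
#'
#' Returns the posterior mean of the latent factor vector for every subject,
#' `E(z_k | x~_k)` at the fitted parameters. Works for new subjects with any
#' missingness pattern (transform semantics); every subject must have at
#' least one observed entry.
#'
#' @param object a fitted `"gpcca"` model.
#' @param newdata optional [multimodal_dataset()] with the same block
#'   structure; defaults to returning the embedding of the training data.
#' @return A `d x n` matrix of posterior latent means.
#' @export
gpcca_embed <- function(object, newdata = NULL) {
  stopifnot(inherits(object, "gpcca"))
  if (is.null(newdata)) return(object$embedding)
  es <- gpcca_estep(object$params, newdata)
  emb <- es$Ez
  rownames(emb) <- paste0("factor_", seq_len(object$params$d))
  colnames(emb) <- newdata$sample_ids
  emb
}

#' Impute missing entries
#'
#' Replaces every unobserved entry by its conditional expectation
#' `W_i E(z_k | x~_k) + mu_i` at the fitted parameters; observed entries are
#' returned unchanged (bit-exact).
#'
#' @param object a fitted `"gpcca"` model.
#' @param x the dataset to complete (the model does not store its training
#'   data; any dataset with the same block structure is accepted).
#' @return A completed [multimodal_dataset()] with an all-ones mask.
#' @export
gpcca_impute <- function(object, x) {
  stopifnot(inherits(object, "gpcca"), inherits(x, "multimodal_dataset"))
  check_params_data(object$params, x)
  es <- gpcca_estep(object$params, x)
  multimodal_dataset(split_blocks(es$Ex, x), sample_ids = x$sample_ids)
}

#' Partial-observation view for one subject
#'
#' Extracts the observed-data quantities used by the E-step for a single
#' subject: the observed rows, data sub-vector, partial loadings, partial
#' means, the observed sub-blocks of the error covariance, and the `d x d`
#' Woodbury matrix `M~ = (I + W~' Psi~^-1 W~)^-1` computed by blockwise
#' inversion. Mainly a diagnostic / testing surface.
#'
#' @param params a `"gpcca_params"` object.
#' @param x a [multimodal_dataset()].
#' @param k subject index (column).
#' @return A list with `observed_rows` (stacked indices), `x_tilde`,
#'   `W_tilde`, `mu_tilde`, `Psi_tilde_blocks` (observed sub-block per
#'   modality, dropped when a modality is entirely missing) and `M_tilde`.
#' @export
gpcca_partial <- function(params, x, k) {
  stopifnot(inherits(params, "gpcca_params"), inherits(x, "multimodal_dataset"))
  check_params_data(params, x)
  k <- as.integer(k)
  X <- stacked_data(x)
  obs <- which(x$mask[, k] == 1L)
  if (length(obs) == 0L) stop("subject ", k, " has no observed entries")
  S <- diag(params$d)
  Psi_blocks <- list()
  for (r in seq_along(params$block_sizes)) {
    rows <- params$offsets[r] + seq_len(params$block_sizes[r])
    o <- intersect(rows, obs)
    if (length(o) == 0L) next
    Pb <- params$Psi[[r]][match(o, rows), match(o, rows), drop = FALSE]
    Psi_blocks[[names(params$Psi)[r]]] <- Pb
    Wo <- params$W[o, , drop = FALSE]
    sol <- tryCatch(solve(Pb, Wo), error = function(e)
      stop("singular observed error-covariance block in modality '",
           names(params$Psi)[r], "' for subject ", k, call. = FALSE))
    S <- S + crossprod(Wo, sol)
  }
  list(subject = k,
       observed_rows = obs,
       x_tilde = X[obs, k],
       W_tilde = params$W[obs, , drop = FALSE],
       mu_tilde = params$mu[obs],
       Psi_tilde_blocks = Psi_blocks,
       M_tilde = solve((S + t(S)) / 2))
}
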