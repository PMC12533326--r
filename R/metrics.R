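#' Adjusted Rand index
#'
#' Chance-adjusted agreement between two partitions of the same samples,
#' computed from the contingency table under the permutation model. Equals 1
#' exactly when the partitions are identical (up to relabeling) and has
#' expectation 0 for independent random partitions.
#'
#' @param a,b integer (or factor/character) label vectors of equal length.
#' @return A scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  check_label_pair(a, b)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1) # both partitions trivial and identical
  (sum_ij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by a symmetric
#' combination of their entropies; lies in `[0, 1]` with 1 for identical
#' partitions and 0 for independent ones.
#'
#' @param a,b integer (or factor/character) label vectors of equal length.
#' @param normalization how to combine the two partition entropies in the
#'   denominator; the arithmetic mean (default) is the common convention.
#' @return A scalar in `[0, 1]`.
#' @export
normalized_mutual_info <- function(a, b,
                                   normalization = c("arithmetic", "geometric",
                                                     "min", "max")) {
  check_label_pair(a, b)
  normalization <- match.arg(normalization)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1) # two trivial (hence identical) partitions
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  min = min(ha, hb),
                  max = max(ha, hb))
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

check_label_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors differ in length (", length(a), " vs ", length(b), ")")
  if (length(a) == 0L) stop("label vectors are empty")
  if (anyNA(a) || anyNA(b)) stop("label vectors must not contain NA")
  invisible(TRUE)
}
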