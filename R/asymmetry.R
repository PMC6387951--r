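#' Interhemispheric mean difference
#'
#' The first of the two asymmetry statistics: the contralesional ROI mean
#' minus the ipsilesional ROI mean, in the units of the parameter map. For
#' a parameter that falls on the lesioned side (FA, GFA, AD) the statistic
#' is positive in stroke; for one that rises (ODI) it is negative.
#'
#' @param contra_values,ipsi_values Nonempty numeric vectors of voxel
#'   values from the contralesional and ipsilesional ROI.
#' @return `mean(contra_values) - mean(ipsi_values)`.
#' @export
#' @examples
#' delta_mean(c(0.3, 0.5, 0.7), c(0.2, 0.4, 0.6))  # 0.1
delta_mean <- function(contra_values, ipsi_values) {
  check_sample(contra_values, "contra_values")
  check_sample(ipsi_values, "ipsi_values")
  mean(contra_values) - mean(ipsi_values)
}

check_sample <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop(sprintf("`%s` must be a nonempty numeric vector", what))
  }
  if (anyNA(x)) stop(sprintf("`%s` contains missing values", what))
  invisible(x)
}

#' Shared-edge histogram pair for two ROI samples
#'
#' Bins both samples on one common partition: `n_bins` equal-width bins
#' spanning the pooled min-max of the two samples. Bins are half-open
#' `[e_i, e_{i+1})` with the last bin closed, so every value is counted
#' exactly once. A divergence is only meaningful on a common partition,
#' which is why the edges are shared. If the pooled range is zero the
#' histogram degenerates to a single bin holding everything and the
#' `degenerate` flag is set.
#'
#' @inheritParams delta_mean
#' @param n_bins Number of bins (default 10).
#' @return A list of class `histogram_pair`: `edges`, `counts_C`,
#'   `counts_I`, shrinkage-estimated probabilities `p_C`, `p_I`, `n_bins`,
#'   `degenerate`.
#' @seealso [shrink_probabilities()], [delta_kld()]
#' @export
shared_histogram <- function(contra_values, ipsi_values, n_bins = 10L) {
  check_sample(contra_values, "contra_values")
  check_sample(ipsi_values, "ipsi_values")
  stopifnot(n_bins >= 1)
  pooled <- range(c(contra_values, ipsi_values))
  if (diff(pooled) == 0) {
    out <- list(edges = pooled, counts_C = length(contra_values),
                counts_I = length(ipsi_values), p_C = 1, p_I = 1,
                n_bins = 1L, degenerate = TRUE)
    return(structure(out, class = "histogram_pair"))
  }
  edges <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
  counts_C <- bin_counts(contra_values, pooled, n_bins)
  counts_I <- bin_counts(ipsi_values, pooled, n_bins)
  structure(list(edges = edges,
                 counts_C = counts_C, counts_I = counts_I,
                 p_C = shrink_probabilities(counts_C),
                 p_I = shrink_probabilities(counts_I),
                 n_bins = as.integer(n_bins), degenerate = FALSE),
            class = "histogram_pair")
}

# [e_i, e_{i+1}) membership, last bin closed at the pooled maximum.
bin_counts <- function(x, pooled, n_bins) {
  width <- diff(pooled) / n_bins
  idx <- pmin(floor((x - pooled[1]) / width) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' James-Stein shrinkage estimate of bin probabilities
#'
#' Regularised cell-probability estimator that shrinks the empirical bin
#' frequencies toward the uniform distribution. With empirical frequencies
#' `theta_k = counts_k / N` over `B` bins, the shrinkage intensity is
#'
#' \deqn{\lambda^* = \frac{1 - \sum_k \theta_k^2}
#'                        {(N - 1) \sum_k (1/B - \theta_k)^2}}
#'
#' clipped to `[0, 1]`, and the estimate is
#' `p = lambda * (1/B) + (1 - lambda) * theta`. At small counts the
#' estimate pulls strongly toward uniform (keeping every bin probability
#' strictly positive, so log-ratios stay finite); as `N` grows `lambda`
#' vanishes and `p` converges to the empirical frequencies. When the
#' empirical frequencies are already uniform the denominator is zero and
#' the uniform vector is returned directly.
#'
#' @param counts Nonnegative integer vector of per-bin counts, at least
#'   two bins, total count at least 1.
#' @return Probability vector summing to 1.
#' @references James-Stein shrinkage estimation of cell frequencies as
#'   used in entropy and divergence estimation (Hausser & Strimmer, JMLR
#'   2009).
#' @export
#' @examples
#' shrink_probabilities(c(3, 1))    # lambda = 1: fully uniform
#' shrink_probabilities(c(12, 4))   # lambda = 0.2: c(0.7, 0.3)
shrink_probabilities <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be nonnegative numbers")
  }
  if (any(counts != round(counts))) stop("`counts` must be integers")
  B <- length(counts)
  N <- sum(counts)
  if (N < 1) stop("total count is zero")
  if (B < 2) stop("need at least 2 bins")
  theta <- counts / N
  den <- (N - 1) * sum((1 / B - theta)^2)
  if (den == 0) return(rep(1 / B, B))
  lambda <- min(1, max(0, (1 - sum(theta^2)) / den))
  lambda / B + (1 - lambda) * theta
}

#' Half Kullback-Leibler divergence between two probability vectors
#'
#' The directional form as used by the asymmetry statistic:
#' `0.5 * sum(p_C * ln(p_C / p_I))`, in nats. Terms with `p_C = 0`
#' contribute zero; a bin with `p_C > 0` and `p_I = 0` makes the
#' divergence infinite. `symmetrized = TRUE` instead computes
#' `0.5 * (D(C||I) + D(I||C))` (the Jeffreys-type average).
#'
#' @param p_C,p_I Probability vectors on the same partition.
#' @param symmetrized Average the two directional divergences?
#' @return Nonnegative scalar (nats), possibly `Inf`.
#' @export
#' @examples
#' kld_from_probs(c(0.7, 0.3), c(0.5, 0.5))  # 0.04114
kld_from_probs <- function(p_C, p_I, symmetrized = FALSE) {
  stopifnot(length(p_C) == length(p_I),
            all(p_C >= 0), all(p_I >= 0))
  if (symmetrized) {
    return(0.5 * (kl_directional(p_C, p_I) + kl_directional(p_I, p_C)))
  }
  0.5 * kl_directional(p_C, p_I)
}

kl_directional <- function(p, q) {
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Kullback-Leibler divergence asymmetry of two ROI samples
#'
#' The second asymmetry statistic: bins the two samples on a shared
#' 10-bin partition ([shared_histogram()]), estimates bin probabilities
#' with James-Stein shrinkage toward uniform ([shrink_probabilities()]),
#' and returns the half KL divergence of the contralesional distribution
#' from the ipsilesional one, in nats. Unlike the mean difference it is
#' sensitive to any distributional change (spread, shape), not only a
#' location shift, and is unbounded above.
#'
#' @inheritParams shared_histogram
#' @param symmetrized Compute `0.5 * (D(C||I) + D(I||C))` instead of the
#'   directional `0.5 * D(C||I)` (default `FALSE`).
#' @param epsilon Optional probability floor applied to both estimated
#'   probability vectors (then renormalised) before the divergence; `0`
#'   (default) disables it, leaving infinite divergences representable.
#' @return Nonnegative scalar with attribute `degenerate` (`TRUE` when the
#'   pooled sample range was zero and a single bin was used, in which case
#'   the divergence is 0).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200, 0.5, 0.05)
#' delta_kld(x, x)               # exactly 0
#' delta_kld(x, x + 0.03) > 0    # location shift registers
delta_kld <- function(contra_values, ipsi_values, n_bins = 10L,
                      symmetrized = FALSE, epsilon = 0) {
  hp <- shared_histogram(contra_values, ipsi_values, n_bins)
  p_C <- hp$p_C
  p_I <- hp$p_I
  if (epsilon > 0) {
    p_C <- pmax(p_C, epsilon); p_C <- p_C / sum(p_C)
    p_I <- pmax(p_I, epsilon); p_I <- p_I / sum(p_I)
  }
  out <- if (hp$degenerate) 0 else kld_from_probs(p_C, p_I, symmetrized)
  attr(out, "degenerate") <- hp$degenerate
  out
}

#' Natural log of the KLD asymmetry
#'
#' The validation stage correlates outcomes with the log-transformed KLD.
#' Natural log throughout; a nonpositive divergence has no log and is
#' reported as missing (`NA`) for that subject.
#'
#' @param delta_kld Scalar divergence (nats), or a vector of them.
#' @return `log(delta_kld)`, `NA` where the input is not strictly
#'   positive or not finite.
#' @export
log_kld <- function(delta_kld) {
  out <- rep(NA_real_, length(delta_kld))
  ok <- is.finite(delta_kld) & delta_kld > 0
  out[ok] <- log(delta_kld[ok])
  out
}

#' Per-subject asymmetry table for one region
#'
#' Applies both asymmetry statistics to every subject x parameter pair of
#' a cohort sample table, for one region (the PLIC by default, the region
#' the outcome analysis focuses on).
#'
#' @param samples Sample table from [generate_cohort()] (or assembled from
#'   [extract_roi_sample()] calls): columns `subject_id`, `region`,
#'   `side`, `parameter`, list column `values`.
#' @param region Region to analyse (default `"PLIC"`).
#' @param n_bins Histogram bins for the KLD (default 10).
#' @param symmetrized Passed to [delta_kld()].
#' @return Data frame: `subject_id`, `region`, `parameter`, `delta_mean`,
#'   `delta_kld`, `log_delta_kld`, `degenerate`.
#' @export
roi_asymmetry <- function(samples, region = "PLIC", n_bins = 10L,
                          symmetrized = FALSE) {
  sub <- samples[samples$region == region, ]
  if (nrow(sub) == 0L) stop("no samples for region ", region)
  keys <- unique(sub[, c("subject_id", "parameter")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    contra <- roi_values(sub, keys$subject_id[i], region,
                         "contralesional", keys$parameter[i])
    ipsi <- roi_values(sub, keys$subject_id[i], region,
                       "ipsilesional", keys$parameter[i])
    dm <- delta_mean(contra, ipsi)
    dk <- delta_kld(contra, ipsi, n_bins = n_bins, symmetrized = symmetrized)
    data.frame(subject_id = keys$subject_id[i], region = region,
               parameter = keys$parameter[i], delta_mean = dm,
               delta_kld = as.numeric(dk), log_delta_kld = log_kld(dk),
               degenerate = attr(dk, "degenerate"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
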