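test_that("delta_mean computes the contralesional-minus-ipsilesional mean", {
  expect_equal(delta_mean(c(0.3, 0.5, 0.7), c(0.2, 0.4, 0.6)), 0.1)
  x <- runif(20)
  expect_equal(delta_mean(x, x), 0)
  expect_error(delta_mean(numeric(0), 1), "nonempty")
  expect_error(delta_mean(c(1, NA), c(1, 2)), "missing")
})

test_that("delta_mean is antisymmetric and shift-equivariant", {
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(12); cshift <- rnorm(1)
    expect_equal(delta_mean(a, b), -delta_mean(b, a))
    expect_equal(delta_mean(a, b + cshift), delta_mean(a, b) - cshift)
  }
})

test_that("shared_histogram bins both samples on a common partition", {
  hp <- shared_histogram(c(0, 1), c(0, 1), n_bins = 2)
  expect_equal(hp$edges, c(0, 0.5, 1))
  expect_equal(hp$counts_C, c(1, 1))  # right edge closed
  expect_equal(hp$counts_I, c(1, 1))
  expect_false(hp$degenerate)
})

test_that("histogram counts partition each sample", {
  set.seed(11)
  for (i in 1:15) {
    a <- rnorm(sample(5:80, 1)); b <- rnorm(sample(5:80, 1), 0.3)
    hp <- shared_histogram(a, b, n_bins = sample(2:12, 1))
    expect_equal(sum(hp$counts_C), length(a))
    expect_equal(sum(hp$counts_I), length(b))
    expect_equal(sum(hp$p_C), 1)
    expect_equal(sum(hp$p_I), 1)
  }
})

test_that("identical constant samples degenerate to one flagged bin", {
  hp <- shared_histogram(rep(0.4, 5), rep(0.4, 8))
  expect_true(hp$degenerate)
  expect_equal(hp$counts_C, 5)
  expect_equal(hp$counts_I, 8)
  dk <- delta_kld(rep(0.4, 5), rep(0.4, 8))
  expect_equal(as.numeric(dk), 0)
  expect_true(attr(dk, "degenerate"))
})

test_that("shrinkage probabilities match hand-evaluated lambda examples", {
  expect_equal(shrink_probabilities(c(5, 5)), c(0.5, 0.5))
  # theta = (.75,.25), lambda = .375/.375 = 1 -> uniform
  expect_equal(shrink_probabilities(c(3, 1)), c(0.5, 0.5))
  # theta = (.75,.25), lambda = .375/1.875 = 0.2 -> (0.7, 0.3)
  expect_equal(shrink_probabilities(c(12, 4)), c(0.7, 0.3))
  expect_error(shrink_probabilities(c(0, 0)), "zero")
  expect_error(shrink_probabilities(5), "bins")
  expect_error(shrink_probabilities(c(-1, 2)), "nonnegative")
})

test_that("shrinkage vanishes as the sample grows", {
  probs <- c(0.5, 0.2, 0.2, 0.05, 0.05)
  set.seed(12)
  dev <- sapply(c(1e2, 1e4), function(N) {
    counts <- as.vector(table(factor(sample(1:5, N, TRUE, probs),
                                     levels = 1:5)))
    max(abs(shrink_probabilities(counts) - counts / N))
  })
  expect_lt(dev[2], dev[1])
  expect_lt(dev[2], 1e-3)   # empirical frequencies recovered at N = 1e4
})

test_that("half-KL on fixed probabilities matches hand arithmetic", {
  expect_equal(kld_from_probs(c(0.7, 0.3), c(0.5, 0.5)),
               0.5 * (0.7 * log(1.4) + 0.3 * log(0.6)))
  expect_equal(kld_from_probs(c(0.7, 0.3), c(0.5, 0.5)), 0.04114144,
               tolerance = 1e-6)
  # directional infinity when the reference distribution has an empty bin
  expect_equal(kld_from_probs(c(0.5, 0.5), c(1, 0)), Inf)
  expect_equal(kld_from_probs(c(1, 0), c(1, 0)), 0)
})

test_that("delta_kld agrees with an independent brute-force oracle", {
  # oracle: histogram via cut(), shrinkage and half-KL typed out separately
  oracle_kld <- function(a, b, bins = 10) {
    e <- seq(min(c(a, b)), max(c(a, b)), length.out = bins + 1)
    count <- function(x) {
      cts <- numeric(bins)
      for (v in x) {
        j <- bins
        for (k in seq_len(bins - 1)) {
          if (v >= e[k] && v < e[k + 1]) { j <- k; break }
        }
        cts[j] <- cts[j] + 1
      }
      cts
    }
    shrunk <- function(cts) {
      N <- sum(cts); th <- cts / N
      den <- (N - 1) * sum((1 / bins - th)^2)
      lam <- if (den == 0) 1 else min(1, max(0, (1 - sum(th^2)) / den))
      lam / bins + (1 - lam) * th
    }
    p <- shrunk(count(a)); q <- shrunk(count(b))
    s <- 0
    for (k in seq_len(bins)) {
      if (p[k] > 0) s <- s + p[k] * log(p[k] / q[k])
    }
    s / 2
  }
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(sample(8:40, 1), 0.5, 0.1)
    b <- rnorm(sample(8:40, 1), 0.55, 0.12)
    expect_equal(as.numeric(delta_kld(a, b)), oracle_kld(a, b),
                 tolerance = 1e-12)
  }
})

test_that("symmetrized divergence averages the two directions", {
  set.seed(14)
  a <- rnorm(30, 0.4, 0.05); b <- rnorm(30, 0.5, 0.08)
  d_ab <- as.numeric(delta_kld(a, b))  # = D(C||I) / 2
  d_ba <- as.numeric(delta_kld(b, a))  # = D(I||C) / 2
  expect_equal(as.numeric(delta_kld(a, b, symmetrized = TRUE)),
               d_ab + d_ba, tolerance = 1e-12)
})

test_that("log_kld is the natural log, missing when undefined", {
  expect_equal(log_kld(1), 0)
  expect_equal(log_kld(exp(1)), 1)
  expect_equal(log_kld(0.04114144), -3.190739, tolerance = 1e-6)
  expect_true(is.na(log_kld(0)))
  expect_true(is.na(log_kld(-1)))
  expect_true(is.na(log_kld(Inf)))
})

test_that("roi_asymmetry produces one row per subject and parameter", {
  cohort <- generate_cohort(small_config(seed = 21))
  asym <- roi_asymmetry(cohort$samples)
  expect_equal(nrow(asym), 18 * 2)
  expect_true(all(asym$delta_kld >= 0))
  expect_false(any(asym$degenerate))
  # spot-check one cell against direct statistic calls
  contra <- roi_values(cohort$samples, "S03", "PLIC", "contralesional", "ODI")
  ipsi <- roi_values(cohort$samples, "S03", "PLIC", "ipsilesional", "ODI")
  row <- asym[asym$subject_id == "S03" & asym$parameter == "ODI", ]
  expect_equal(row$delta_mean, delta_mean(contra, ipsi))
  expect_equal(row$delta_kld, as.numeric(delta_kld(contra, ipsi)))
  expect_error(roi_asymmetry(cohort$samples, region = "thalamus"),
               "no samples")
})
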