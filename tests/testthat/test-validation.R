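test_that("split enumeration is exhaustive, ordered, and validated", {
  splits <- enumerate_splits(9, 3)
  expect_length(splits, choose(9, 3))
  membership <- tabulate(unlist(lapply(splits, `[[`, "test")), nbins = 9)
  expect_equal(membership, rep(choose(8, 2), 9))
  expect_length(enumerate_splits(3, 1), 3)
  # lexicographic order of test tuples
  first <- do.call(rbind, lapply(splits[1:3], `[[`, "test"))
  expect_equal(first, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(enumerate_splits(3, 3), "n > k_test")
})

test_that("fit_line recovers exact lines and matches the normal equations", {
  x <- c(1, 2, 3, 5)
  fit <- fit_line(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    fit <- fit_line(x, y)
    slope <- (sum(x * y) - length(x) * mean(x) * mean(y)) /
      (sum(x^2) - length(x) * mean(x)^2)
    intercept <- mean(y) - slope * mean(x)
    r2 <- 1 - sum((y - intercept - slope * x)^2) / sum((y - mean(y))^2)
    expect_equal(fit$slope, slope, tolerance = 1e-12)
    expect_equal(fit$intercept, intercept, tolerance = 1e-12)
    expect_equal(fit$r2, r2, tolerance = 1e-9)  # near-zero r2: absolute scale
  }
  expect_error(fit_line(rep(2, 5), rnorm(5)), "constant predictor")
  expect_warning(fit_line(rnorm(5), rep(3, 5)), "constant outcome")
})

test_that("nrmse normalises the RMSE and scales correctly", {
  expect_equal(nrmse(c(1, 9), c(0, 10), 10), 0.1)
  expect_equal(nrmse(c(5, 5), c(5, 5), 3), 0)
  set.seed(32)
  p <- rnorm(8); o <- rnorm(8)
  expect_equal(nrmse(2 * p, 2 * o, 2 * 4), nrmse(p, o, 4))
  expect_error(nrmse(p, o, 0), "positive")
})

test_that("best-fit-line selection picks the split nearest the mean NRMSE", {
  expect_equal(select_best_line(c(0.1, 0.2, 0.3)), 2)
  expect_equal(select_best_line(c(0.1, 0.3)), 1)  # tie: earliest split
  expect_equal(select_best_line(0.42), 1)
})

test_that("optimism adjustment subtracts the mean training excess", {
  expect_equal(optimism_adjusted_r2(0.8, rep(0.8, 10)), 0.8)
  expect_equal(optimism_adjusted_r2(0.9, c(0.95, 0.85)), 0.9)
  expect_equal(optimism_adjusted_r2(0.83, rep(1, 84)), 0.66)
})

test_that("a noiseless linear relation validates perfectly", {
  x <- seq(-0.1, 0.1, length.out = 9)
  vs <- validate_predictor(x, 60 + 400 * x)
  expect_equal(vs$n_splits, 84)
  expect_equal(vs$r2_adjusted, 1)
  expect_equal(vs$final_nrmse, 0)
  expect_equal(vs$mean_nrmse_test, 0)
})

test_that("the full procedure matches a brute-force oracle at n = 5, k = 1", {
  # independent re-implementation: explicit loops, no shared helpers
  oracle <- function(x, y) {
    n <- length(x)
    rng <- max(y) - min(y)
    slopes <- inter <- r2s <- errs <- numeric(n)
    for (j in 1:n) {
      xt <- x[-j]; yt <- y[-j]
      b <- sum((xt - mean(xt)) * (yt - mean(yt))) / sum((xt - mean(xt))^2)
      a <- mean(yt) - b * mean(xt)
      r2s[j] <- 1 - sum((yt - a - b * xt)^2) / sum((yt - mean(yt))^2)
      errs[j] <- sqrt(mean((a + b * x[j] - y[j])^2)) / rng
      slopes[j] <- b; inter[j] <- a
    }
    best <- which.min(abs(errs - mean(errs)))
    b0 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a0 <- mean(y) - b0 * mean(x)
    r2f <- 1 - sum((y - a0 - b0 * x)^2) / sum((y - mean(y))^2)
    list(r2_adj = r2f - mean(r2s - r2f),
         mean_nrmse = mean(errs),
         final = sqrt(mean((inter[best] + slopes[best] * x - y)^2)) / rng,
         best = best)
  }
  set.seed(33)
  for (i in 1:5) {
    x <- rnorm(5); y <- 2 * x + rnorm(5)
    vs <- validate_predictor(x, y, k_test = 1)
    ref <- oracle(x, y)
    expect_equal(vs$r2_adjusted, ref$r2_adj, tolerance = 1e-13)
    expect_equal(vs$mean_nrmse_test, ref$mean_nrmse, tolerance = 1e-13)
    expect_equal(vs$final_nrmse, ref$final, tolerance = 1e-13)
    expect_equal(vs$best_split, ref$best)
  }
})

test_that("validation is deterministic and handles missing subjects", {
  set.seed(34)
  x <- rnorm(9); y <- 3 * x + rnorm(9)
  a <- validate_predictor(x, y)
  b <- validate_predictor(x, y)
  expect_identical(a, b)
  x[4] <- NA
  expect_warning(vs <- validate_predictor(x, y), "dropping 1 subject")
  expect_equal(vs$n, 8)
  expect_equal(vs$n_splits, choose(8, 3))
  expect_error(suppressWarnings(
    validate_predictor(c(1, 2, 3, 4, NA), c(1, 2, 3, 4, 5))),
    "at least 5")
})

test_that("permuted outcomes show no optimism-adjusted association", {
  set.seed(35)
  d <- runif(9, 0, 0.1)
  y <- 60 - 550 * d + rnorm(9, 0, 3)
  vs <- validate_predictor(-d, sample(y))
  expect_lt(vs$r2_adjusted, 0.3)
})

test_that("validate_outcomes covers the predictor-by-outcome grid", {
  cohort <- generate_cohort(small_config(seed = 36))
  asym <- roi_asymmetry(cohort$samples)
  res <- validate_outcomes(asym, cohort$subjects)
  expect_equal(nrow(res), 2 * 2 * 2)  # 2 parameters x 2 predictors x 2 outcomes
  expect_true(all(res$n == 9))        # controls dropped (no FM scores)
  expect_true(all(res$n_splits == 84))
  # strong injected effect: the mean-difference predictor carries signal
  expect_gt(min(res$r2_adjusted[res$predictor == "delta_mean" &
                                  res$outcome == "fm_ue_tp2"]), 0.3)
})
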