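#' Enumerate exhaustive train/test combination splits
#'
#' All `choose(n, k_test)` ways of holding out `k_test` subjects as a test
#' set, in lexicographic order of the test-index tuples (deterministic).
#' For the study cohort size, `enumerate_splits(9, 3)` yields the 84
#' six-train / three-test repetitions of the combination validation.
#'
#' @param n Cohort size.
#' @param k_test Held-out test-set size (default 3).
#' @return List of lists with integer index vectors `train` and `test`.
#' @export
#' @examples
#' length(enumerate_splits(9, 3))  # 84
enumerate_splits <- function(n, k_test = 3L) {
  if (!(n > k_test && k_test >= 1)) {
    stop("need n > k_test >= 1, got n = ", n, ", k_test = ", k_test)
  }
  test_sets <- combn(n, k_test)
  lapply(seq_len(ncol(test_sets)), function(j) {
    test <- test_sets[, j]
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Ordinary least-squares line fit
#'
#' One-predictor OLS via [stats::lm()], returning only what the
#' combination validation needs: the line and its in-sample r-squared
#' (`1 - SS_res / SS_tot`). A constant outcome has no explainable
#' variance; its r-squared is defined as 0 with a warning. A constant
#' predictor has no defined line and is an error.
#'
#' @param x Predictor vector (length >= 2, not constant).
#' @param y Outcome vector, same length.
#' @return List: `slope`, `intercept`, `r2`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (anyNA(x) || anyNA(y)) stop("missing values in regression input")
  if (var(x) == 0) stop("constant predictor: regression line undefined")
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant outcome: r-squared defined as 0")
    0
  } else {
    1 - sum(fit$residuals^2) / ss_tot
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2)
}

#' Normalized root-mean-square error
#'
#' RMSE of predictions divided by a fixed normalizer. The validation uses
#' the range (max - min) of the observed outcome over the full cohort as
#' the normalizer for every split and for the final fit, so split NRMSEs
#' are comparable and dimensionless.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @param normalizer Positive scalar.
#' @return `sqrt(mean((predicted - observed)^2)) / normalizer`.
#' @export
#' @examples
#' nrmse(c(1, 9), c(0, 10), 10)  # 0.1
nrmse <- function(predicted, observed, normalizer) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 1)
  if (!is.numeric(normalizer) || length(normalizer) != 1 || normalizer <= 0) {
    stop("`normalizer` must be a positive scalar")
  }
  sqrt(mean((predicted - observed)^2)) / normalizer
}

#' Select the best-fit line among combination splits
#'
#' The "line of best fit" of the combination scheme: the training-split
#' line whose test-set NRMSE is closest (absolute distance) to the mean
#' test NRMSE over all splits. Ties go to the earliest split in
#' enumeration order.
#'
#' @param nrmse_test Numeric vector of per-split test NRMSEs, in
#'   enumeration order.
#' @return Integer index of the selected split.
#' @export
select_best_line <- function(nrmse_test) {
  stopifnot(length(nrmse_test) >= 1, !anyNA(nrmse_test))
  dist <- abs(nrmse_test - mean(nrmse_test))
  # tolerance guards the earliest-split tie-break against rounding noise
  which(dist <= min(dist) + 1e-12)[1]
}

#' Optimism-adjusted r-squared
#'
#' Corrects the full-data r-squared for the optimism of small-sample
#' training fits: the mean excess of the training r-squared over the
#' full-data r-squared is subtracted from the full-data r-squared,
#' `r2_full - mean(r2_train - r2_full)`. Differences are signed, so a
#' training fit worse than the full fit reduces the correction.
#'
#' @param r2_full Full-data coefficient of determination.
#' @param r2_train Vector of per-split training r-squared values.
#' @return Adjusted r-squared (can be negative for uninformative
#'   predictors).
#' @export
#' @examples
#' optimism_adjusted_r2(0.83, rep(1, 84))  # 0.66
optimism_adjusted_r2 <- function(r2_full, r2_train) {
  stopifnot(length(r2_train) >= 1)
  r2_full - mean(r2_train - r2_full)
}

#' Exhaustive combination validation of one predictor
#'
#' The full small-cohort validation procedure: every `choose(n, k_test)`
#' train/test split is enumerated; an OLS line is fit to each training
#' set and scored by NRMSE on its held-out test points (normalizer: the
#' observed-outcome range over the full cohort); the best-fit line is the
#' one whose test NRMSE is nearest the mean test NRMSE, and its NRMSE
#' over all points is the final NRMSE; the reported r-squared is the
#' full-data r-squared shrunk by the mean training-set optimism. The
#' procedure contains no randomness: repeated runs are identical.
#'
#' @param x Predictor values, one per subject (e.g. the ODI
#'   interhemispheric mean difference).
#' @param y Outcome values (e.g. FM-UE at follow-up). Subjects missing
#'   either value are dropped with a warning; at least 5 complete
#'   subjects are required.
#' @param ids Optional subject identifiers (default `seq_along(x)`).
#' @param k_test Held-out test-set size (default 3).
#' @return Object of class `validation_summary`: `n`, `n_splits`,
#'   `splits` (data frame: `split`, `test_ids`, `slope`, `intercept`,
#'   `r2_train`, `nrmse_test`), `r2_full`, `r2_adjusted`,
#'   `mean_nrmse_test`, `best_split`, `best_line` (slope/intercept),
#'   `final_nrmse`, `normalizer`.
#' @export
#' @examples
#' set.seed(3)
#' d <- runif(9, 0, 0.1)
#' summary9 <- validate_predictor(-d, 60 - 550 * d + rnorm(9, 0, 4))
#' summary9$n_splits
validate_predictor <- function(x, y, ids = NULL, k_test = 3L) {
  stopifnot(length(x) == length(y))
  if (is.null(ids)) ids <- as.character(seq_along(x))
  keep <- complete.cases(x, y)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " subject(s) with missing values: ",
            paste(ids[!keep], collapse = ", "))
    x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  }
  n <- length(x)
  if (n < 5) stop("need at least 5 subjects with complete data, have ", n)
  normalizer <- diff(range(y))
  if (normalizer <= 0) stop("outcome is constant over the cohort")

  splits <- enumerate_splits(n, k_test)
  per_split <- lapply(seq_along(splits), function(j) {
    s <- splits[[j]]
    fit <- fit_line(x[s$train], y[s$train])
    pred <- fit$intercept + fit$slope * x[s$test]
    data.frame(split = j,
               test_ids = paste(ids[s$test], collapse = ";"),
               slope = fit$slope, intercept = fit$intercept,
               r2_train = fit$r2,
               nrmse_test = nrmse(pred, y[s$test], normalizer),
               stringsAsFactors = FALSE)
  })
  per_split <- do.call(rbind, per_split)

  full <- fit_line(x, y)
  best <- select_best_line(per_split$nrmse_test)
  best_line <- per_split[best, c("slope", "intercept")]
  final <- nrmse(best_line$intercept + best_line$slope * x, y, normalizer)

  structure(list(
    n = n, n_splits = nrow(per_split), splits = per_split,
    r2_full = full$r2,
    r2_adjusted = optimism_adjusted_r2(full$r2, per_split$r2_train),
    mean_nrmse_test = mean(per_split$nrmse_test),
    best_split = best,
    best_line = list(slope = best_line$slope,
                     intercept = best_line$intercept),
    final_nrmse = final, normalizer = normalizer
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Combination validation: %d subjects, %d splits\n",
              x$n, x$n_splits))
  cat(sprintf("  r2 full %.3f | optimism-adjusted %.3f\n",
              x$r2_full, x$r2_adjusted))
  cat(sprintf("  mean test NRMSE %.3f | final NRMSE %.3f (best split %d)\n",
              x$mean_nrmse_test, x$final_nrmse, x$best_split))
  invisible(x)
}

#' Validate every predictor x outcome combination of an asymmetry table
#'
#' Runs [validate_predictor()] for each parameter map, for both asymmetry
#' predictors (`delta_mean` and `log_delta_kld`) and both clinical
#' outcomes (FM-UE at follow-up, and change from baseline), reproducing
#' the grid of correlations the asymmetry analysis reports. Only stroke
#' subjects contribute (controls have no FM scores).
#'
#' @param asymmetry Asymmetry table from [roi_asymmetry()].
#' @param subjects Subject table with `subject_id`, `fm_ue_tp2`,
#'   `fm_ue_change`.
#' @param predictors Subset of `c("delta_mean", "log_delta_kld")`.
#' @param outcomes Subset of `c("fm_ue_tp2", "fm_ue_change")`.
#' @param k_test Held-out test-set size (default 3).
#' @return Data frame: `parameter`, `predictor`, `outcome`, `n`,
#'   `n_splits`, `r2_full`, `r2_adjusted`, `mean_nrmse_test`,
#'   `final_nrmse`, `best_slope`, `best_intercept`.
#' @export
validate_outcomes <- function(asymmetry, subjects,
                              predictors = c("delta_mean", "log_delta_kld"),
                              outcomes = c("fm_ue_tp2", "fm_ue_change"),
                              k_test = 3L) {
  predictors <- match.arg(predictors, several.ok = TRUE)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  merged <- merge(asymmetry, subjects, by = "subject_id")
  grid <- expand.grid(parameter = unique(asymmetry$parameter),
                      predictor = predictors, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    d <- merged[merged$parameter == g$parameter, ]
    vs <- suppressWarnings(
      validate_predictor(d[[g$predictor]], d[[g$outcome]],
                         ids = d$subject_id, k_test = k_test))
    data.frame(parameter = g$parameter, predictor = g$predictor,
               outcome = g$outcome, n = vs$n, n_splits = vs$n_splits,
               r2_full = vs$r2_full, r2_adjusted = vs$r2_adjusted,
               mean_nrmse_test = vs$mean_nrmse_test,
               final_nrmse = vs$final_nrmse,
               best_slope = vs$best_line$slope,
               best_intercept = vs$best_line$intercept,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
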