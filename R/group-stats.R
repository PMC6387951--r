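#' Two-tailed Student-t tail probability
#'
#' Converts a t statistic and its degrees of freedom to the two-tailed
#' p-value, `2 * P(T_df > |t|)`, via the t distribution function (which R
#' evaluates through the regularized incomplete beta function).
#'
#' @param t_stat t statistic.
#' @param df Degrees of freedom (> 0; fractional allowed, as produced by
#'   the Welch-Satterthwaite approximation).
#' @return Two-tailed probability.
#' @export
#' @examples
#' t_two_tailed_p(3.59, 8)  # 0.0071 to 4 decimals
t_two_tailed_p <- function(t_stat, df) {
  if (any(df <= 0)) stop("degrees of freedom must be positive")
  2 * pt(abs(t_stat), df, lower.tail = FALSE)
}

#' Paired two-tailed t-test
#'
#' Thin wrapper over [stats::t.test()] for the within-subject hemispheric
#' comparisons (control left vs right; stroke ipsilesional vs
#' contralesional), returning a tidy list. Zero-variance differences have
#' no defined t statistic and raise an error.
#'
#' @param a,b Paired numeric vectors (one value per subject).
#' @return List: `test_kind = "paired"`, `t_stat`, `df`, `p_raw`, `n`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) stop("zero-variance paired differences: t undefined")
  ht <- t.test(a, b, paired = TRUE)
  list(test_kind = "paired", t_stat = unname(ht$statistic),
       df = unname(ht$parameter), p_raw = ht$p.value, n = length(a))
}

#' Welch two-sample heteroscedastic t-test
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE` for the
#' stroke-vs-control comparisons. The Welch-Satterthwaite degrees of
#' freedom are kept fractional.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return List: `test_kind = "welch"`, `t_stat`, `df`, `p_raw`, `n_a`,
#'   `n_b`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    stop("zero variance in both groups: Welch t undefined")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(test_kind = "welch", t_stat = unname(ht$statistic),
       df = unname(ht$parameter), p_raw = ht$p.value,
       n_a = length(a), n_b = length(b))
}

#' Holm step-down multiplicity adjustment
#'
#' Familywise-error control without a preceding global (ANOVA) test:
#' p-values are sorted ascending, the i-th smallest is multiplied by
#' `m - i + 1`, a running maximum enforces monotonicity, results are
#' capped at 1 and returned in the input order. Wraps
#' [stats::p.adjust()].
#'
#' @param p_values Vector of probabilities in `[0, 1]`.
#' @return Adjusted probabilities, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.04 0.04
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "holm")
}

# Per-subject ROI mean for one region/side/parameter, across given subjects.
subject_roi_means <- function(samples, subject_ids, region, side, parameter) {
  vapply(subject_ids, function(id) {
    mean(roi_values(samples, id, region, side, parameter))
  }, numeric(1))
}

#' Deviation-from-control analysis across CST regions
#'
#' For every region x parameter cell, runs the three group comparisons of
#' the deviation analysis on per-subject ROI mean values:
#' \describe{
#'   \item{`control_paired`}{left vs right hemisphere within controls.}
#'   \item{`stroke_paired`}{ipsilesional vs contralesional within stroke
#'     subjects.}
#'   \item{`stroke_vs_control` (Welch)}{stroke ipsilesional means vs one
#'     summary value per control (by default the mean of the control's two
#'     hemispheres, avoiding double counting).}
#' }
#' Holm adjustment is applied within each family, a family being all
#' parameters of one region x test kind; raw and adjusted p-values are
#' reported side by side so either multiplicity reading can be inspected.
#' A cell whose test fails (e.g. zero-variance differences) is reported
#' with `NA` statistics rather than aborting the analysis.
#'
#' @param cohort A `synthetic_cohort` (or any list with `subjects` and
#'   `samples` in the same layout).
#' @param regions Regions to analyse (default all three CST segments).
#' @param control_mode How a control subject is summarised for the Welch
#'   comparison: `"mean"` of both hemispheres (default), or `"left"` /
#'   `"right"` only.
#' @return Data frame: `region`, `parameter`, `test_kind`, `t_stat`,
#'   `df`, `p_raw`, `p_holm`, `family_id`, `n`.
#' @export
region_deviation_analysis <- function(cohort, regions = CST_REGIONS,
                                      control_mode = c("mean", "left",
                                                       "right")) {
  control_mode <- match.arg(control_mode)
  subjects <- cohort$subjects
  samples <- cohort$samples
  stroke_ids <- subjects$subject_id[subjects$group == "stroke"]
  control_ids <- subjects$subject_id[subjects$group == "control"]
  parameters <- unique(samples$parameter)

  one_cell <- function(region, parameter) {
    cells <- list()
    if (length(control_ids) >= 2) {
      # controls: "ipsilesional" is left by convention
      left <- subject_roi_means(samples, control_ids, region,
                                "ipsilesional", parameter)
      right <- subject_roi_means(samples, control_ids, region,
                                 "contralesional", parameter)
      cells$control_paired <- try_test(paired_t, left, right)
    }
    ipsi <- subject_roi_means(samples, stroke_ids, region,
                              "ipsilesional", parameter)
    contra <- subject_roi_means(samples, stroke_ids, region,
                                "contralesional", parameter)
    cells$stroke_paired <- try_test(paired_t, ipsi, contra)
    if (length(control_ids) >= 2) {
      left <- subject_roi_means(samples, control_ids, region,
                                "ipsilesional", parameter)
      right <- subject_roi_means(samples, control_ids, region,
                                 "contralesional", parameter)
      ctrl <- switch(control_mode,
                     mean = (left + right) / 2,
                     left = left,
                     right = right)
      cells$stroke_vs_control <- try_test(welch_t, ipsi, ctrl)
    }
    do.call(rbind, lapply(names(cells), function(kind) {
      r <- cells[[kind]]
      data.frame(region = region, parameter = parameter, test_kind = kind,
                 t_stat = r$t_stat, df = r$df, p_raw = r$p_raw,
                 n = if (!is.null(r$n)) r$n else r$n_a,
                 stringsAsFactors = FALSE)
    }))
  }

  grid <- expand.grid(region = regions, parameter = parameters,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    one_cell(grid$region[i], grid$parameter[i])
  }))
  out$family_id <- paste(out$region, out$test_kind, sep = ":")
  out$p_holm <- NA_real_
  for (fam in unique(out$family_id)) {
    idx <- out$family_id == fam & !is.na(out$p_raw)
    out[idx, "p_holm"] <- holm_adjust(out$p_raw[idx])
  }
  rownames(out) <- NULL
  out[, c("region", "parameter", "test_kind", "t_stat", "df",
          "p_raw", "p_holm", "family_id", "n")]
}

try_test <- function(fn, a, b) {
  tryCatch(fn(a, b), error = function(e) {
    list(t_stat = NA_real_, df = NA_real_, p_raw = NA_real_,
         n = length(a))
  })
}
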