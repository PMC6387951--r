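#' Default microstructural parameter distribution table
#'
#' One row per parameter map the generator emulates. Bounded indices
#' (ODI, FA, GFA, RDI: support `[0, 1]`) use a truncated normal family;
#' diffusivities (MD, AD, RD, in units of 10^-3 mm^2/s so magnitudes stay
#' near 1) use a log-normal family. `mean` and `spread` describe the
#' contralesional (healthy-side) voxel distribution; `shift_sign` gives the
#' direction in which the ipsilesional distribution moves in stroke
#' subjects (+1: ipsilesional higher, as for orientation dispersion under
#' Wallerian degeneration; -1: ipsilesional lower, as for anisotropy
#' indices).
#'
#' @return A data frame with columns `parameter`, `family` (`"tnorm"` or
#'   `"lnorm"`), `mean`, `spread`, `shift_sign`.
#' @export
#' @examples
#' default_parameter_specs()
default_parameter_specs <- function() {
  data.frame(
    parameter  = c("ODI", "FA", "GFA", "RDI", "MD", "AD", "RD"),
    family     = c("tnorm", "tnorm", "tnorm", "tnorm", "lnorm", "lnorm", "lnorm"),
    mean       = c(0.25, 0.60, 0.55, 0.40, 0.80, 1.70, 0.45),
    spread     = c(0.05, 0.08, 0.08, 0.08, 0.10, 0.20, 0.08),
    shift_sign = c(1, -1, -1, 1, -1, -1, 1),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic stroke/control cohort
#'
#' Bundles and validates every knob of the synthetic cohort generator: how
#' many stroke and control subjects, the per-parameter voxel-value
#' distributions, the per-subject ipsilesional shift, and the linear model
#' tying that shift to the follow-up Fugl-Meyer Upper Extremity (FM-UE)
#' score.
#'
#' The effect model: each stroke subject j receives a shift
#' `delta_j ~ Uniform(0, delta_max)`; its ipsilesional voxel distribution
#' for parameter p is the contralesional distribution translated by
#' `shift_sign_p * delta_j`. Follow-up motor score is
#' `fm_ue_tp2 = clamp(round(intercept - slope * delta_j + noise), 0, 66)`,
#' so larger microstructural asymmetry means worse outcome. Controls have
#' identically distributed hemispheres and no FM scores.
#'
#' @param n_stroke,n_control Subject counts (default 9 + 9).
#' @param parameters Parameter distribution table as produced by
#'   [default_parameter_specs()]; any subset or re-parameterisation with
#'   the same columns is accepted.
#' @param voxels_per_roi Voxels drawn per region/side sample (default 500,
#'   which equals the default label-volume region size so disk round trips
#'   are exact).
#' @param delta_max Upper bound of the uniform per-subject ipsilesional
#'   shift, in parameter units (default 0.1).
#' @param outcome List `(intercept, slope, noise_sd)` for the follow-up
#'   FM-UE model, in FM-UE points (slope: points per unit shift).
#' @param baseline List `(intercept, slope, noise_sd)` for the baseline
#'   FM-UE model. Baseline scores are clamped to `[0, 50]` (the study
#'   inclusion criterion); an intercept above 50 triggers a warning.
#' @param grid_shape Integer triple: label-volume extents (default
#'   `c(24, 24, 24)`).
#' @param box_shape Integer triple: extents of each region box (default
#'   `c(10, 10, 5)`, i.e. 500 voxels per region).
#' @param voxel_dims Voxel dimensions in mm (default `c(1.9, 1.9, 2.1)`).
#' @param seed Integer seed; identical configs reproduce cohorts
#'   bit-for-bit.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [generate_label_volume()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 42)
#' cfg$n_stroke
cohort_config <- function(n_stroke = 9,
                          n_control = 9,
                          parameters = default_parameter_specs(),
                          voxels_per_roi = 500,
                          delta_max = 0.1,
                          outcome = list(intercept = 60, slope = 550, noise_sd = 5),
                          baseline = list(intercept = 45, slope = 400, noise_sd = 4),
                          grid_shape = c(24L, 24L, 24L),
                          box_shape = c(10L, 10L, 5L),
                          voxel_dims = c(1.9, 1.9, 2.1),
                          seed = 1L) {
  stopifnot(
    length(n_stroke) == 1, n_stroke >= 1,
    length(n_control) == 1, n_control >= 0,
    is.data.frame(parameters),
    all(c("parameter", "family", "mean", "spread", "shift_sign") %in%
          names(parameters)),
    nrow(parameters) >= 1,
    all(parameters$family %in% c("tnorm", "lnorm")),
    all(parameters$spread > 0),
    all(parameters$mean > 0),
    all(parameters$shift_sign %in% c(-1, 0, 1)),
    voxels_per_roi >= 1,
    delta_max >= 0,
    length(grid_shape) == 3, all(grid_shape >= 1),
    length(box_shape) == 3, all(box_shape >= 1),
    length(voxel_dims) == 3, all(voxel_dims > 0),
    is.numeric(seed), length(seed) == 1
  )
  for (m in list(outcome, baseline)) {
    stopifnot(all(c("intercept", "slope", "noise_sd") %in% names(m)),
              m$noise_sd >= 0)
  }
  if (anyDuplicated(parameters$parameter)) {
    stop("duplicated parameter names in `parameters`")
  }
  bounded <- parameters$family == "tnorm"
  if (any(parameters$mean[bounded] + delta_max >= 1)) {
    stop("a bounded parameter mean plus delta_max reaches 1; ",
         "shrink delta_max or the mean")
  }
  if (baseline$intercept > 50) {
    warning("baseline outcome model can exceed the FM-UE <= 50 inclusion ",
            "criterion; baseline scores will be clamped to 50")
  }
  structure(
    list(n_stroke = as.integer(n_stroke),
         n_control = as.integer(n_control),
         parameters = parameters,
         voxels_per_roi = as.integer(voxels_per_roi),
         delta_max = delta_max,
         outcome = outcome,
         baseline = baseline,
         grid_shape = as.integer(grid_shape),
         box_shape = as.integer(box_shape),
         voxel_dims = as.numeric(voxel_dims),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d stroke + %d control\n", x$n_stroke, x$n_control))
  cat(sprintf("  parameters: %s\n", paste(x$parameters$parameter, collapse = ", ")))
  cat(sprintf("  voxels per ROI: %d; delta_max: %g; seed: %d\n",
              x$voxels_per_roi, x$delta_max, x$seed))
  cat(sprintf("  grid %s, boxes %s, voxel dims %s mm\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$box_shape, collapse = "x"),
              paste(x$voxel_dims, collapse = " x ")))
  invisible(x)
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Set outcome noise to hit a target generating r-squared
#'
#' Returns the config with `outcome$noise_sd` chosen so that the
#' population squared correlation between the injected shift and the
#' follow-up FM-UE score equals `target_r2`: with
#' `delta ~ Uniform(0, delta_max)` the signal standard deviation is
#' `|slope| * delta_max / sqrt(12)`, and
#' `noise_sd = signal_sd * sqrt(1 / target_r2 - 1)`. Score rounding,
#' clamping, and the finite voxel sample attenuate the realised
#' r-squared slightly below the target.
#'
#' @param config A [cohort_config()] with `delta_max > 0`.
#' @param target_r2 Desired generating r-squared in (0, 1].
#' @return The modified config.
#' @export
calibrate_outcome_noise <- function(config, target_r2) {
  stopifnot(inherits(config, "cohort_config"),
            target_r2 > 0, target_r2 <= 1, config$delta_max > 0)
  signal_sd <- abs(config$outcome$slope) * config$delta_max / sqrt(12)
  config$outcome$noise_sd <- signal_sd * sqrt(1 / target_r2 - 1)
  config
}
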