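#' @name cst_regions
#' @title Corticospinal tract region names
#' @description The three CST segments carried by every label volume and
#'   ROI sample, ordered inferior to superior.
#' @export
CST_REGIONS <- c("cerebral_peduncle", "PLIC", "corona_radiata")

# Truncated normal on [0, 1] by inverse-CDF sampling; truncation mass is
# negligible for the default means/spreads but the support guarantee is hard.
r_truncnorm01 <- function(n, mean, sd) {
  plo <- pnorm((0 - mean) / sd)
  phi <- pnorm((1 - mean) / sd)
  u <- runif(n, plo, phi)
  mean + sd * qnorm(u)
}

# Log-normal with a given natural-scale mean and sd.
r_lognormal_mean <- function(n, mean, sd) {
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

draw_roi_values <- function(n, family, mean, sd, shift = 0) {
  switch(family,
    tnorm = r_truncnorm01(n, mean + shift, sd),
    # exact location shift of the healthy-side distribution keeps the
    # generated mean difference equal to the injected shift
    lnorm = r_lognormal_mean(n, mean, sd) + shift,
    stop("unknown distribution family: ", family)
  )
}

#' Generate a synthetic stroke + control cohort
#'
#' Draws the subject table and all per-region voxel samples implied by a
#' [cohort_config()]. Stroke subject j carries a latent ipsilesional shift
#' `delta_j ~ Uniform(0, delta_max)`: for every parameter its ipsilesional
#' sample is drawn from the contralesional distribution translated by
#' `shift_sign * delta_j`, and its follow-up FM-UE score is a noisy linear
#' function of `delta_j` (clamped to the 0-66 FM-UE scale and rounded).
#' Controls have identically distributed hemispheres; their "ipsilesional"
#' side is left by convention so downstream code treats both groups
#' uniformly, and their FM scores are `NA` (controls are not assessed).
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{subjects}{data frame: `subject_id`, `group`,
#'       `lesioned_hemisphere`, `fm_ue_baseline`, `fm_ue_tp2`,
#'       `fm_ue_change`, `days_to_baseline_scan`, `days_to_followup`, and
#'       the latent `delta` (generator truth, kept for validation).}
#'     \item{samples}{data frame with one row per subject x region x side
#'       x parameter: `subject_id`, `region`, `side`
#'       (ipsilesional/contralesional), `hemisphere` (left/right),
#'       `parameter`, and a list column `values` of voxel vectors.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(voxels_per_roi = 50, seed = 7))
#' table(cohort$subjects$group)
#' head(cohort$samples[, c("subject_id", "region", "side", "parameter")])
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    subjects <- generate_subject_table(config)
    samples <- generate_roi_samples(config, subjects)
  })
  structure(list(subjects = subjects, samples = samples, config = config),
            class = "synthetic_cohort")
}

generate_subject_table <- function(config) {
  ns <- config$n_stroke
  nc <- config$n_control
  delta <- runif(ns, 0, config$delta_max)

  om <- config$outcome
  bm <- config$baseline
  tp2 <- clamp(round(om$intercept - om$slope * delta +
                       rnorm(ns, 0, om$noise_sd)), 0, 66)
  base <- clamp(round(bm$intercept - bm$slope * delta +
                        rnorm(ns, 0, bm$noise_sd)), 0, 50)
  days_base <- sample(3:13, ns, replace = TRUE)
  days_fu <- pmax(round(rnorm(ns, 38, 9)), days_base + 7)

  stroke <- data.frame(
    subject_id = sprintf("S%02d", seq_len(ns)),
    group = "stroke",
    lesioned_hemisphere = sample(c("left", "right"), ns, replace = TRUE),
    fm_ue_baseline = base,
    fm_ue_tp2 = tp2,
    days_to_baseline_scan = days_base,
    days_to_followup = days_fu,
    delta = delta,
    stringsAsFactors = FALSE
  )
  control <- data.frame(
    subject_id = sprintf("C%02d", seq_len(nc)),
    group = rep("control", nc),
    lesioned_hemisphere = rep("none", nc),
    fm_ue_baseline = rep(NA_real_, nc),
    fm_ue_tp2 = rep(NA_real_, nc),
    days_to_baseline_scan = rep(NA_integer_, nc),
    days_to_followup = rep(NA_integer_, nc),
    delta = rep(0, nc),
    stringsAsFactors = FALSE
  )
  out <- rbind(stroke, control)
  out$fm_ue_change <- out$fm_ue_tp2 - out$fm_ue_baseline
  out[, c("subject_id", "group", "lesioned_hemisphere", "fm_ue_baseline",
          "fm_ue_tp2", "fm_ue_change", "days_to_baseline_scan",
          "days_to_followup", "delta")]
}

# Control subjects use left as the pseudo-ipsilesional side so every
# downstream operation runs uniformly on both groups.
ipsi_hemisphere <- function(group, lesioned_hemisphere) {
  ifelse(group == "stroke", lesioned_hemisphere, "left")
}

generate_roi_samples <- function(config, subjects) {
  pars <- config$parameters
  nv <- config$voxels_per_roi
  rows <- vector("list",
                 nrow(subjects) * nrow(pars) * length(CST_REGIONS) * 2L)
  k <- 0L
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    is_stroke <- subj$group == "stroke"
    ipsi_hemi <- ipsi_hemisphere(subj$group, subj$lesioned_hemisphere)
    contra_hemi <- setdiff(c("left", "right"), ipsi_hemi)
    for (pi in seq_len(nrow(pars))) {
      p <- pars[pi, ]
      shift <- if (is_stroke) p$shift_sign * subj$delta else 0
      for (region in CST_REGIONS) {
        contra <- draw_roi_values(nv, p$family, p$mean, p$spread, 0)
        ipsi <- draw_roi_values(nv, p$family, p$mean, p$spread, shift)
        for (side in c("contralesional", "ipsilesional")) {
          k <- k + 1L
          rows[[k]] <- list(
            subject_id = subj$subject_id,
            region = region,
            side = side,
            hemisphere = if (side == "ipsilesional") ipsi_hemi else contra_hemi,
            parameter = p$parameter,
            values = if (side == "ipsilesional") ipsi else contra
          )
        }
      }
    }
  }
  out <- data.frame(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    region = vapply(rows, `[[`, "", "region"),
    side = vapply(rows, `[[`, "", "side"),
    hemisphere = vapply(rows, `[[`, "", "hemisphere"),
    parameter = vapply(rows, `[[`, "", "parameter"),
    stringsAsFactors = FALSE
  )
  out$values <- lapply(rows, `[[`, "values")
  out
}

#' Pick one ROI sample vector out of a cohort sample table
#'
#' Convenience accessor used throughout the analysis stages and tests.
#'
#' @param samples Sample table from [generate_cohort()].
#' @param subject_id,region,side,parameter Row selectors.
#' @return Numeric vector of voxel values.
#' @export
roi_values <- function(samples, subject_id, region, side, parameter) {
  i <- which(samples$subject_id == subject_id & samples$region == region &
               samples$side == side & samples$parameter == parameter)
  if (length(i) != 1L) {
    stop(sprintf("no unique sample for %s/%s/%s/%s",
                 subject_id, region, side, parameter))
  }
  samples$values[[i]]
}

#' Generate a synthetic CST label volume
#'
#' Builds an integer-coded 3-D label grid holding six disjoint axis-aligned
#' boxes: the cerebral peduncle, PLIC and corona radiata in each
#' hemisphere. The first array axis is left-right; left and right boxes are
#' mirror images about the midsagittal plane, and the three regions are
#' stacked along the third (inferior-superior) axis.
#'
#' @param config A [cohort_config()]; only `grid_shape`, `box_shape` and
#'   `voxel_dims` are used.
#' @return A list of class `label_volume`: `grid` (integer array),
#'   `code_table` (data frame `region`, `hemisphere`, `code`),
#'   `voxel_dims`.
#' @export
#' @examples
#' labels <- generate_label_volume(cohort_config())
#' table(labels$grid[labels$grid > 0])
generate_label_volume <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$grid_shape
  bs <- config$box_shape
  half <- gs[1] %/% 2L
  gap_z <- (gs[3] - 3L * bs[3]) %/% 4L
  if (bs[1] > half || bs[2] > gs[2] || 3L * bs[3] > gs[3]) {
    stop("grid too small to hold six disjoint region boxes: need ",
         "box x <= floor(grid x / 2), box y <= grid y, 3 * box z <= grid z")
  }
  x_left <- seq_len(bs[1]) + max(0L, (half - bs[1]) %/% 2L)
  x_right <- gs[1] + 1L - rev(x_left)       # mirror about the midplane
  y0 <- max(0L, (gs[2] - bs[2]) %/% 2L)
  y_idx <- seq_len(bs[2]) + y0
  code_table <- data.frame(
    region = rep(CST_REGIONS, each = 2L),
    hemisphere = rep(c("left", "right"), times = 3L),
    code = 1:6,
    stringsAsFactors = FALSE
  )
  grid <- array(0L, dim = gs)
  for (ri in seq_along(CST_REGIONS)) {
    z_idx <- seq_len(bs[3]) + gap_z * ri + bs[3] * (ri - 1L)
    grid[x_left, y_idx, z_idx] <- code_table$code[2L * ri - 1L]
    grid[x_right, y_idx, z_idx] <- code_table$code[2L * ri]
  }
  structure(list(grid = grid, code_table = code_table,
                 voxel_dims = config$voxel_dims),
            class = "label_volume")
}

region_code <- function(labels, region, hemisphere) {
  ct <- labels$code_table
  i <- which(ct$region == region & ct$hemisphere == hemisphere)
  if (length(i) != 1L) {
    stop(sprintf("unknown region/hemisphere: %s/%s", region, hemisphere))
  }
  ct$code[i]
}

#' Generate a lesion mask with an exact region overlap
#'
#' Builds a binary mask covering `floor(overlap_fraction * |region|)`
#' voxels of the target region (taken in ascending linear-index order, so
#' the overlap count is exact by construction), optionally padded with
#' surrounding background voxels that belong to no labelled region and
#' therefore leave every lesion load analytically known.
#'
#' @param labels A `label_volume`.
#' @param region,hemisphere Target region, e.g. `"PLIC"`, `"left"`.
#' @param overlap_fraction Fraction of the target region the lesion covers,
#'   in `[0, 1]`.
#' @param pad Chebyshev radius of background padding around the covered
#'   voxels (default 0: the mask is exactly the covered region voxels).
#' @return A list of class `lesion_mask`: `grid` (0/1 integer array, same
#'   shape as the labels) and `voxel_dims`.
#' @export
#' @examples
#' labels <- generate_label_volume(cohort_config())
#' mask <- generate_lesion_mask(labels, "PLIC", "left", 0.25)
#' sum(mask$grid)
generate_lesion_mask <- function(labels, region, hemisphere,
                                 overlap_fraction, pad = 0L) {
  stopifnot(inherits(labels, "label_volume"),
            overlap_fraction >= 0, overlap_fraction <= 1, pad >= 0)
  code <- region_code(labels, region, hemisphere)
  target <- which(labels$grid == code)
  if (length(target) == 0L) stop("target region is empty")
  n_cover <- floor(overlap_fraction * length(target))
  grid <- array(0L, dim = dim(labels$grid))
  covered <- target[seq_len(n_cover)]
  grid[covered] <- 1L
  if (pad > 0L && n_cover > 0L) {
    idx <- arrayInd(covered, dim(grid))
    lo <- pmax(apply(idx, 2, min) - pad, 1L)
    hi <- pmin(apply(idx, 2, max) + pad, dim(grid))
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    lin <- box[, 1] + dim(grid)[1] * (box[, 2] - 1L) +
      prod(dim(grid)[1:2]) * (box[, 3] - 1L)
    halo <- lin[labels$grid[lin] == 0L]   # never spill into labelled tissue
    grid[halo] <- 1L
  }
  structure(list(grid = grid, voxel_dims = labels$voxel_dims),
            class = "lesion_mask")
}

#' Generate one lesion mask per stroke subject
#'
#' Seeded helper used by the pipeline: each stroke subject gets an
#' ipsilesional-PLIC lesion whose overlap fraction is drawn uniformly.
#'
#' @param config A [cohort_config()] (its seed, offset by one, drives the
#'   overlap draws).
#' @param labels A `label_volume`.
#' @param subjects Subject table from [generate_cohort()].
#' @param max_fraction Upper bound of the uniform overlap fraction.
#' @return Named list of `lesion_mask` objects, one per stroke subject,
#'   with the drawn fraction attached as attribute `overlap_fraction`.
#' @export
generate_cohort_lesions <- function(config, labels, subjects,
                                    max_fraction = 0.6) {
  stroke <- subjects[subjects$group == "stroke", ]
  fractions <- with_seed(config$seed + 1L,
                         runif(nrow(stroke), 0, max_fraction))
  masks <- lapply(seq_len(nrow(stroke)), function(i) {
    hemi <- stroke$lesioned_hemisphere[i]
    m <- generate_lesion_mask(labels, "PLIC", hemi, fractions[i])
    attr(m, "overlap_fraction") <- fractions[i]
    m
  })
  names(masks) <- stroke$subject_id
  masks
}
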