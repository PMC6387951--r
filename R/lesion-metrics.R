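#' Lesion volume in milliliters
#'
#' Voxel count times voxel volume; voxel dimensions are in mm so the mm^3
#' total is divided by 1000 to give mL (cm^3).
#'
#' @param mask A `lesion_mask` (binary grid + `voxel_dims`).
#' @return Volume in mL.
#' @export
#' @examples
#' labels <- generate_label_volume(cohort_config())
#' lesion_volume(generate_lesion_mask(labels, "PLIC", "left", 1))
lesion_volume <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  check_binary(mask$grid)
  sum(mask$grid) * prod(mask$voxel_dims) / 1000
}

check_binary <- function(grid) {
  if (!all(grid %in% c(0L, 1L))) stop("lesion mask must be binary")
  invisible(grid)
}

#' Lesion load of one region
#'
#' Percent of a labelled region's voxels overlapped by the lesion mask:
#' `100 * |mask intersect region| / |region|`. Mask and labels must share
#' a grid; no resampling is attempted.
#'
#' @param mask A `lesion_mask`.
#' @param labels A `label_volume` on the same grid.
#' @param region,hemisphere Target region.
#' @return Percent overlap in `[0, 100]`.
#' @export
lesion_load <- function(mask, labels, region, hemisphere) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(labels, "label_volume"))
  if (!identical(dim(mask$grid), dim(labels$grid))) {
    stop("lesion mask and label volume are on different grids")
  }
  check_binary(mask$grid)
  code <- region_code(labels, region, hemisphere)
  in_region <- labels$grid == code
  n_region <- sum(in_region)
  if (n_region == 0L) stop("region ", region, "/", hemisphere, " is empty")
  100 * sum(mask$grid[in_region] == 1L) / n_region
}

#' Lesion load of the whole corticospinal tract
#'
#' Percent overlap computed over the union of the three CST region labels
#' in one hemisphere (cerebral peduncle, PLIC, corona radiata).
#'
#' @inheritParams lesion_load
#' @param hemisphere Which hemisphere's CST (normally the lesioned one).
#' @return Percent overlap in `[0, 100]`.
#' @export
cst_lesion_load <- function(mask, labels, hemisphere) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(labels, "label_volume"))
  if (!identical(dim(mask$grid), dim(labels$grid))) {
    stop("lesion mask and label volume are on different grids")
  }
  codes <- vapply(CST_REGIONS, region_code, integer(1),
                  labels = labels, hemisphere = hemisphere)
  in_cst <- labels$grid %in% codes
  if (!any(in_cst)) stop("CST labels are empty for hemisphere ", hemisphere)
  100 * sum(mask$grid[in_cst] == 1L) / sum(in_cst)
}

#' Pearson correlation with two-tailed p-value
#'
#' Wraps [stats::cor.test()] (Pearson; p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom).
#' Besides r and r^2 the signed `r * |r|` is reported, since a signed
#' "r-squared" convention appears in some clinical reporting.
#'
#' @param x,y Numeric vectors, length >= 3, neither constant.
#' @param x_name,y_name Labels carried into the result.
#' @return List of class `correlation_result`: `x_name`, `y_name`, `r`,
#'   `r_squared`, `signed_r_squared`, `p_two_tailed`, `n`.
#' @export
#' @examples
#' correlate(1:9, c(2, 1, 4, 3, 6, 5, 8, 7, 9))
correlate <- function(x, y, x_name = deparse(substitute(x)),
                      y_name = deparse(substitute(y))) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("constant input: correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  structure(list(x_name = x_name, y_name = y_name, r = r,
                 r_squared = r^2, signed_r_squared = sign(r) * r^2,
                 p_two_tailed = ht$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s vs %s: r = %.3f (r^2 = %.3f), p = %.4f, n = %d\n",
              x$x_name, x$y_name, x$r, x$r_squared, x$p_two_tailed, x$n))
  invisible(x)
}

#' Per-subject lesion statistics
#'
#' Lesion volume, per-region CST lesion loads, and the whole-CST load for
#' each stroke subject's mask. Loads are measured against the subject's
#' ipsilesional (lesioned-hemisphere) labels.
#'
#' @param masks Named list of `lesion_mask` objects keyed by subject id
#'   (e.g. from [generate_cohort_lesions()]).
#' @param labels A `label_volume`.
#' @param subjects Subject table (for each subject's lesioned hemisphere).
#' @return Data frame: `subject_id`, `lesion_volume_ml`,
#'   `load_cerebral_peduncle`, `load_PLIC`, `load_corona_radiata`,
#'   `load_cst`.
#' @export
lesion_statistics <- function(masks, labels, subjects) {
  rows <- lapply(names(masks), function(id) {
    hemi <- subjects$lesioned_hemisphere[subjects$subject_id == id]
    if (length(hemi) != 1 || hemi == "none") {
      stop("subject ", id, " has no lesioned hemisphere")
    }
    loads <- vapply(CST_REGIONS, function(r) {
      lesion_load(masks[[id]], labels, r, hemi)
    }, numeric(1))
    data.frame(subject_id = id,
               lesion_volume_ml = lesion_volume(masks[[id]]),
               load_cerebral_peduncle = loads[["cerebral_peduncle"]],
               load_PLIC = loads[["PLIC"]],
               load_corona_radiata = loads[["corona_radiata"]],
               load_cst = cst_lesion_load(masks[[id]], labels, hemi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate lesion metrics with Fugl-Meyer outcomes
#'
#' Pearson correlations of lesion volume and each lesion-load metric with
#' baseline FM-UE, follow-up FM-UE, and change in FM-UE.
#'
#' @param lesion_stats Output of [lesion_statistics()].
#' @param subjects Subject table.
#' @return Data frame: `metric`, `outcome`, `r`, `r_squared`,
#'   `signed_r_squared`, `p_two_tailed`, `n` (one row per pair; pairs
#'   whose correlation is undefined, e.g. a constant metric, are reported
#'   with `NA`).
#' @export
lesion_outcome_correlations <- function(lesion_stats, subjects) {
  d <- merge(lesion_stats, subjects, by = "subject_id")
  metrics <- c("lesion_volume_ml", "load_cerebral_peduncle", "load_PLIC",
               "load_corona_radiata", "load_cst")
  outcomes <- c("fm_ue_baseline", "fm_ue_tp2", "fm_ue_change")
  grid <- expand.grid(metric = metrics, outcome = outcomes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    res <- tryCatch(correlate(d[[g$metric]], d[[g$outcome]],
                              g$metric, g$outcome),
                    error = function(e) NULL)
    data.frame(metric = g$metric, outcome = g$outcome,
               r = if (is.null(res)) NA_real_ else res$r,
               r_squared = if (is.null(res)) NA_real_ else res$r_squared,
               signed_r_squared = if (is.null(res)) NA_real_ else
                 res$signed_r_squared,
               p_two_tailed = if (is.null(res)) NA_real_ else
                 res$p_two_tailed,
               n = if (is.null(res)) sum(complete.cases(
                 d[[g$metric]], d[[g$outcome]])) else res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
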