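#' Write a 3-D volume as NIfTI-1
#'
#' @param grid 3-D numeric or integer array.
#' @param voxel_dims Voxel dimensions in mm.
#' @param path Output path (`.nii`; the pipeline writes uncompressed NIfTI
#'   so repeated runs are byte-identical).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(grid, voxel_dims, path) {
  img <- RNifti::asNifti(grid)
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI file.
#' @return List: `grid` (plain array), `voxel_dims` (mm).
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(grid = array(as.vector(img), dim = dim(img)),
       voxel_dims = RNifti::pixdim(img)[1:3])
}

#' Extract the ROI sample of one region from a parameter map
#'
#' Values of the map at voxels whose label equals the region code, in
#' ascending linear (column-major) voxel-index order — the same
#' deterministic order the synthetic writer uses, so write + extract round
#' trips are exact. Non-finite voxels are dropped; the number dropped is
#' attached as attribute `n_dropped`.
#'
#' @param map 3-D numeric array (parameter map).
#' @param labels A `label_volume` on the same grid.
#' @param region,hemisphere Target region.
#' @return Numeric vector of voxel values (attribute `n_dropped`).
#' @export
extract_roi_sample <- function(map, labels, region, hemisphere) {
  stopifnot(inherits(labels, "label_volume"))
  if (!identical(dim(map), dim(labels$grid))) {
    stop("parameter map and label volume are on different grids")
  }
  code <- region_code(labels, region, hemisphere)
  values <- map[labels$grid == code]
  if (length(values) == 0L) {
    stop("region ", region, "/", hemisphere, " is empty in the label volume")
  }
  ok <- is.finite(values)
  out <- values[ok]
  if (length(out) == 0L) stop("region ", region, "/", hemisphere,
                              " contains only non-finite voxels")
  attr(out, "n_dropped") <- sum(!ok)
  out
}

# Paint one subject's ROI samples into a full 3-D parameter map.
# Region voxels are filled in ascending linear-index order with the first
# |region| values of the sample (samples at least as long as the region).
build_parameter_map <- function(samples, labels, subject_id, parameter) {
  map <- array(0, dim = dim(labels$grid))
  rows <- which(samples$subject_id == subject_id &
                  samples$parameter == parameter)
  for (i in rows) {
    code <- region_code(labels, samples$region[i], samples$hemisphere[i])
    idx <- which(labels$grid == code)
    v <- samples$values[[i]]
    if (length(v) < length(idx)) {
      stop(sprintf("sample %s/%s/%s has %d values but region holds %d voxels",
                   subject_id, samples$region[i], parameter,
                   length(v), length(idx)))
    }
    map[idx] <- v[seq_along(idx)]
  }
  map
}

subject_table_columns <- c("subject_id", "group", "lesioned_hemisphere",
                           "fm_ue_baseline", "fm_ue_tp2", "fm_ue_change",
                           "days_to_baseline_scan", "days_to_followup")

#' Write a synthetic cohort to disk
#'
#' Serialises everything the analysis consumes: the subject table (CSV),
#' the label volume plus its region-code table, one NIfTI parameter map
#' per subject x parameter, one NIfTI lesion mask per stroke subject, and
#' the generating configuration (JSON). All volumes share the affine
#' implied by the configured voxel dimensions.
#'
#' @param cohort A `synthetic_cohort`.
#' @param labels A `label_volume`.
#' @param masks Named list of `lesion_mask` objects (may be empty).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, labels, masks, dir) {
  dir.create(file.path(dir, "maps"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "lesions"), showWarnings = FALSE)

  write.csv(cohort$subjects[, subject_table_columns],
            file.path(dir, "subjects.csv"), row.names = FALSE)
  write_nifti_volume(labels$grid, labels$voxel_dims,
                     file.path(dir, "labels.nii"))
  write.csv(labels$code_table, file.path(dir, "label_codes.csv"),
            row.names = FALSE)
  for (id in unique(cohort$samples$subject_id)) {
    for (p in unique(cohort$samples$parameter)) {
      map <- build_parameter_map(cohort$samples, labels, id, p)
      write_nifti_volume(map, labels$voxel_dims,
                         file.path(dir, "maps", sprintf("%s_%s.nii", id, p)))
    }
  }
  for (id in names(masks)) {
    write_nifti_volume(masks[[id]]$grid, masks[[id]]$voxel_dims,
                       file.path(dir, "lesions", sprintf("%s.nii", id)))
  }
  cfg <- cohort$config
  cfg$parameters <- as.list(cfg$parameters)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory back into analysis structures
#'
#' Counterpart of [write_cohort()]: loads the subject table, label volume
#' and code table, per-subject parameter maps and lesion masks, and
#' re-extracts the per-region ROI samples from the maps. A missing map for
#' any subject/parameter aborts with a message naming the subject and the
#' stage. Volumes whose voxel dimensions disagree with the label volume's
#' are rejected (no silent resampling).
#'
#' @param dir Directory written by [write_cohort()].
#' @return List: `subjects`, `labels` (`label_volume`), `samples` (same
#'   layout as [generate_cohort()]'s), `masks` (named list of
#'   `lesion_mask`).
#' @export
read_cohort_dir <- function(dir) {
  subjects <- read.csv(file.path(dir, "subjects.csv"),
                       stringsAsFactors = FALSE)
  code_table <- read.csv(file.path(dir, "label_codes.csv"),
                         stringsAsFactors = FALSE)
  lab <- read_nifti_volume(file.path(dir, "labels.nii"))
  labels <- structure(list(grid = array(as.integer(round(lab$grid)),
                                        dim = dim(lab$grid)),
                           code_table = code_table,
                           voxel_dims = lab$voxel_dims),
                      class = "label_volume")

  map_files <- list.files(file.path(dir, "maps"), pattern = "\\.nii$")
  parameters <- unique(sub("^[^_]+_(.+)\\.nii$", "\\1", map_files))

  rows <- list()
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    ipsi_hemi <- ipsi_hemisphere(subj$group, subj$lesioned_hemisphere)
    contra_hemi <- setdiff(c("left", "right"), ipsi_hemi)
    for (p in parameters) {
      path <- file.path(dir, "maps", sprintf("%s_%s.nii", subj$subject_id, p))
      if (!file.exists(path)) {
        stop("[extract] missing parameter map for subject ",
             subj$subject_id, ", parameter ", p, ": ", path)
      }
      vol <- read_nifti_volume(path)
      if (!isTRUE(all.equal(vol$voxel_dims, labels$voxel_dims,
                            tolerance = 1e-5))) {
        stop("[extract] voxel dimensions of ", path,
             " disagree with the label volume")
      }
      for (region in CST_REGIONS) {
        for (side in c("contralesional", "ipsilesional")) {
          hemi <- if (side == "ipsilesional") ipsi_hemi else contra_hemi
          rows[[length(rows) + 1L]] <- list(
            subject_id = subj$subject_id, region = region, side = side,
            hemisphere = hemi, parameter = p,
            values = as.numeric(
              extract_roi_sample(vol$grid, labels, region, hemi))
          )
        }
      }
    }
  }
  samples <- data.frame(
    subject_id = vapply(rows, `[[`, "", "subject_id"),
    region = vapply(rows, `[[`, "", "region"),
    side = vapply(rows, `[[`, "", "side"),
    hemisphere = vapply(rows, `[[`, "", "hemisphere"),
    parameter = vapply(rows, `[[`, "", "parameter"),
    stringsAsFactors = FALSE
  )
  samples$values <- lapply(rows, `[[`, "values")

  lesion_files <- list.files(file.path(dir, "lesions"), pattern = "\\.nii$")
  masks <- lapply(lesion_files, function(f) {
    vol <- read_nifti_volume(file.path(dir, "lesions", f))
    structure(list(grid = array(as.integer(round(vol$grid)),
                                dim = dim(vol$grid)),
                   voxel_dims = vol$voxel_dims),
              class = "lesion_mask")
  })
  names(masks) <- sub("\\.nii$", "", lesion_files)

  list(subjects = subjects, labels = labels, samples = samples,
       masks = masks)
}
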