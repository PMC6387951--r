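# Small, fast cohort configurations used across test files.

# Two parameters covering both distribution families.
small_parameters <- function() {
  specs <- default_parameter_specs()
  specs[specs$parameter %in% c("ODI", "MD"), ]
}

small_config <- function(seed = 1L, ...) {
  args <- list(parameters = small_parameters(), voxels_per_roi = 60L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

# Hand-built two-region label volume for geometric edge cases:
# code 1 occupies 8 voxels, code 2 a disjoint 8, code 9 appears nowhere.
tiny_labels <- function() {
  grid <- array(0L, dim = c(6L, 4L, 4L))
  grid[1:2, 1:2, 1:2] <- 1L
  grid[5:6, 1:2, 1:2] <- 2L
  structure(list(
    grid = grid,
    code_table = data.frame(
      region = c("PLIC", "PLIC", "corona_radiata"),
      hemisphere = c("left", "right", "left"),
      code = c(1L, 2L, 9L),
      stringsAsFactors = FALSE
    ),
    voxel_dims = c(1, 1, 1)
  ), class = "label_volume")
}

make_mask <- function(labels, idx) {
  grid <- array(0L, dim = dim(labels$grid))
  grid[idx] <- 1L
  structure(list(grid = grid, voxel_dims = labels$voxel_dims),
            class = "lesion_mask")
}
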