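test_that("cohort has the configured composition", {
  cohort <- generate_cohort(small_config(seed = 1))
  expect_equal(nrow(cohort$subjects), 18)
  expect_equal(sum(cohort$subjects$lesioned_hemisphere != "none"), 9)
  expect_equal(sum(cohort$subjects$group == "stroke"), 9)
  s <- cohort$subjects[cohort$subjects$group == "stroke", ]
  expect_true(all(s$fm_ue_baseline >= 0 & s$fm_ue_baseline <= 50))
  expect_true(all(s$fm_ue_tp2 >= 0 & s$fm_ue_tp2 <= 66))
  expect_true(all(s$fm_ue_tp2 == round(s$fm_ue_tp2)))
  expect_true(all(s$days_to_baseline_scan > 2 & s$days_to_baseline_scan < 14))
  # 2 parameters x 3 regions x 2 sides x 18 subjects
  expect_equal(nrow(cohort$samples), 2 * 3 * 2 * 18)
  expect_true(all(lengths(cohort$samples$values) == 60))
  odi <- unlist(cohort$samples$values[cohort$samples$parameter == "ODI"])
  expect_true(all(odi >= 0 & odi <= 1))
  md <- unlist(cohort$samples$values[cohort$samples$parameter == "MD"])
  expect_true(all(md > 0))
})

test_that("identical configs reproduce cohorts bit-for-bit", {
  a <- generate_cohort(small_config(seed = 7))
  b <- generate_cohort(small_config(seed = 7))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$samples$values, b$samples$values)
  c <- generate_cohort(small_config(seed = 8))
  expect_false(identical(a$samples$values[[1]], c$samples$values[[1]]))
})

test_that("zero effect and zero noise give flat outcomes and no asymmetry", {
  cfg <- small_config(seed = 2, delta_max = 0,
                      outcome = list(intercept = 60.4, slope = 550,
                                     noise_sd = 0))
  cohort <- generate_cohort(cfg)
  s <- cohort$subjects[cohort$subjects$group == "stroke", ]
  expect_true(all(s$fm_ue_tp2 == 60))
  asym <- roi_asymmetry(cohort$samples)
  # Monte-Carlo error of a mean difference at 60 voxels/side
  tol <- 3 * sqrt(2) * max(small_parameters()$spread) / sqrt(60)
  expect_true(all(abs(asym$delta_mean) < tol))
})

test_that("the injected shift is recovered from each stroke subject", {
  cfg <- small_config(seed = 3, voxels_per_roi = 2000L)
  cohort <- generate_cohort(cfg)
  asym <- roi_asymmetry(cohort$samples)
  merged <- merge(asym, cohort$subjects[, c("subject_id", "group", "delta")])
  specs <- small_parameters()
  for (i in seq_len(nrow(specs))) {
    p <- specs[i, ]
    rows <- merged[merged$parameter == p$parameter & merged$group == "stroke", ]
    # ipsi = contra + sign * delta, so delta_mean = -sign * delta
    expected <- -p$shift_sign * rows$delta
    tol <- 3 * sqrt(2) * p$spread / sqrt(2000)
    expect_true(all(abs(rows$delta_mean - expected) < tol),
                label = paste("shift recovery for", p$parameter))
  }
})

test_that("control hemispheres are symmetric on average across seeds", {
  deltas <- unlist(lapply(1:25, function(s) {
    cohort <- generate_cohort(small_config(seed = 100 + s))
    asym <- roi_asymmetry(cohort$samples)
    asym$delta_mean[grepl("^C", asym$subject_id) & asym$parameter == "ODI"]
  }))
  se <- sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas)), 3 * se)
})

test_that("with no noise the latent shift determines the outcome exactly", {
  cfg <- small_config(seed = 4,
                      outcome = list(intercept = 60, slope = 550,
                                     noise_sd = 0))
  s <- generate_cohort(cfg)$subjects
  s <- s[s$group == "stroke", ]
  expect_lt(cor(s$delta, s$fm_ue_tp2), -0.999)  # rounding only
})

test_that("a baseline model violating the inclusion criterion warns", {
  expect_warning(
    small_config(baseline = list(intercept = 58, slope = 400, noise_sd = 4)),
    "clamped")
})

test_that("label volume geometry is exact and mirror-symmetric", {
  cfg <- small_config(grid_shape = c(20L, 20L, 20L),
                      box_shape = c(4L, 4L, 4L))
  labels <- generate_label_volume(cfg)
  counts <- table(labels$grid[labels$grid > 0])
  expect_setequal(as.integer(names(counts)), 1:6)
  expect_true(all(counts == 64))
  region_sizes <- NULL
  for (h in c("left", "right")) {
    code <- labels$code_table$code[labels$code_table$region == "PLIC" &
                                     labels$code_table$hemisphere == h]
    region_sizes <- c(region_sizes, sum(labels$grid == code))
  }
  expect_equal(region_sizes[1], region_sizes[2])
  # mirror symmetry about the midsagittal plane (first axis)
  flipped <- labels$grid[dim(labels$grid)[1]:1, , ]
  left_codes <- labels$code_table$code[labels$code_table$hemisphere == "left"]
  right_codes <- labels$code_table$code[labels$code_table$hemisphere == "right"]
  for (i in 1:3) {
    expect_identical(flipped == left_codes[i], labels$grid == right_codes[i])
  }
  expect_error(
    generate_label_volume(small_config(grid_shape = c(6L, 6L, 6L),
                                       box_shape = c(4L, 4L, 4L))),
    "too small")
})

test_that("lesion masks cover an exact fraction of the target region", {
  labels <- generate_label_volume(small_config(grid_shape = c(20L, 20L, 20L),
                                               box_shape = c(4L, 4L, 4L)))
  code <- labels$code_table$code[
    labels$code_table$region == "PLIC" & labels$code_table$hemisphere == "left"]
  for (f in c(0, 0.25, 1)) {
    mask <- generate_lesion_mask(labels, "PLIC", "left", f)
    overlap <- sum(mask$grid == 1L & labels$grid == code)
    expect_equal(overlap, floor(f * 64))
  }
  expect_error(generate_lesion_mask(labels, "PLIC", "none", 0.5), "unknown")
  # padding adds only background voxels: loads stay exact
  padded <- generate_lesion_mask(labels, "PLIC", "left", 0.5, pad = 1L)
  plain <- generate_lesion_mask(labels, "PLIC", "left", 0.5)
  expect_gt(sum(padded$grid), sum(plain$grid))
  expect_equal(sum(padded$grid == 1L & labels$grid == code),
               sum(plain$grid == 1L & labels$grid == code))
  expect_true(all(labels$grid[padded$grid != plain$grid] == 0L))
})
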