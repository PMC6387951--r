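#' Run the full asymmetry analysis end-to-end
#'
#' One call from synthetic cohort to result tables: simulate, write all
#' inputs to disk in standard formats (NIfTI volumes, CSV tables), read
#' them back, extract ROI samples, and run the three analysis stages —
#' PLIC asymmetry statistics, exhaustive combination validation against
#' FM-UE outcomes, group deviation tests with Holm correction — plus the
#' lesion metrics. The disk round trip is part of the contract: analysis
#' consumes what was re-read, not the in-memory cohort, so the I/O path is
#' exercised on every run. All randomness comes from `config$seed`;
#' rerunning with an identical config writes byte-identical tables and
#' manifest.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory. Inputs go to `out_dir/input/`, result
#'   tables and the JSON manifest to `out_dir/`.
#' @param n_bins Histogram bins for the KLD statistic (default 10).
#' @param symmetrized Use the symmetrized KLD (default `FALSE`).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list: `asymmetry`, `validation`, `group_stats`,
#'   `lesion_stats`, `lesion_correlations`, `manifest` (also written as
#'   CSV/JSON under `out_dir`).
#' @export
#' @examples
#' \donttest{
#' cfg <- cohort_config(parameters = default_parameter_specs()[1:2, ],
#'                      seed = 11)
#' res <- run_pipeline(cfg, tempfile("plicasym"), quiet = TRUE)
#' res$validation[, c("parameter", "predictor", "outcome", "r2_adjusted")]
#' }
run_pipeline <- function(config, out_dir, n_bins = 10L,
                         symmetrized = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_dir <- file.path(out_dir, "input")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  say("[simulate] generating cohort (seed ", config$seed, ")")
  cohort <- stage("simulate", generate_cohort(config))
  labels <- stage("simulate", generate_label_volume(config))
  masks <- stage("simulate",
                 generate_cohort_lesions(config, labels, cohort$subjects))
  say("[simulate] ", nrow(cohort$subjects), " subjects, ",
      nrow(cohort$samples), " ROI samples")

  say("[write] serialising inputs to ", input_dir)
  stage("write", write_cohort(cohort, labels, masks, input_dir))

  say("[extract] reading volumes back and extracting ROI samples")
  data <- stage("extract", read_cohort_dir(input_dir))

  say("[asymmetry] PLIC asymmetry statistics (", n_bins, " bins)")
  asym <- stage("asymmetry",
                roi_asymmetry(data$samples, region = "PLIC",
                              n_bins = n_bins, symmetrized = symmetrized))

  say("[validate] exhaustive 6-train/3-test combination validation")
  validation <- stage("validate", validate_outcomes(asym, data$subjects))

  say("[groupstats] deviation-from-control t-tests with Holm adjustment")
  gstats <- stage("groupstats", region_deviation_analysis(data))

  say("[lesion] lesion volume, CST lesion load, outcome correlations")
  lstats <- stage("lesion",
                  lesion_statistics(data$masks, data$labels, data$subjects))
  lcorr <- stage("lesion",
                 lesion_outcome_correlations(lstats, data$subjects))

  write.csv(asym, file.path(out_dir, "asymmetry.csv"), row.names = FALSE)
  write.csv(validation, file.path(out_dir, "validation.csv"),
            row.names = FALSE)
  write.csv(gstats, file.path(out_dir, "group_stats.csv"),
            row.names = FALSE)
  write.csv(lstats, file.path(out_dir, "lesion_stats.csv"),
            row.names = FALSE)
  write.csv(lcorr, file.path(out_dir, "lesion_correlations.csv"),
            row.names = FALSE)

  manifest <- pipeline_manifest(config, out_dir, input_dir, data)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] results under ", out_dir)

  invisible(list(asymmetry = asym, validation = validation,
                 group_stats = gstats, lesion_stats = lstats,
                 lesion_correlations = lcorr, manifest = manifest))
}

# No timestamps: reruns with identical inputs must be byte-identical.
pipeline_manifest <- function(config, out_dir, input_dir, data) {
  files <- c(
    list.files(input_dir, recursive = TRUE, full.names = TRUE),
    list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  )
  md5 <- tools::md5sum(sort(files))
  cfg <- config
  cfg$parameters <- as.list(cfg$parameters)
  list(
    package = "plicasym",
    version = as.character(packageVersion("plicasym")),
    seed = config$seed,
    config = unclass(cfg),
    n_subjects = nrow(data$subjects),
    n_stroke = sum(data$subjects$group == "stroke"),
    n_roi_samples = nrow(data$samples),
    n_lesion_masks = length(data$masks),
    files = lapply(seq_along(md5), function(i) {
      list(path = sub(paste0("^", out_dir, "/?"), "", names(md5)[i]),
           md5 = unname(md5[i]))
    })
  )
}
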