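#' Run the full synthetic study end-to-end
#'
#' Orchestrates every stage on generated data with a single configuration:
#' (1) simulate hemisphere records with the configured association and a
#' two-dipole evoked dataset; (2) preprocess the epochs (artifact rejection,
#' averaging, 20 Hz zero-phase low-pass, baseline correction, peak finding);
#' (3) fit two dipoles by variational Bayes at the peak topography;
#' (4) build synthetic volumes and extract grey-matter-masked ROI means;
#' (5) compute the 3 x 6 correlation table, the summed statistic and its
#' permutation test; (6) run the spatial-extent comparison per map and the
#' 18-model family comparison. Each stage appends a provenance record
#' (parameters + input hash); when `output_dir` is given, the resolved
#' configuration and all tabular results are written next to each other.
#'
#' @param cfg A [sim_config()].
#' @param output_dir Optional directory for the results bundle (created if
#'   missing). `NULL` keeps everything in memory.
#' @param stages Character subset of
#'   `c("simulate", "preprocess", "fit_dipoles", "roi_extract", "stats",
#'   "model_compare")` to run (later stages re-use provided `records`).
#' @param records Pre-computed records tibble (used when the simulate stage
#'   is skipped).
#' @param n_perm Permutations for the summed-statistic test.
#' @param n_restarts Restarts for the dipole fit.
#' @return A `pipeline_result` list with per-stage outputs and `provenance`.
#' @export
run_pipeline <- function(cfg = sim_config(), output_dir = NULL,
                         stages = c("simulate", "preprocess", "fit_dipoles",
                                    "roi_extract", "stats", "model_compare"),
                         records = NULL, n_perm = 5000, n_restarts = 3) {
  stages <- match.arg(stages, several.ok = TRUE)
  prov <- list()
  note <- function(stage, params, input = NULL) {
    prov[[stage]] <<- list(stage = stage, params = params,
                           input_hash = if (!is.null(input)) rlang::hash(input),
                           time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                           version = as.character(utils::packageVersion("megmyelin")))
  }
  res <- list(config = cfg)

  if ("simulate" %in% stages) {
    sim <- simulate_hemisphere_records(cfg)
    records <- sim$records
    res$records <- records
    res$records_truth <- sim$truth
    note("simulate", list(seed = cfg$seed, n = cfg$n_hemispheres,
                          rho = cfg$association_rho), records)
  }

  if (any(c("preprocess", "fit_dipoles") %in% stages)) {
    array <- make_sensor_array(cfg$n_channels, cfg$helmet_radius_mm)
    conductor <- conductor_model(radius_mm = cfg$conductor_radius_mm)
    truth <- make_auditory_truth(cfg)
    epochs <- simulate_evoked_epochs(truth, array, cfg, conductor)
    res$evoked_truth <- truth

    kept <- reject_artifacts(epochs, 5e-12)
    evoked <- kept |> average_epochs() |> lowpass(20) |> baseline_correct()
    peak <- find_peak_latency(evoked)
    res$evoked <- evoked
    res$peak <- peak
    note("preprocess", list(threshold_T = 5e-12, lowpass_hz = 20,
                            baseline_ms = 100,
                            rejection_fraction = attr(kept, "rejection_fraction")),
         evoked$data)

    if ("fit_dipoles" %in% stages) {
      topo <- evoked$data[, peak$index]
      fit <- fit_vb_ecd(topo, array, conductor, dipole_prior(),
                        n_restarts = n_restarts, seed = cfg$seed)
      res$dipole_fit <- fit
      res$moment_magnitudes_nAm <- vapply(
        seq_len(nrow(fit$locations_mm)),
        function(i) moment_magnitude(fit, i), numeric(1))
      note("fit_dipoles", list(n_restarts = n_restarts,
                               location_sd_mm = 10, moment_sd_nAm = 100),
           topo)
    }
  }

  if ("roi_extract" %in% stages) {
    vols <- make_synthetic_volumes(cfg)
    res$volumes <- vols
    res$roi_means <- extract_roi_means(vols$maps, vols$rois, vols$gm_prob,
                                       fwhm_mm = 3)
    note("roi_extract", list(fwhm_mm = 3, gm_threshold = 0.2,
                             wm_threshold = 0.8), res$roi_means)
  }

  if (any(c("stats", "model_compare") %in% stages)) {
    if (is.null(records)) stop_config("stats stages need records")
  }

  if ("stats" %in% stages) {
    res$correlation_table <- correlation_table(records)
    res$summed_r <- summed_r(res$correlation_table)
    res$permutation <- permutation_test(records, n_perm = n_perm,
                                        seed = cfg$seed)
    res$rm_anova <- rm_anova_roi(records)
    note("stats", list(n_perm = n_perm, seed = cfg$seed), records)
  }

  if ("model_compare" %in% stages) {
    res$extent_comparison <- purrr::map_dfr(map_types(), function(mt) {
      dplyr::mutate(spatial_extent_comparison(records, mt), map = mt,
                    .before = 1)
    })
    res$evidences <- model_evidence_set(records)
    res$families <- family_comparison(res$evidences)
    note("model_compare", list(prior_map = 1 / 3, prior_roi = 1 / 6), records)
  }

  res$provenance <- prov
  class(res) <- "pipeline_result"

  if (!is.null(output_dir)) write_pipeline_bundle(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:", paste(names(x$provenance), collapse = ", "),
      "\n")
  if (!is.null(x$summed_r)) {
    cat("  summed r =", signif(x$summed_r, 4),
        " permutation p =", signif(x$permutation$p_one_tailed, 3), "\n")
  }
  if (!is.null(x$families)) {
    best_roi <- x$families$roi_families |>
      dplyr::slice_max(.data$posterior, n = 1)
    best_map <- x$families$map_families |>
      dplyr::slice_max(.data$posterior, n = 1)
    cat("  top ROI family:", best_roi$roi,
        sprintf("(%.4f)", best_roi$posterior),
        "; top map family:", best_map$map,
        sprintf("(%.4f)", best_map$posterior), "\n")
  }
  invisible(x)
}

write_pipeline_bundle <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  pj <- function(...) file.path(output_dir, ...)
  cfg <- res$config
  jsonlite::write_json(unclass(cfg), pj("config.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(res$provenance, pj("provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$records)) write_records_csv(res$records, pj("records.csv"))
  if (!is.null(res$correlation_table)) {
    write.csv(res$correlation_table, pj("correlation_table.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(summed_r = res$summed_r,
           p_one_tailed = res$permutation$p_one_tailed,
           n_perm = res$permutation$n_perm,
           seed = res$permutation$seed),
      pj("permutation.json"), auto_unbox = TRUE, digits = NA)
    write.csv(tibble(null_sum = res$permutation$null_samples),
              pj("null_samples.csv"), row.names = FALSE)
  }
  if (!is.null(res$extent_comparison)) {
    write.csv(res$extent_comparison, pj("extent_comparison.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$families)) {
    write.csv(res$families$roi_families, pj("roi_families.csv"),
              row.names = FALSE)
    write.csv(res$families$map_families, pj("map_families.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$dipole_fit)) {
    jsonlite::write_json(
      list(locations_mm = res$dipole_fit$locations_mm,
           moments_nAm = res$dipole_fit$moments_nAm,
           moment_magnitudes_nAm = res$moment_magnitudes_nAm,
           free_energy = res$dipole_fit$free_energy,
           variance_explained = res$dipole_fit$variance_explained),
      pj("dipole_fit.json"), digits = NA)
  }
  if (!is.null(res$volumes)) {
    write_map_nifti(res$volumes$maps$R1, pj("R1.nii.gz"))
    write_map_nifti(res$volumes$gm_prob, pj("gm_prob.nii.gz"))
  }
  if (!is.null(res$roi_means)) {
    write.csv(res$roi_means, pj("roi_means.csv"), row.names = FALSE)
  }
  invisible(output_dir)
}
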