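#' Simulation configuration for the synthetic study
#'
#' Collects every tunable of the synthetic-data generator in one validated
#' object. The defaults reproduce the conditions of the auditory MEG / myelin
#' study the package emulates: ten hemispheres, dipole moments spanning
#' 3.01--71.34 nAm, grey-matter map means of 0.8521 p.u. (MT saturation),
#' 0.628 1/s (R1) and 19.0 1/s (R2*), 3.5 s epochs from -0.75 s to 2.75 s
#' around stimulus onset sampled at 600 Hz, a noise-to-pitch transition at
#' 0.8 s, and a pitch-onset response peaking ~150 ms after the transition.
#'
#' @param seed Integer seed fixing all downstream randomness.
#' @param n_hemispheres Number of hemisphere records (>= 4).
#' @param association_rho Target monotone (Spearman) association between
#'   dipole moments and myelin estimates, in \[-1, 1\].
#' @param snr_db Evoked-field signal-to-noise ratio in dB, defined on the
#'   trial average at the peak sample (mean-square signal over channels vs.
#'   per-channel noise variance of the average). `Inf` disables noise.
#' @param n_trials Number of epochs per simulated subject.
#' @param n_channels Number of MEG channels.
#' @param grid_shape Integer 3-vector of voxels for synthetic volumes
#'   (each >= 32).
#' @param voxel_size_mm Isotropic voxel size of the synthetic volumes.
#' @param map_means Named grey-matter means for the three quantitative maps
#'   (`MT` p.u., `R1` 1/s, `R2star` 1/s).
#' @param wm_means Named white-matter means for the same maps.
#' @param moment_range_nAm Length-2 range the simulated dipole-moment
#'   magnitudes are drawn from.
#' @param sfreq_hz Sampling rate of simulated epochs.
#' @param epoch_window_s Epoch start/end relative to stimulus onset.
#' @param transition_s Time of the noise-to-pitch transition within the epoch
#'   (relative to stimulus onset).
#' @param peak_latency_s Latency of the simulated response peak after the
#'   transition.
#' @param bump_sd_s Temporal standard deviation of the Gaussian activation.
#' @param helmet_radius_mm Sensor helmet radius.
#' @param conductor_radius_mm Radius of the spherical conductor.
#' @param max_voxels Hard cap on `prod(grid_shape)`; exceeding it is an error.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, n_hemispheres = 10, association_rho = 0.8)
#' cfg$moment_range_nAm
sim_config <- function(seed = 1L,
                       n_hemispheres = 10L,
                       association_rho = 0.6,
                       snr_db = 10,
                       n_trials = 250L,
                       n_channels = 275L,
                       grid_shape = c(48L, 48L, 48L),
                       voxel_size_mm = 1.5,
                       map_means = c(MT = 0.8521, R1 = 0.628, R2star = 19.0),
                       wm_means = c(MT = 1.6855, R1 = 0.944, R2star = 20.0),
                       moment_range_nAm = c(3.01, 71.34),
                       sfreq_hz = 600,
                       epoch_window_s = c(-0.75, 2.75),
                       transition_s = 0.8,
                       peak_latency_s = 0.15,
                       bump_sd_s = 0.04,
                       helmet_radius_mm = 120,
                       conductor_radius_mm = 90,
                       max_voxels = 2^24) {
  check_scalar(seed, "seed")
  check_scalar(n_hemispheres, "n_hemispheres")
  if (n_hemispheres < 4) stop_config("n_hemispheres must be >= 4")
  check_scalar(association_rho, "association_rho")
  if (abs(association_rho) > 1) stop_config("association_rho must lie in [-1, 1]")
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop_config("snr_db must be a single number (possibly Inf)")
  }
  check_scalar(n_trials, "n_trials")
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L || any(grid_shape < 1)) {
    stop_config("grid_shape must be 3 positive integers")
  }
  check_scalar(voxel_size_mm, "voxel_size_mm")
  required_maps <- c("MT", "R1", "R2star")
  if (!all(required_maps %in% names(map_means)) ||
      !all(required_maps %in% names(wm_means))) {
    stop_config("map_means and wm_means must name MT, R1 and R2star")
  }
  if (length(moment_range_nAm) != 2L || diff(moment_range_nAm) <= 0 ||
      any(moment_range_nAm < 0)) {
    stop_config("moment_range_nAm must be an increasing non-negative pair")
  }
  check_scalar(sfreq_hz, "sfreq_hz")
  if (sfreq_hz <= 0) stop_config("sfreq_hz must be positive")
  if (helmet_radius_mm <= conductor_radius_mm) {
    stop_config("helmet_radius_mm must exceed conductor_radius_mm")
  }

  structure(list(
    seed = as.integer(seed),
    n_hemispheres = as.integer(n_hemispheres),
    association_rho = association_rho,
    snr_db = snr_db,
    n_trials = as.integer(n_trials),
    n_channels = as.integer(n_channels),
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm,
    map_means = map_means[required_maps],
    wm_means = wm_means[required_maps],
    moment_range_nAm = as.numeric(moment_range_nAm),
    sfreq_hz = sfreq_hz,
    epoch_window_s = as.numeric(epoch_window_s),
    transition_s = transition_s,
    peak_latency_s = peak_latency_s,
    bump_sd_s = bump_sd_s,
    helmet_radius_mm = helmet_radius_mm,
    conductor_radius_mm = conductor_radius_mm,
    max_voxels = max_voxels
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " hemispheres:", x$n_hemispheres,
      " rho:", x$association_rho, "\n")
  cat("  channels:", x$n_channels, " trials:", x$n_trials,
      " snr_db:", x$snr_db, "\n")
  cat("  grid:", paste(x$grid_shape, collapse = "x"),
      "@", x$voxel_size_mm, "mm\n")
  invisible(x)
}

#' Canonical map and ROI label sets
#'
#' The three quantitative map types and six auditory regions of interest the
#' analysis operates over: auditory koniocortex subdivisions TE1.0 / TE1.1 /
#' TE1.2, secondary auditory cortex TE3, and the two 5 mm spherical ROIs
#' centred on the dipole location priors (`Patt`) and on the mean posterior
#' locations (`Post`).
#'
#' @return Character vectors of labels.
#' @export
map_types <- function() c("MT", "R1", "R2star")

#' @rdname map_types
#' @export
roi_labels <- function() c("TE1.0", "TE1.1", "TE1.2", "TE3", "Patt", "Post")
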