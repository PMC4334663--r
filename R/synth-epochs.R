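#' Ground truth container for simulated datasets
#'
#' Every generated dataset ships with the parameters that produced it, so
#' parameter-recovery tests never rely on hidden state.
#'
#' @param dipole_locations_mm n_dipoles x 3 matrix of source locations (mm).
#' @param dipole_moments_nAm n_dipoles x 3 matrix of moment vectors (nAm).
#' @param roi_myelin Optional tibble of per-(hemisphere, map, ROI) myelin.
#' @param extra Optional named list of further truth values.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(dipole_locations_mm = NULL, dipole_moments_nAm = NULL,
                         roi_myelin = NULL, extra = list()) {
  if (!is.null(dipole_locations_mm)) {
    dipole_locations_mm <- rbind(dipole_locations_mm)
    dipole_moments_nAm <- rbind(dipole_moments_nAm)
    stopifnot(nrow(dipole_locations_mm) == nrow(dipole_moments_nAm))
  }
  structure(list(dipole_locations_mm = dipole_locations_mm,
                 dipole_moments_nAm = dipole_moments_nAm,
                 roi_myelin = roi_myelin, extra = extra),
            class = "ground_truth")
}

#' Epoched sensor data
#'
#' @param data trials x channels x samples array (tesla).
#' @param sfreq_hz Sampling rate.
#' @param t0_s Epoch start relative to stimulus onset (s).
#' @param transition_s Noise-to-pitch transition time within the epoch,
#'   relative to stimulus onset (s).
#' @param retained Logical per original trial (bookkeeping after rejection).
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, sfreq_hz, t0_s, transition_s,
                      retained = rep(TRUE, dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L)
  if (sfreq_hz <= 0) stop_config("sfreq_hz must be positive")
  structure(list(data = data, sfreq_hz = sfreq_hz, t0_s = t0_s,
                 transition_s = transition_s, retained = retained),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$sfreq_hz, " Hz (t0 = ", x$t0_s, " s)\n", sep = "")
  invisible(x)
}

epoch_times <- function(x) x$t0_s + (seq_len(dim(x$data)[3]) - 1) / x$sfreq_hz

#' Simulate evoked epochs from known dipoles
#'
#' Generates `cfg$n_trials` epochs of channel-by-time data. The signal is the
#' forward field of the ground-truth dipoles modulated by a smooth Gaussian
#' activation peaking `cfg$peak_latency_s` after the noise-to-pitch
#' transition; i.i.d. Gaussian sensor noise is added per trial, scaled so
#' that the trial average attains `cfg$snr_db` at the peak sample
#' (mean-square signal across channels over per-channel noise variance of
#' the average).
#'
#' @param truth A [ground_truth()] with dipole locations and moments.
#' @param array A [make_sensor_array()] result.
#' @param cfg A [sim_config()].
#' @param conductor Optional [conductor_model()]; defaults to a sphere of
#'   `cfg$conductor_radius_mm` at the origin.
#' @return An [epoch_set()] with attribute `"noiseless"` holding the
#'   channels x samples noise-free evoked signal, and `"noise_sd"` the
#'   per-trial noise standard deviation used.
#' @export
simulate_evoked_epochs <- function(truth, array, cfg, conductor = NULL) {
  conductor <- conductor %||% conductor_model(radius_mm = cfg$conductor_radius_mm)
  nloc <- nrow(truth$dipole_locations_mm)
  for (i in seq_len(nloc)) {
    check_source_geometry(truth$dipole_locations_mm[i, ], conductor, array)
  }
  times <- seq(cfg$epoch_window_s[1], cfg$epoch_window_s[2], by = 1 / cfg$sfreq_hz)
  n_samp <- length(times)
  n_ch <- nrow(array$positions)

  t_peak <- cfg$transition_s + cfg$peak_latency_s
  activation <- exp(-((times - t_peak)^2) / (2 * cfg$bump_sd_s^2))

  topo <- rep(0, n_ch)
  for (i in seq_len(nloc)) {
    topo <- topo + dipole_field(truth$dipole_locations_mm[i, ],
                                truth$dipole_moments_nAm[i, ],
                                conductor, array)
  }
  signal <- outer(topo, activation) # channels x samples

  peak_ms <- mean(signal[, which.max(activation)]^2)
  if (is.infinite(cfg$snr_db)) {
    noise_sd_avg <- 0
  } else {
    noise_sd_avg <- sqrt(peak_ms / 10^(cfg$snr_db / 10))
  }
  noise_sd_trial <- noise_sd_avg * sqrt(cfg$n_trials)

  data <- with_seed_(derive_seed(cfg$seed, 11L), {
    arr <- array(0, dim = c(cfg$n_trials, n_ch, n_samp))
    for (tr in seq_len(cfg$n_trials)) {
      noise <- if (noise_sd_trial > 0) {
        matrix(rnorm(n_ch * n_samp, sd = noise_sd_trial), n_ch, n_samp)
      } else 0
      arr[tr, , ] <- signal + noise
    }
    arr
  })

  out <- epoch_set(data, cfg$sfreq_hz, cfg$epoch_window_s[1], cfg$transition_s)
  attr(out, "noiseless") <- signal
  attr(out, "noise_sd") <- noise_sd_trial
  out
}

#' Default two-dipole ground truth at auditory-cortex-like locations
#'
#' Tangential dipoles near the bilateral auditory location priors used by the
#' dipole fitter, with magnitudes drawn from the configured moment range.
#' Moment orientations are tangential (orthogonal to the source radius), so
#' the sources are visible to MEG.
#'
#' @param cfg A [sim_config()].
#' @param locations_mm Optional 2 x 3 matrix overriding the default bilateral
#'   locations.
#' @param seed Seed for the magnitude draw (defaults to `cfg$seed`).
#' @return A [ground_truth()].
#' @export
make_auditory_truth <- function(cfg, locations_mm = NULL, seed = NULL) {
  locations_mm <- locations_mm %||% rbind(c(-55.3, -12.9, 1.5),
                                          c(57.2, -8.8, -1.3))
  seed <- seed %||% cfg$seed
  moments <- with_seed_(derive_seed(seed, 7L), {
    mags <- runif(nrow(locations_mm), cfg$moment_range_nAm[1],
                  cfg$moment_range_nAm[2])
    t(vapply(seq_len(nrow(locations_mm)), function(i) {
      r <- locations_mm[i, ] / vnorm(locations_mm[i, ])
      # deterministic tangential direction: z-axis component removed from a
      # helper vector least aligned with r
      h <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      tang <- h - sum(h * r) * r
      tang <- tang / vnorm(tang)
      tang * mags[i]
    }, numeric(3)))
  })
  ground_truth(locations_mm, moments)
}
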