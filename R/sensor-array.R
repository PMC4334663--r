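#' Construct a quasi-uniform MEG sensor array on a spherical cap
#'
#' Places `n_channels` sensors on the upper cap of a helmet sphere using a
#' Fibonacci lattice (deterministic, quasi-uniform in area), with radial unit
#' orientations. Sensors can be read out as magnetometers or as axial
#' gradiometers (two-point difference along the radial axis with a fixed
#' baseline, CTF-like).
#'
#' @param n_channels Number of channels (>= 16).
#' @param helmet_radius_mm Helmet radius in mm (all sensors at this radius).
#' @param cap_angle_deg Half-opening angle of the covered cap, measured from
#'   the +z pole. The default 120 degrees covers somewhat more than a
#'   hemisphere, as whole-head helmets do.
#' @param type `"magnetometer"` or `"axial_gradiometer"`.
#' @param baseline_mm Gradiometer baseline (distance between the two coils
#'   along the radial orientation).
#'
#' @return A `sensor_array` object: list with `positions` (n x 3 mm),
#'   `orientations` (n x 3 unit vectors), `type`, `baseline_mm`,
#'   `helmet_radius_mm`.
#' @export
#' @examples
#' arr <- make_sensor_array(275, 120)
#' nrow(arr$positions)
make_sensor_array <- function(n_channels, helmet_radius_mm,
                              cap_angle_deg = 120,
                              type = c("magnetometer", "axial_gradiometer"),
                              baseline_mm = 50) {
  check_scalar(n_channels, "n_channels")
  if (n_channels < 16) stop_config("n_channels must be >= 16")
  check_scalar(helmet_radius_mm, "helmet_radius_mm")
  if (helmet_radius_mm <= 0) stop_config("helmet_radius_mm must be positive")
  type <- match.arg(type)

  n <- as.integer(n_channels)
  # Fibonacci cap: z descends from just below the pole to cos(cap angle),
  # azimuth advances by the golden angle.
  z_hi <- 1
  z_lo <- cos(cap_angle_deg * pi / 180)
  i <- seq_len(n)
  z <- z_hi - (i - 0.5) / n * (z_hi - z_lo)
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  s <- sqrt(pmax(0, 1 - z^2))
  pos <- helmet_radius_mm * cbind(s * cos(phi), s * sin(phi), z)
  ori <- pos / helmet_radius_mm

  structure(list(
    positions = pos,
    orientations = ori,
    type = type,
    baseline_mm = baseline_mm,
    helmet_radius_mm = helmet_radius_mm,
    cap_angle_deg = cap_angle_deg
  ), class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", nrow(x$positions), " ", x$type,
      " channels, helmet radius ", x$helmet_radius_mm, " mm\n", sep = "")
  invisible(x)
}

#' @export
tidy.sensor_array <- function(x, ...) {
  tibble(
    channel = seq_len(nrow(x$positions)),
    x_mm = x$positions[, 1], y_mm = x$positions[, 2], z_mm = x$positions[, 3],
    ox = x$orientations[, 1], oy = x$orientations[, 2], oz = x$orientations[, 3]
  )
}
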