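#' Generate synthetic quantitative volumes, tissue probabilities and an atlas
#'
#' Builds a simple head-like geometry on a common RAS affine centred at the
#' world origin: a white-matter core sphere surrounded by a cortical-ribbon
#' grey-matter shell. Quantitative maps take the configured grey-matter means
#' inside the ribbon and white-matter means in the core; six disjoint
#' labelled ROIs sit on the ribbon. Mild multiplicative voxel noise (0.5%)
#' makes the volumes non-degenerate while keeping ROI means within
#' tolerance of the configured values.
#'
#' @param cfg A [sim_config()]; `grid_shape` must be at least 32 per axis and
#'   `prod(grid_shape)` at most `cfg$max_voxels`.
#' @param noise_frac Multiplicative voxel noise fraction (0 disables).
#' @return A list: `maps` (named list of [quantitative_map()]s for MT, R1,
#'   R2star), `gm_prob`, `wm_prob`, `atlas` (labels 1..6 with a `labels`
#'   attribute naming them), `rois` (list of atlas [roi_definition()]s),
#'   `affine`, and `truth` (per-ROI noise-free map values).
#' @export
make_synthetic_volumes <- function(cfg, noise_frac = 0.005) {
  if (any(cfg$grid_shape < 32L)) stop_config("grid_shape must be >= 32 per axis")
  if (prod(cfg$grid_shape) > cfg$max_voxels) {
    stop_config("voxel budget exceeded: ", prod(cfg$grid_shape), " > ",
                cfg$max_voxels)
  }
  d <- cfg$grid_shape
  vs <- cfg$voxel_size_mm
  # RAS affine, origin at the grid centre
  affine <- diag(c(vs, vs, vs, 1))
  affine[1:3, 4] <- -vs * (d - 1) / 2

  xyz <- voxel_world_coords(d, affine)
  r <- sqrt(rowSums(xyz^2))
  half_extent <- min(d) * vs / 2
  wm_r <- 0.58 * half_extent
  gm_r <- 0.80 * half_extent

  in_wm <- r <= wm_r
  in_gm <- r > wm_r & r <= gm_r

  gm_prob <- array(0.02, d); gm_prob[in_gm] <- 0.9; gm_prob[in_wm] <- 0.05
  wm_prob <- array(0.01, d); wm_prob[in_wm] <- 0.95; wm_prob[in_gm] <- 0.08

  csf_means <- c(MT = 0.05, R1 = 0.25, R2star = 1.0)
  maps_noise <- with_seed_(derive_seed(cfg$seed, 31L), {
    lapply(map_types(), function(mt) {
      v <- array(csf_means[[mt]], d)
      v[in_gm] <- cfg$map_means[[mt]]
      v[in_wm] <- cfg$wm_means[[mt]]
      if (noise_frac > 0) v <- v * (1 + array(rnorm(prod(d), sd = noise_frac), d))
      quantitative_map(abs(v), affine, mt)
    })
  })
  names(maps_noise) <- map_types()

  # six disjoint ROI patches on the ribbon: 5 mm spheres at mid-ribbon radius
  roi_r <- (wm_r + gm_r) / 2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(sqrt(0.5), sqrt(0.5), 0), c(0, 0, 1))
  labels <- roi_labels()
  atlas_vals <- array(0L, d)
  centres <- dirs * roi_r
  for (k in seq_len(6)) {
    d2 <- (xyz[, 1] - centres[k, 1])^2 + (xyz[, 2] - centres[k, 2])^2 +
      (xyz[, 3] - centres[k, 3])^2
    atlas_vals[array(d2 <= 25, d)] <- k # 5 mm radius
  }
  atlas <- quantitative_map(atlas_vals, affine, "atlas")
  attr(atlas, "labels") <- setNames(seq_len(6), labels)
  rois <- lapply(seq_len(6), function(k) {
    roi_definition(labels[k], atlas = atlas, atlas_label = k)
  })

  truth <- tibble(
    map = rep(map_types(), each = 2),
    tissue = rep(c("GM", "WM"), times = 3),
    value = as.numeric(rbind(cfg$map_means, cfg$wm_means))
  )

  list(
    maps = maps_noise,
    gm_prob = quantitative_map(gm_prob, affine, "GM_prob"),
    wm_prob = quantitative_map(wm_prob, affine, "WM_prob"),
    atlas = atlas,
    rois = rois,
    roi_centres_mm = centres,
    affine = affine,
    truth = ground_truth(extra = list(tissue_means = truth,
                                      wm_radius_mm = wm_r,
                                      gm_radius_mm = gm_r))
  )
}

#' Simulate a multi-echo gradient-echo decay signal
#'
#' Mono-exponential decay `s0 * exp(-R2* * TE)` sampled on an echo grid
#' (default: 8 equidistant echoes from 2.39 to 18.91 ms) with additive
#' Gaussian noise.
#'
#' @param s0 Signal amplitude at TE = 0.
#' @param r2star_per_s Apparent transverse relaxation rate (1/s, >= 0).
#' @param echo_times_s Echo times in seconds, strictly increasing.
#' @param noise_sd Additive Gaussian noise standard deviation (0 = none).
#' @param seed Seed for the noise draw.
#' @return Numeric vector of signal intensities, one per echo.
#' @export
#' @examples
#' make_multiecho_signal(100, 19, noise_sd = 0)
make_multiecho_signal <- function(s0, r2star_per_s,
                                  echo_times_s = default_echo_times(),
                                  noise_sd = 0, seed = 1L) {
  check_scalar(s0, "s0")
  check_scalar(r2star_per_s, "r2star_per_s")
  if (r2star_per_s < 0) stop_config("r2star_per_s must be >= 0")
  te <- as.numeric(echo_times_s)
  if (any(te <= 0) || any(diff(te) <= 0)) {
    stop_input("echo times must be positive and strictly increasing")
  }
  s <- s0 * exp(-r2star_per_s * te)
  if (noise_sd > 0) {
    s <- s + with_seed_(seed, rnorm(length(te), sd = noise_sd))
  }
  s
}
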