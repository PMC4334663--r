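#' Simulate hemisphere records with a controlled myelin--moment association
#'
#' Generates `cfg$n_hemispheres` hemisphere records, each holding a dipole
#' moment magnitude (drawn within `cfg$moment_range_nAm`) and myelin
#' estimates for every (map, ROI) pair plus a whole-hemisphere `global`
#' value. The monotone association between moments and myelin is induced by
#' a Gaussian-copula latent factor: a standard-normal hemisphere factor is
#' shared between the moment and the myelin values with latent (Pearson)
#' correlation `2*sin(pi*rho/6)`, so the population Spearman correlation of
#' every linked cell equals `cfg$association_rho`.
#'
#' Per-ROI baselines follow the myeloarchitecture ordering seen in auditory
#' cortex for MT and R1 (koniocortical core TE1.1, TE1.0 above transitional
#' TE1.2 above secondary TE3).
#'
#' @param cfg A [sim_config()]; `association_rho` sets the target Spearman
#'   correlation.
#' @param plant Either `NULL` (all cells share the latent factor), or a
#'   character vector of cells `"map:roi"` (e.g. `"R1:TE1.2"`, `"MT:global"`)
#'   that alone carry the association while all other cells are independent
#'   noise.
#' @param cell_noise_sd Standard deviation of independent per-cell jitter,
#'   as a fraction of the cell's association amplitude. 0 (default) gives the
#'   pure latent-factor construction (`rho = 1` then yields Spearman r = 1
#'   exactly in every linked cell).
#' @return A list with `records` (long tibble: `hemisphere_id`,
#'   `moment_nAm`, `map`, `roi`, `myelin`) and `truth` (a [ground_truth()]
#'   whose `roi_myelin` stores the noise-free cell values and whose `extra`
#'   records the latent factors).
#' @export
#' @examples
#' sim <- simulate_hemisphere_records(sim_config(seed = 1, association_rho = 0.9))
#' dplyr::glimpse(sim$records)
simulate_hemisphere_records <- function(cfg, plant = NULL, cell_noise_sd = 0) {
  n <- cfg$n_hemispheres
  rho <- cfg$association_rho
  rho_latent <- 2 * sin(pi * rho / 6)

  maps <- map_types()
  rois <- c(roi_labels(), "global")
  cells <- tidyr::expand_grid(map = maps, roi = rois)

  if (!is.null(plant)) {
    cell_keys <- paste(cells$map, cells$roi, sep = ":")
    if (!all(plant %in% cell_keys)) {
      stop_config("unknown plant cell(s): ",
                  paste(setdiff(plant, cell_keys), collapse = ", "))
    }
  }

  # ROI baseline offsets (fraction of the map's GM mean) and association
  # amplitudes. MT/R1 follow the cortical myeloarchitecture ordering
  # TE1.1, TE1.0 > TE1.2 > TE3; R2* is flatter, iron-dominated.
  offsets <- c("TE1.0" = 0.09, "TE1.1" = 0.10, "TE1.2" = 0.03,
               "TE3" = -0.03, "Patt" = 0.02, "Post" = 0.06, "global" = 0)
  offsets_r2 <- c("TE1.0" = 0.02, "TE1.1" = 0.03, "TE1.2" = 0.01,
                  "TE3" = -0.01, "Patt" = 0.02, "Post" = 0.03, "global" = 0)
  # per-ROI association amplitude (fraction of the map mean); varying it
  # across ROIs keeps between-ROI contrasts non-degenerate
  amp_frac <- 0.05 * c("TE1.0" = 1.0, "TE1.1" = 0.9, "TE1.2" = 1.25,
                       "TE3" = 0.8, "Patt" = 1.1, "Post" = 0.95,
                       "global" = 0.7)

  out <- with_seed_(derive_seed(cfg$seed, 23L), {
    z <- rnorm(n) # shared hemisphere factor
    e <- rnorm(n)
    b <- rho_latent * z + sqrt(max(0, 1 - rho_latent^2)) * e
    u_moment <- pnorm(z)
    moments <- cfg$moment_range_nAm[1] +
      u_moment * diff(cfg$moment_range_nAm)

    u_link <- pnorm(b)
    recs <- purrr::pmap_dfr(cells, function(map, roi) {
      base <- cfg$map_means[[map]]
      off <- if (map == "R2star") offsets_r2[[roi]] else offsets[[roi]]
      amp <- amp_frac[[roi]] * base
      key <- paste(map, roi, sep = ":")
      linked <- is.null(plant) || key %in% plant
      u_cell <- if (linked) u_link else runif(n)
      myel <- base * (1 + off) + amp * (u_cell - 0.5)
      if (cell_noise_sd > 0) myel <- myel + rnorm(n, sd = cell_noise_sd * amp)
      tibble(hemisphere_id = sprintf("H%02d", seq_len(n)),
             moment_nAm = moments, map = map, roi = roi, myelin = myel)
    })
    list(recs = recs, z = z, b = b, moments = moments)
  })

  truth <- ground_truth(
    roi_myelin = out$recs,
    extra = list(latent_moment = out$z, latent_myelin = out$b,
                 moments_nAm = out$moments, association_rho = rho,
                 plant = plant)
  )
  list(records = out$recs, truth = truth)
}

#' Read and write hemisphere-record tables
#'
#' The on-disk interchange format is a wide CSV with columns
#' `hemisphere_id`, `moment_nAm`, then one column per `map_roi` pair
#' (e.g. `R1_TE1.2`). In memory the package uses the long (tidy) form.
#'
#' @param records Long-format records tibble.
#' @param path File path.
#' @return `read_records_csv()` returns the long tibble;
#'   `write_records_csv()` returns `path` invisibly.
#' @export
write_records_csv <- function(records, path) {
  wide <- records |>
    dplyr::mutate(key = paste(.data$map, .data$roi, sep = "_")) |>
    dplyr::select("hemisphere_id", "moment_nAm", "key", "myelin") |>
    tidyr::pivot_wider(names_from = "key", values_from = "myelin")
  write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  wide <- as_tibble(read.csv(path, check.names = FALSE))
  long <- wide |>
    tidyr::pivot_longer(-c("hemisphere_id", "moment_nAm"),
                        names_to = "key", values_to = "myelin") |>
    tidyr::separate_wider_delim("key", "_", names = c("map", "roi"),
                                too_many = "merge")
  long
}
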