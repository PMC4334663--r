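test_that("spearman handles monotone, reversed and tied data", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearman(c(1, 2, 3), c(30, 20, 10)), -1)
  x <- c(1, 1, 2, 3); y <- c(2, 1, 4, 4)
  expect_equal(spearman(x, y), spearman_midrank_oracle(x, y))
  for (s in 1:20) {
    withr::with_seed(s, {
      a <- sample(1:6, 8, replace = TRUE)
      b <- sample(1:6, 8, replace = TRUE)
    })
    if (var(rank(a)) > 0 && var(rank(b)) > 0) {
      expect_equal(spearman(a, b), spearman_midrank_oracle(a, b))
    }
  }
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman(1:2, 1:2), class = "megmyelin_input_error")
})

test_that("correlation tables span the full maps x ROIs grid", {
  sim <- simulate_hemisphere_records(sim_config(seed = 1))
  tab <- correlation_table(sim$records)
  expect_equal(nrow(tab), 18)
  expect_equal(sort(unique(tab$map)), sort(map_types()))
  expect_equal(sort(unique(tab$roi)), sort(roi_labels()))
  expect_true(all(abs(tab$r) <= 1))
  expect_equal(attr(tab, "n"), 10)
})

test_that("summed statistic: perfect association gives the cell count, null gives ~0", {
  sim <- simulate_hemisphere_records(sim_config(seed = 2, association_rho = 1))
  expect_equal(summed_r(correlation_table(sim$records)), 18)

  cfg0 <- sim_config(seed = 3, association_rho = 0, n_hemispheres = 200)
  sim0 <- simulate_hemisphere_records(cfg0, plant = character(0))
  expect_lt(abs(summed_r(correlation_table(sim0$records))), 18 * 0.25)
})

test_that("the reported reference table sums to the published statistic", {
  ref <- reference_correlation_table()
  expect_equal(nrow(ref), 18)
  expect_equal(summed_r(ref), 7.5637, tolerance = 1e-10)
})

test_that("summed statistic is invariant under monotone transforms (rank basis)", {
  sim <- simulate_hemisphere_records(sim_config(seed = 4, association_rho = 0.7))
  base <- summed_r(correlation_table(sim$records))
  warped <- dplyr::mutate(sim$records,
                          moment_nAm = exp(.data$moment_nAm / 20),
                          myelin = .data$myelin^3)
  expect_equal(summed_r(correlation_table(warped)), base, tolerance = 1e-12)
})

test_that("permutation p honours the add-one rule and fixed-seed reproducibility", {
  sim <- simulate_hemisphere_records(sim_config(seed = 5, association_rho = 0.9))
  pt <- permutation_test(sim$records, n_perm = 500, seed = 11)
  expect_gte(pt$p_one_tailed, 1 / 501)
  expect_equal(length(pt$null_samples), 500)
  pt2 <- permutation_test(sim$records, n_perm = 500, seed = 11)
  expect_identical(pt$null_samples, pt2$null_samples)
  expect_identical(pt$p_one_tailed, pt2$p_one_tailed)
})

test_that("monte-carlo permutation sums match direct cor() recomputation", {
  sim <- simulate_hemisphere_records(sim_config(seed = 6, association_rho = 0.5,
                                                n_hemispheres = 8))
  recs <- sim$records
  pt <- permutation_test(recs, n_perm = 20, seed = 3)
  # replay the same permutations with a plain cor()-based recomputation
  hemis <- sort(unique(recs$hemisphere_id))
  n <- length(hemis)
  moments <- recs |>
    dplyr::distinct(.data$hemisphere_id, .data$moment_nAm) |>
    dplyr::arrange(.data$hemisphere_id)
  perms <- withr::with_seed(megmyelin:::derive_seed(3, 53L), {
    lapply(1:20, function(i) sample.int(n))
  })
  replay <- vapply(perms, function(p) {
    shuffled <- moments$moment_nAm[p]
    relabeled <- dplyr::mutate(
      recs, moment_nAm = shuffled[match(.data$hemisphere_id, hemis)])
    summed_r(correlation_table(relabeled))
  }, numeric(1))
  expect_equal(pt$null_samples, replay, tolerance = 1e-12)
})

test_that("enumeration at n = 4 equals the brute-force exact null", {
  cfg <- sim_config(seed = 7, n_hemispheres = 4, association_rho = 0.8)
  recs <- simulate_hemisphere_records(cfg)$records
  pt <- permutation_test(recs, enumerate = TRUE)
  expect_equal(pt$n_perm, 24)

  hemis <- sort(unique(recs$hemisphere_id))
  moments <- recs |>
    dplyr::distinct(.data$hemisphere_id, .data$moment_nAm) |>
    dplyr::arrange(.data$hemisphere_id)
  sums <- vapply(perms_oracle(4), function(p) {
    shuffled <- moments$moment_nAm[p]
    relabeled <- dplyr::mutate(
      recs, moment_nAm = shuffled[match(.data$hemisphere_id, hemis)])
    summed_r(correlation_table(relabeled))
  }, numeric(1))
  expect_equal(sort(pt$null_samples), sort(sums), tolerance = 1e-12)
  expect_equal(pt$p_one_tailed,
               mean(sums >= summed_r(correlation_table(recs)) - 1e-12))
})

test_that("the permutation null is centred near zero for independent data", {
  cfg <- sim_config(seed = 8, association_rho = 0, n_hemispheres = 10)
  recs <- simulate_hemisphere_records(cfg, plant = character(0))$records
  pt <- permutation_test(recs, n_perm = 2000, seed = 9)
  se <- sd(pt$null_samples) / sqrt(pt$n_perm)
  expect_lt(abs(mean(pt$null_samples)), 3 * se)
})

test_that("permutation p is super-uniform under the null", {
  hits <- vapply(1:1000, function(s) {
    cfg <- sim_config(seed = 20000 + s, association_rho = 0, n_hemispheres = 10)
    recs <- simulate_hemisphere_records(cfg, plant = character(0))$records
    permutation_test(recs, n_perm = 200, seed = s)$p_one_tailed
  }, numeric(1))
  expect_lte(mean(hits <= 0.05), 0.05 + 0.02)
  expect_lte(mean(hits <= 0.10), 0.10 + 0.02)
})

test_that("rm-anova: degenerate tables give F = 0; two ROIs reduce to paired t", {
  cfg <- sim_config(seed = 10)
  recs <- simulate_hemisphere_records(cfg)$records
  flat <- recs |>
    dplyr::group_by(.data$hemisphere_id, .data$map) |>
    dplyr::mutate(myelin = mean(.data$myelin)) |>
    dplyr::ungroup()
  res <- rm_anova_roi(flat, "R1")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  two <- rm_anova_roi(recs, "R1", rois = c("TE1.0", "TE3"))
  wide <- recs |>
    dplyr::filter(.data$map == "R1", .data$roi %in% c("TE1.0", "TE3")) |>
    tidyr::pivot_wider(names_from = "roi", values_from = "myelin")
  tt <- t.test(wide$`TE1.0`, wide$TE3, paired = TRUE)
  expect_equal(two$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(two$p_value, tt$p.value, tolerance = 1e-10)

  holed <- dplyr::filter(recs, !(.data$map == "R1" & .data$roi == "TE1.0" &
                                   .data$hemisphere_id == "H01"))
  expect_error(rm_anova_roi(holed, "R1"), class = "megmyelin_input_error")
})

test_that("rm-anova type-I error is calibrated near the nominal level", {
  # independent myelin values per cell, ROI baselines removed: no true effect
  hits <- vapply(1:1000, function(s) {
    recs <- simulate_hemisphere_records(
      sim_config(seed = 40000 + s, association_rho = 0),
      plant = character(0))$records
    recs <- recs |>
      dplyr::group_by(.data$map, .data$roi) |>
      dplyr::mutate(myelin = .data$myelin - mean(.data$myelin)) |>
      dplyr::ungroup()
    rm_anova_roi(recs, "MT", alpha = 0.05)$p_value < 0.05
  }, logical(1))
  expect_equal(mean(hits), 0.05, tolerance = 0.02 / 0.05)
})

test_that("post-hoc pairwise tests cover all 15 pairs with Bonferroni flags", {
  recs <- simulate_hemisphere_records(sim_config(seed = 12))$records
  ph <- posthoc_pairwise(recs, "R1")
  expect_equal(nrow(ph), 15)
  expect_true(all(ph$significant == (ph$p_value < 0.05 / 15)))
  # paired-t oracle for one pair
  wide <- recs |>
    dplyr::filter(.data$map == "R1", .data$roi %in% c("TE1.1", "TE3")) |>
    tidyr::pivot_wider(names_from = "roi", values_from = "myelin")
  tt <- t.test(wide$`TE1.1`, wide$TE3, paired = TRUE)
  row <- ph[ph$roi1 == "TE1.1" & ph$roi2 == "TE3", ]
  expect_equal(row$statistic, unname(tt$statistic))
  expect_equal(row$p_value, tt$p.value)
})

test_that("records CSV round-trips through the wide interchange format", {
  sim <- simulate_hemisphere_records(sim_config(seed = 14))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(sim$records, tmp)
  back <- read_records_csv(tmp)
  orig <- dplyr::arrange(sim$records, .data$hemisphere_id, .data$map, .data$roi)
  back <- dplyr::arrange(back, .data$hemisphere_id, .data$map, .data$roi)
  expect_equal(back$myelin, orig$myelin, tolerance = 1e-12)
  expect_equal(back$moment_nAm, orig$moment_nAm, tolerance = 1e-12)
  expect_equal(paste(back$map, back$roi), paste(orig$map, orig$roi))
})
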