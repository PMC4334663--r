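make_glm_fixture <- function(seed, n = 10, beta = c(40, 8), sd = 5) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    y <- beta[1] + beta[2] * x + rnorm(n, sd = sd)
    list(y = y, X = cbind(intercept = 1, myelin = x - mean(x)))
  })
}

test_that("identical models give identical evidence (Bayes factor 1)", {
  fx <- make_glm_fixture(1)
  f1 <- vb_glm(fx$y, fx$X)
  f2 <- vb_glm(fx$y, fx$X)
  expect_identical(f1$free_energy, f2$free_energy)
})

test_that("a 3-nat evidence difference maps to posterior odds ~ 20", {
  expect_equal(exp(3), 20.09, tolerance = 1e-3)
  # two-model posterior under equal priors
  post <- exp(c(3, 0)) / sum(exp(c(3, 0)))
  expect_equal(post[1] / post[2], exp(3), tolerance = 1e-12)
})

test_that("free energy equals the conjugate closed form with fixed hyperparameters", {
  for (s in 1:5) {
    fx <- make_glm_fixture(s)
    alpha <- 0.03; lambda <- 0.2
    fit <- vb_glm(fx$y, fx$X, fixed_hyper = TRUE, alpha0 = alpha,
                  lambda0 = lambda, tol = 1e-12)
    expect_equal(fit$free_energy,
                 log_marginal_oracle(fx$y, fx$X, alpha, lambda),
                 tolerance = 1e-6)
  }
})

test_that("free energy is non-decreasing across VB iterations", {
  for (s in 1:5) {
    fx <- make_glm_fixture(s)
    fit <- vb_glm(fx$y, fx$X)
    expect_true(all(diff(fit$f_trace) > -1e-8))
  }
})

test_that("rank-deficient designs error; redundant regressors never gain evidence", {
  fx <- make_glm_fixture(2)
  expect_error(vb_glm(fx$y, cbind(fx$X, fx$X[, 2])),
               class = "megmyelin_input_error")
  for (s in 1:10) {
    fx <- make_glm_fixture(s)
    near_dup <- fx$X[, 2] + withr::with_seed(s + 500, rnorm(10, sd = 1e-3))
    f_base <- vb_glm(fx$y, fx$X)$free_energy
    f_aug <- vb_glm(fx$y, cbind(fx$X, dup = near_dup))$free_energy
    expect_lte(f_aug, f_base + 1e-6)
  }
})

test_that("weight posterior shrinks sensibly and tidies into broom-style output", {
  fx <- make_glm_fixture(3, n = 40, beta = c(40, 8), sd = 2)
  fit <- vb_glm(fx$y, fx$X)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "myelin"))
  expect_equal(td$estimate[1], 40, tolerance = 0.1)
  expect_equal(td$estimate[2], 8, tolerance = 0.2)
  gl <- glance(fit)
  expect_true(gl$converged)
})

test_that("spatial-extent comparison favours the planted extent", {
  # association planted only in TE1.2
  cfg <- sim_config(seed = 31, association_rho = 0.95, n_hemispheres = 10)
  recs <- simulate_hemisphere_records(cfg, plant = "R1:TE1.2")$records
  sx <- spatial_extent_comparison(recs, "R1")
  expect_equal(sx$extent, c("TE1.2", "TE1", "global"))
  expect_equal(min(sx$log_bayes_factor), 0)
  expect_gt(sx$log_evidence[sx$extent == "TE1.2"],
            sx$log_evidence[sx$extent == "global"] + 3)

  # identical regressors across extents: all Bayes factors vanish
  same <- recs
  base <- dplyr::filter(recs, .data$roi == "TE1.2")
  for (roi_l in c("TE1.0", "TE1.1", "global")) {
    same$myelin[same$roi == roi_l] <- base$myelin[match(
      paste(same$hemisphere_id[same$roi == roi_l], same$map[same$roi == roi_l]),
      paste(base$hemisphere_id, base$map))]
  }
  sx_same <- spatial_extent_comparison(same, "R1")
  expect_equal(sx_same$log_bayes_factor, rep(0, 3), tolerance = 1e-6)

  expect_error(spatial_extent_comparison(
    dplyr::filter(recs, .data$roi != "global"), "R1"),
    class = "megmyelin_input_error")
})

test_that("a global-only association does not leave the global model worst", {
  cfg <- sim_config(seed = 33, association_rho = 0.95, n_hemispheres = 10)
  recs <- simulate_hemisphere_records(cfg, plant = "R1:global")$records
  sx <- spatial_extent_comparison(recs, "R1")
  expect_gt(sx$log_bayes_factor[sx$extent == "global"], 0)
  # ordering agrees with the exact conjugate evidence at fixed hyperparameters
  ev_fixed <- vapply(c("TE1.2", "TE1", "global"), function(ext) {
    x <- if (ext == "TE1") {
      (megmyelin:::records_glm_inputs(recs, "R1", "TE1.0")$x +
         megmyelin:::records_glm_inputs(recs, "R1", "TE1.1")$x +
         megmyelin:::records_glm_inputs(recs, "R1", "TE1.2")$x) / 3
    } else {
      megmyelin:::records_glm_inputs(recs, "R1", ext)$x
    }
    y <- megmyelin:::records_glm_inputs(recs, "R1", "TE1.2")$y
    X <- cbind(1, x - mean(x))
    log_marginal_oracle(y, X, alpha = 1e-4, lambda = 1 / var(y))
  }, numeric(1))
  sx_fixed <- vapply(c("TE1.2", "TE1", "global"), function(ext) {
    sx$log_evidence[sx$extent == ext]
  }, numeric(1))
  expect_equal(order(ev_fixed), order(sx_fixed))
})

test_that("family posteriors: uniformity, dominance, high-precision oracle, invariance", {
  grid <- tidyr::expand_grid(map = map_types(), roi = roi_labels())

  flat <- dplyr::mutate(grid, log_evidence = -12.3)
  fam <- family_comparison(flat)
  expect_equal(fam$roi_families$posterior, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(fam$map_families$posterior, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(fam$roi_families$posterior), 1, tolerance = 1e-12)
  expect_equal(sum(fam$map_families$posterior), 1, tolerance = 1e-12)

  dom <- dplyr::mutate(grid, log_evidence = ifelse(
    .data$map == "R1" & .data$roi == "TE1.2", 100, 0))
  fam_dom <- family_comparison(dom)
  expect_gt(fam_dom$roi_families$posterior[fam_dom$roi_families$roi == "TE1.2"],
            0.999)
  expect_gt(fam_dom$map_families$posterior[fam_dom$map_families$map == "R1"],
            0.999)

  withr::with_seed(5, {
    rnd <- dplyr::mutate(grid, log_evidence = rnorm(18, sd = 4))
  })
  fam_rnd <- family_comparison(rnd)
  # direct normalisation oracle at shifted precision
  w <- exp(rnd$log_evidence - mean(rnd$log_evidence))
  post <- w / sum(w)
  for (i in seq_len(6)) {
    roi_i <- fam_rnd$roi_families$roi[i]
    expect_equal(fam_rnd$roi_families$posterior[i],
                 sum(post[rnd$roi == roi_i]), tolerance = 1e-12)
  }
  # invariance to adding a constant to all log evidences
  fam_shift <- family_comparison(
    dplyr::mutate(rnd, log_evidence = .data$log_evidence + 1234))
  expect_equal(fam_shift$roi_families$posterior,
               fam_rnd$roi_families$posterior, tolerance = 1e-10)

  expect_error(family_comparison(dplyr::slice(rnd, -1)),
               class = "megmyelin_input_error")
})

test_that("planted (R1, TE1.2) associations dominate the family posteriors", {
  wins <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = 60000 + s, association_rho = 0.95,
                      n_hemispheres = 10)
    recs <- simulate_hemisphere_records(cfg, plant = "R1:TE1.2")$records
    fam <- family_comparison(model_evidence_set(recs))
    top_roi <- fam$roi_families$roi[which.max(fam$roi_families$posterior)]
    top_map <- fam$map_families$map[which.max(fam$map_families$posterior)]
    top_roi == "TE1.2" && top_map == "R1"
  }, logical(1))
  expect_gte(mean(wins), 0.90)
})
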