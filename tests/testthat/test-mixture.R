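test_that("the mixture likelihood matches hand-computed values", {
  one <- tibble::tibble(target_angle_deg = 40,
                        distractor_angles_deg = list(c(160, 280)),
                        reported_angle_deg = 40)
  # uniform-only: each trial contributes ln(1/360)
  many <- one[rep(1, 7), ]
  many$reported_angle_deg <- seq(0, 300, 50)
  expect_equal(loglik_mixture(many, mixture_params(0, 0, 1, kappa = 3)),
               7 * log(1 / 360))
  # two-component value at zero deviation, written out from the density
  k <- 5
  f_t <- exp(k) / (2 * pi * besselI(k, 0)) * pi / 180
  f_d <- (exp(k * cos(120 * pi / 180)) + exp(k * cos(240 * pi / 180))) /
    (2 * 2 * pi * besselI(k, 0)) * pi / 180
  expect_equal(loglik_mixture(one, mixture_params(0.5, 0, 0.5, kappa = k)),
               log(0.5 * f_t + 0.5 / 360), tolerance = 1e-10)
  expect_equal(loglik_mixture(one, mixture_params(0.4, 0.25, 0.35, kappa = k)),
               log(0.4 * f_t + 0.25 * f_d + 0.35 / 360), tolerance = 1e-10)
  expect_error(mixture_params(0.5, 0.2, 0.2, 3), "summing to 1")
  bad <- one
  bad$reported_angle_deg <- NA_real_
  expect_error(loglik_mixture(bad, mixture_params(1, 0, 0, 1)), "missing")
})

test_that("EM recovers generating parameters and beats a brute-force grid", {
  tr <- make_mixture_data(200, 0.68, 0.16, 0.16, sd_deg = 18.4, seed = 71)
  fit <- fit_mixture(tr, seed = 72)
  expect_true(fit$converged)
  grid <- oracle_grid_search(tr)
  expect_gte(fit$log_likelihood, grid$ll - 1e-6)
  # the coarse grid's argmax sits near the generating parameters
  expect_equal(grid$p_target, 0.68, tolerance = 0.12)
  expect_equal(grid$sd_deg, 18.4, tolerance = 4)
  # and near the EM solution
  expect_equal(fit$params$p_target, grid$p_target, tolerance = 0.06)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (s in 1:20) {
    w <- rexp(3)
    w <- w / sum(w)
    tr <- make_mixture_data(100, w[1], w[2], w[3],
                            sd_deg = runif(1, 10, 35), n_items = 8L,
                            seed = 100 + s)
    fit <- fit_mixture(tr, n_starts = 3, seed = 200 + s, trace = TRUE)
    expect_true(all(diff(fit$ll_path) > -1e-6))
  }
})

test_that("degenerate and sparse data are handled explicitly", {
  # all responses exactly at the target: essentially pure target component
  tr <- make_mixture_data(60, 1, 0, 0, sd_deg = 18.4, seed = 81)
  tr$reported_angle_deg <- tr$target_angle_deg
  fit <- fit_mixture(tr, seed = 82)
  expect_gte(fit$params$p_target, 0.99)
  expect_true(fit$kappa_at_bound)
  expect_false(fit_usable(fit))
  # too few trials: refused with a reason, mirroring subject exclusion
  small <- make_mixture_data(10, 0.7, 0.15, 0.15, seed = 83)
  fit_small <- fit_mixture(small)
  expect_false(fit_small$converged)
  expect_match(fit_small$exclusion_reason, "trials")
  expect_null(fit_small$params)
})

test_that("responsibilities normalise and identify obvious swaps", {
  tr <- make_mixture_data(150, 0.6, 0.2, 0.2, sd_deg = 18.4, seed = 91)
  params <- mixture_params(0.6, 0.2, 0.2, kappa = sd_to_k(18.4))
  r <- responsibilities(tr, params)
  expect_equal(r$r_target + r$r_nontarget + r$r_uniform, rep(1, nrow(tr)),
               tolerance = 1e-12)
  # a response on a distractor far from the target is attributed to the swap
  one <- tibble::tibble(target_angle_deg = 0,
                        distractor_angles_deg = list(150),
                        reported_angle_deg = 150)
  r1 <- responsibilities(one, mixture_params(0.6, 0.3, 0.1, kappa = 20))
  expect_gt(r1$r_nontarget, 0.95)
})

test_that("swap-component likelihood histograms separate swap-rich from swap-free data", {
  params <- mixture_params(0.68, 0.16, 0.16, kappa = sd_to_k(18.4))
  rich <- make_mixture_data(1500, 0.68, 0.16, 0.16, seed = 95)
  free <- make_mixture_data(1500, 0.84, 0.0, 0.16, seed = 96)
  thr <- log(0.16 / 360)  # NT mass at the uniform floor
  frac_rich <- mean(responsibilities(rich, params)$nt_loglik > thr)
  frac_free <- mean(responsibilities(free, params)$nt_loglik > thr)
  expect_gt(frac_rich, frac_free + 0.05)
  # matched generative runs give matched histogram summaries
  rich2 <- make_mixture_data(1500, 0.68, 0.16, 0.16, seed = 97)
  frac_rich2 <- mean(responsibilities(rich2, params)$nt_loglik > thr)
  expect_equal(frac_rich, frac_rich2, tolerance = 0.05)
})
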