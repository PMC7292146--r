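test_that("discrete displays use the evenly spaced slots with uniform targets", {
  cfg <- display_config(6, "discrete_slots")
  tr <- generate_displays(cfg, 10000, seed = 5)
  expect_true(all(tr$target_angle_deg %in% seq(0, 300, by = 60)))
  expect_true(all(vapply(tr$distractor_angles_deg, length, integer(1)) == 5L))
  expect_true(all(vapply(seq_len(20), function(i) {
    setequal(c(tr$target_angle_deg[i], tr$distractor_angles_deg[[i]]),
             seq(0, 300, by = 60))
  }, logical(1))))
  expect_gt(chisq.test(table(tr$target_slot))$p.value, 0.001)
})

test_that("continuous displays respect the minimum separation", {
  cfg <- display_config(10, "continuous", min_separation = 12.6)
  tr <- generate_displays(cfg, 1000, seed = 9)
  min_gap <- vapply(seq_len(nrow(tr)), function(i) {
    ang <- sort(c(tr$target_angle_deg[i], tr$distractor_angles_deg[[i]]))
    min(diff(ang), 360 - (max(ang) - min(ang)))
  }, numeric(1))
  expect_true(all(min_gap >= 12.6))
  expect_error(display_config(30, "continuous", min_separation = 12.6),
               "infeasible")
})

test_that("degenerate observers behave as their single component", {
  cfg <- display_config(8, "continuous")
  tr <- generate_displays(cfg, 1000, seed = 21)
  # target-only, near-deterministic kernel
  hit <- simulate_responses(tr, observer_params(1, 1, 0, 0, kappa = 1e4),
                            cfg, seed = 22)
  expect_true(all(abs(report_errors(hit)) < 3))
  # uniform-only: errors indistinguishable from uniform
  tr5 <- generate_displays(cfg, 5000, seed = 23)
  unif <- simulate_responses(tr5, observer_params(1, 0, 0, 1, kappa = 5),
                             cfg, seed = 24)
  expect_gt(ks.test(report_errors(unif), "punif", -180, 180)$p.value, 0.001)
  # swap-only with a sharp kernel lands on a distractor
  swp <- simulate_responses(tr, observer_params(1, 0, 1, 0, kappa = 1e4),
                            cfg, seed = 25)
  near_distractor <- vapply(seq_len(nrow(swp)), function(i) {
    min(abs(wrap_error(swp$reported_angle_deg[i],
                       swp$distractor_angles_deg[[i]]))) < 5
  }, logical(1))
  expect_true(all(near_distractor))
})

test_that("component frequencies and identity accuracy match the generative model", {
  cfg <- display_config(10, "continuous")
  tr <- generate_displays(cfg, 5000, seed = 31)
  p_known <- 0.6
  obs <- observer_params(p_known, 0.68, 0.16, 0.16, sd_deg = 18.4)
  sim <- simulate_responses(tr, obs, cfg, seed = 32)
  known <- sim$component != "identity_guess"
  expect_lt(abs(mean(known) - p_known), 0.02)
  freq <- prop.table(table(sim$component[known]))
  expect_lt(abs(freq[["target"]] - 0.68), 0.02)
  expect_lt(abs(freq[["nontarget"]] - 0.16), 0.02)
  expect_lt(abs(freq[["uniform"]] - 0.16), 0.02)
  # observed accuracy = p + (1 - p)/26, the generative counterpart of the
  # guessing-correction formula
  expect_lt(abs(mean(sim$identity_correct) -
                  (p_known + (1 - p_known) / 26)), 0.02)
})

test_that("seeded simulation runs are bit-reproducible", {
  cfg <- display_config(8, "continuous")
  a <- simulate_responses(generate_displays(cfg, 50, seed = 41),
                          observer_params(0.5, 0.7, 0.2, 0.1, kappa = 10),
                          cfg, seed = 42)
  b <- simulate_responses(generate_displays(cfg, 50, seed = 41),
                          observer_params(0.5, 0.7, 0.2, 0.1, kappa = 10),
                          cfg, seed = 42)
  expect_identical(a, b)
})

test_that("the validation sweep splits non-swap mass 1:4 between guesses and targets", {
  cfg <- display_config(10, "continuous")
  tpl <- generate_displays(cfg, 2500, seed = 51)
  sw <- generate_validation_sweep(tpl, nt_grid = c(0, 100), seed = 52)
  comp0 <- table(sw[[1]]$trials$component)
  expect_equal(unname(comp0[["uniform"]]) / nrow(tpl), 0.20, tolerance = 0.02)
  expect_equal(unname(comp0[["target"]]) / nrow(tpl), 0.80, tolerance = 0.02)
  # at 100% swap, every response is kernel noise around a distractor
  tr100 <- sw[[2]]$trials
  expect_true(all(tr100$component == "nontarget"))
  near <- vapply(seq_len(nrow(tr100)), function(i) {
    min(abs(wrap_error(tr100$reported_angle_deg[i],
                       tr100$distractor_angles_deg[[i]])))
  }, numeric(1))
  expect_true(all(near < 90))
  expect_lt(median(near), 25)
})

test_that("the default sweep produces one dataset per percentage point", {
  cfg <- display_config(10, "continuous")
  tpl <- generate_displays(cfg, 30, seed = 61)
  sw <- generate_validation_sweep(tpl, seed = 62)
  expect_length(sw, 101L)
  expect_equal(vapply(sw, `[[`, numeric(1), "nt_true"), 0:100)
  expect_error(generate_validation_sweep(tpl[0, ]), "at least one")
})
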