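test_that("the guessing-correction chain reproduces the published worked example", {
  # observed 70% identity over 26 alternatives, 71% location over 6 slots
  expect_equal(round(100 * correct_forced_choice(0.70, 1 / 26), 1), 68.8)
  expect_equal(round(100 * lucky_guess_share(0.70, 1 / 26), 1), 1.7)
  expect_equal(round(100 * correct_forced_choice(0.71, 1 / 6), 1), 65.2)
  ct <- combined_location_error(0.71, 0.70)
  expect_equal(round(100 * ct$loc_both_corrected, 1), 63.5)
  expect_equal(round(100 * ct$true_location_error, 1), 36.5)
  # invariant links between the table fields
  expect_equal(ct$loc_both_corrected, ct$loc_corrected - ct$lucky_share)
  expect_equal(ct$true_location_error, 1 - ct$loc_both_corrected)
})

test_that("corrections clamp at chance and handle edge cases", {
  expect_equal(correct_forced_choice(1 / 26, 1 / 26), 0)
  expect_equal(correct_forced_choice(0.01, 1 / 6), 0)
  expect_equal(lucky_guess_share(1.0, 1 / 26), 0)
  expect_error(correct_forced_choice(0.5, 1), "chance")
  expect_error(lucky_guess_share(0, 1 / 26), "> 0")
})

test_that("correction inverts the generative identity model", {
  cfg <- display_config(8, "continuous")
  tr <- generate_displays(cfg, 5000, seed = 101)
  for (p in c(0.3, 0.6, 0.85)) {
    sim <- simulate_responses(tr, observer_params(p, 0.7, 0.15, 0.15,
                                                  sd_deg = 18.4),
                              cfg, seed = round(1000 * p))
    est <- correct_forced_choice(mean(sim$identity_correct), 1 / 26)
    expect_equal(est, p, tolerance = 0.02)
  }
})

test_that("the doubly corrected accuracy is monotone in its inputs", {
  loc <- seq(0.3, 0.9, by = 0.1)
  both <- vapply(loc, function(l) {
    combined_location_error(l, 0.7)$loc_both_corrected
  }, numeric(1))
  expect_true(all(diff(both) > 0))
  # more lucky guessing pulls the corrected accuracy down
  id_obs <- seq(0.4, 0.95, by = 0.05)
  lucky <- lucky_guess_share(id_obs, 1 / 26)
  both2 <- vapply(id_obs, function(i) {
    combined_location_error(0.7, i)$loc_both_corrected
  }, numeric(1))
  expect_true(all(diff(lucky) < 0))
  expect_true(all(diff(both2) > 0))
})

test_that("adjacent/distant ratios match the published coarse-grain checks", {
  expect_equal(round(adjacent_distant_ratio(14, 10.5), 2), 0.57)
  expect_equal(round(adjacent_distant_ratio(16, 14), 2), 0.53)
  expect_true(is.na(adjacent_distant_ratio(0, 0)))
})

test_that("discrete summaries count target, adjacent and distant slots correctly", {
  cfg <- display_config(6, "discrete_slots")
  tr <- generate_displays(cfg, 2000, seed = 111)
  sim <- simulate_responses(tr, observer_params(0.7, 0.6, 0.15, 0.25,
                                                sd_deg = 15), cfg, seed = 112)
  s <- summarize_discrete(sim)
  expect_equal(s$identity_accuracy, mean(sim$identity_correct))
  # frequencies partition correct-identity trials up to the opposite slot
  idc <- sim[sim$identity_correct == 1, ]
  opp <- mean(((idc$reported_slot - idc$target_slot) %% 6) == 3)
  expect_equal(s$freq_target + s$freq_adjacent + s$freq_distant + opp, 1)
  expect_equal(s$adjacent_ratio,
               s$freq_adjacent / (s$freq_adjacent + s$freq_distant))
  # degenerate: all reports at the target slot, ratio undefined
  perfect <- sim
  perfect$reported_slot <- perfect$target_slot
  perfect$identity_correct <- 1L
  sp <- summarize_discrete(perfect)
  expect_equal(sp$location_accuracy, 1)
  expect_true(is.na(sp$adjacent_ratio))
  expect_error(summarize_discrete(make_mixture_data(30, 1, 0, 0, seed = 1)),
               "discrete")
})
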