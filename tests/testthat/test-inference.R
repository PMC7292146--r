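test_that("percentile bootstrap handles degenerate and failing statistics", {
  same <- rep(0.4, 10)
  b <- bootstrap_ci(same, mean, scheme = "trials", n_boot = 100, seed = 1)
  expect_equal(b$lower, b$upper)
  expect_equal(b$point, 0.4)
  flaky <- function(x) stop("no")
  expect_error(bootstrap_ci(rnorm(10), flaky, scheme = "trials",
                            n_boot = 50, seed = 2), "failed on")
  expect_error(bootstrap_ci(1, mean, scheme = "trials"), "at least 2")
})

test_that("subject-level resampling keeps subjects intact", {
  d <- tibble::tibble(subject_id = rep(1:6, each = 10),
                      v = rep(c(0, 10), each = 30)[1:60])
  b <- bootstrap_ci(d, function(x) mean(x$v), scheme = "subjects",
                    n_boot = 200, seed = 3)
  # resampled means are averages of whole-subject blocks: multiples of 10/6
  expect_true(b$lower >= 0 && b$upper <= 10)
  expect_equal(b$point, 5)
})

test_that("trial-level bootstrap of the swap weight brackets the generating value", {
  tr <- make_mixture_data(800, 0.68, 0.16, 0.16, seed = 121)
  b <- bootstrap_ci(tr, function(d) {
    f <- fit_mixture(d, n_starts = 4)
    f$params$p_nontarget
  }, scheme = "trials", n_boot = 60, seed = 122)
  expect_lt(b$lower, 0.16)
  expect_gt(b$upper, 0.135)
  expect_true(b$lower <= b$point && b$point <= b$upper)
})

test_that("bootstrap intervals tighten with more units", {
  set.seed(131)
  widths <- vapply(c(20, 200), function(n) {
    mean(vapply(1:25, function(i) {
      x <- rnorm(n, 0.3, 0.2)
      b <- bootstrap_ci(x, mean, scheme = "trials", n_boot = 200)
      b$upper - b$lower
    }, numeric(1)))
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("power analysis saturates on well-separated pools and stays near alpha on null pools", {
  pool_strong <- seq(0.2, 0.5, length.out = 20)
  pa <- power_analysis(pool_strong, sizes = c(5, 10, 20), seed = 141)
  expect_equal(pa$prop_excluding_zero[pa$size == 20], 1.0)
  set.seed(142)
  pool_null <- rnorm(20, 0, 0.3)
  pool_null <- pool_null - mean(pool_null)  # exactly centred: a true null
  pa0 <- power_analysis(pool_null, sizes = 20, n_outer = 200, seed = 143)
  expect_lt(pa0$prop_excluding_zero, 0.15)
  expect_error(power_analysis(c(1, 2)), "at least 5")
})

test_that("paired t + Bayes factor flags nulls, excludes subjects, and rejects constant data", {
  set.seed(151)
  x <- rnorm(20, 0.1, 0.05)
  y <- x + rnorm(20, 0, 0.04)  # no systematic difference
  r <- paired_t_and_bf(x, y)
  expect_equal(r$df, 19)
  expect_lt(r$bf10, 1.5)
  # exclusion reduces the degrees of freedom, as when one subject's fit fails
  r2 <- paired_t_and_bf(x, y, include = c(FALSE, rep(TRUE, 19)))
  expect_equal(r2$df, 18)
  expect_equal(r2$n_excluded, 1)
  expect_error(paired_t_and_bf(x, x), "zero variance")
})

test_that("the JZS Bayes factor matches an independent Monte-Carlo integration", {
  for (case in list(c(t = 2.5, n = 20), c(t = -2.38, n = 20),
                    c(t = 0.28, n = 19))) {
    bf <- jzs_bf(case[["t"]], case[["n"]])
    bf_mc <- mc_jzs_bf(case[["t"]], case[["n"]], n_mc = 4e5)
    expect_equal(bf, bf_mc, tolerance = 0.01)
  }
  # vanishing t with large n favours the null
  expect_lt(jzs_bf(1e-8, 100), 0.25)
  expect_lt(jzs_bf(0.05, 200), jzs_bf(0.05, 20))
})

test_that("swap recovery tracks the generating swap rate on a small sweep", {
  cfg <- display_config(10, "continuous")
  tpl <- generate_displays(cfg, 600, seed = 161)
  sw <- generate_validation_sweep(tpl, nt_grid = seq(0, 100, 25), seed = 162)
  rec <- nt_recovery_study(sw, n_starts = 4, seed = 163)
  expect_equal(nrow(rec$table), 5)
  expect_gt(rec$pearson_r, 0.95)
})

test_that("a swap-free dataset at full scale yields a near-zero swap estimate", {
  cfg <- display_config(10, "continuous")
  tpl <- generate_displays(cfg, 2826, seed = 165)
  sw0 <- generate_validation_sweep(tpl, nt_grid = 0, seed = 166)
  fit <- fit_mixture(sw0[[1]]$trials, n_starts = 5, seed = 167)
  expect_lte(100 * fit$params$p_nontarget, 3)
})
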