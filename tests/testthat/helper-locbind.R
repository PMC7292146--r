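# Shared fixtures and independent oracles, built in code at test time.

# Quick continuous dataset from a known observer (identity always known, so
# every trial enters the location analyses).
make_mixture_data <- function(n_trials, p_target, p_nontarget, p_uniform,
                              sd_deg = 18.4, n_items = 10L, seed = 1,
                              kernel = "wrapped_normal") {
  cfg <- display_config(n_items, "continuous")
  tr <- generate_displays(cfg, n_trials, seed = seed)
  obs <- observer_params(1, p_target, p_nontarget, p_uniform,
                         sd_deg = sd_deg, error_kernel = kernel)
  simulate_responses(tr, obs, cfg, seed = seed + 1000L)
}

# Independent brute-force likelihood oracle: its own von Mises density and
# an exhaustive grid over (pT, pNT) x SD. Returns the grid maximum and the
# argmax parameters.
oracle_grid_search <- function(trials, sd_grid = 3:60, w_step = 0.02) {
  vm_deg <- function(delta_deg, kappa) {
    d <- delta_deg * pi / 180
    exp(kappa * (cos(d) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) * pi / 180
  }
  err_t <- wrap_error(trials$reported_angle_deg, trials$target_angle_deg)
  m <- lengths(trials$distractor_angles_deg)
  err_d <- wrap_error(rep(trials$reported_angle_deg, times = m),
                      unlist(trials$distractor_angles_deg))
  d_trial <- rep(seq_len(nrow(trials)), times = m)
  pt <- seq(0, 1, by = w_step)
  grid_w <- expand.grid(p_target = pt, p_nontarget = pt)
  grid_w <- grid_w[grid_w$p_target + grid_w$p_nontarget <= 1 + 1e-12, ]
  W <- cbind(grid_w$p_target, grid_w$p_nontarget,
             pmax(0, 1 - grid_w$p_target - grid_w$p_nontarget))
  best <- list(ll = -Inf)
  for (sd in sd_grid) {
    kappa <- sd_to_k(sd)
    f_t <- vm_deg(err_t, kappa)
    f_nt <- as.numeric(rowsum(vm_deg(err_d, kappa), d_trial)) / m
    F <- cbind(f_t, f_nt, 1 / 360)
    ll_all <- colSums(log(F %*% t(W)))
    i <- which.max(ll_all)
    if (ll_all[i] > best$ll) {
      best <- list(ll = ll_all[i], p_target = W[i, 1], p_nontarget = W[i, 2],
                   p_uniform = W[i, 3], sd_deg = sd)
    }
  }
  best
}

# Monte-Carlo oracle for the JZS Bayes factor: average the noncentral-t
# likelihood over Cauchy prior draws.
mc_jzs_bf <- function(t, n, rscale = sqrt(2) / 2, n_mc = 5e5, seed = 42) {
  withr::with_seed(seed, {
    delta <- rcauchy(n_mc, 0, rscale)
    suppressWarnings(mean(dt(t, n - 1, ncp = delta * sqrt(n))) / dt(t, n - 1))
  })
}
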