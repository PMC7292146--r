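# Three-component circular mixture of location-report errors:
# a von Mises centred at the target, von Mises components centred at each
# distractor (sharing the target's concentration), and a uniform component.
# Fitted by maximum likelihood via EM with multiple restarts.

#' Mixture model parameters
#'
#' @param p_target,p_nontarget,p_uniform Component weights; must sum to 1.
#'   `p_nontarget` is the swap probability (a response centred on a
#'   distractor), `p_uniform` the probability of a response carrying
#'   essentially no angular information about the target.
#' @param kappa Shared von Mises concentration of the target and swap
#'   components, `> 0`.
#' @return A `mixture_params` list.
#' @examples
#' mixture_params(0.68, 0.16, 0.16, kappa = 10.22)
#' @export
mixture_params <- function(p_target, p_nontarget, p_uniform, kappa) {
  w <- c(p_target, p_nontarget, p_uniform)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must be probabilities summing to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (!is.finite(kappa) || kappa <= 0) {
    stop("`kappa` must be finite and > 0", call. = FALSE)
  }
  structure(list(p_target = p_target, p_nontarget = p_nontarget,
                 p_uniform = p_uniform, kappa = kappa),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("Mixture params: pT = %.3f, pNT = %.3f, pU = %.3f, kappa = %.2f (SD %.2f deg)\n",
              x$p_target, x$p_nontarget, x$p_uniform, x$kappa, k_to_sd(x$kappa)))
  invisible(x)
}

# Flattened per-trial data used by the likelihood/EM: target deviations,
# concatenated distractor deviations with a trial index, and distractor
# counts.
prep_mixture_data <- function(trials) {
  need <- c("target_angle_deg", "distractor_angles_deg", "reported_angle_deg")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trials are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(trials$reported_angle_deg) || anyNA(trials$target_angle_deg)) {
    stop("trials with missing angles cannot enter the mixture likelihood",
         call. = FALSE)
  }
  m <- lengths(trials$distractor_angles_deg)
  if (any(m < 1L)) {
    stop("every trial needs at least one distractor angle", call. = FALSE)
  }
  n <- nrow(trials)
  err_t <- deg2rad(wrap_error(trials$reported_angle_deg, trials$target_angle_deg))
  d_all <- unlist(trials$distractor_angles_deg, use.names = FALSE)
  rep_resp <- rep(trials$reported_angle_deg, times = m)
  err_d <- deg2rad(wrap_error(rep_resp, d_all))
  list(n = n, err_t = err_t, err_d = err_d,
       d_trial = rep(seq_len(n), times = m), m = m)
}

# von Mises density per degree at deviation `delta` (radians), vectorised.
vm_dens_rad_arg <- function(delta, kappa) {
  exp(kappa * (cos(delta) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) * pi / 180
}

# Per-trial component densities (per degree): target, swap (averaged over
# that trial's distractors), uniform.
component_densities <- function(prep, kappa) {
  f_t <- vm_dens_rad_arg(prep$err_t, kappa)
  f_d_long <- vm_dens_rad_arg(prep$err_d, kappa)
  f_nt <- as.numeric(rowsum(f_d_long, prep$d_trial, reorder = TRUE)) / prep$m
  list(f_t = f_t, f_nt = f_nt, f_u = rep(1 / 360, prep$n), f_d_long = f_d_long)
}

#' Log-likelihood of the three-component mixture
#'
#' Sum over trials of the log of
#' `pT * vM(err_T; kappa) + pNT * mean_j vM(err_Dj; kappa) + pU / 360`,
#' with densities per degree and the swap component averaged uniformly over
#' that trial's distractors.
#'
#' @param trials Trial tibble with `target_angle_deg`,
#'   `distractor_angles_deg` (list column) and `reported_angle_deg`.
#' @param params A [mixture_params()].
#' @return Log-likelihood in nats.
#' @export
loglik_mixture <- function(trials, params) {
  stopifnot(inherits(params, "mixture_params"))
  prep <- prep_mixture_data(trials)
  cd <- component_densities(prep, params$kappa)
  sum(log(params$p_target * cd$f_t + params$p_nontarget * cd$f_nt +
            params$p_uniform * cd$f_u))
}

# Invert A(kappa) = I1/I0 = R by bracketed root-finding, clamped to bounds.
a_inv <- function(R, bounds) {
  if (!is.finite(R) || R <= bessel_ratio(bounds[1])) return(bounds[1])
  if (R >= bessel_ratio(bounds[2])) return(bounds[2])
  stats::uniroot(function(k) bessel_ratio(k) - R, interval = bounds,
                 tol = 1e-10)$root
}

# One EM run from a given start; returns params, ll (evaluated at the
# returned params), iterations, optional ll trace.
em_run <- function(prep, w0, kappa0, tol, max_iter, kappa_bounds,
                   trace = FALSE) {
  w <- w0
  kappa <- kappa0
  ll_old <- -Inf
  ll_path <- numeric(0)
  converged <- FALSE
  it_used <- 0L
  for (it in seq_len(max_iter)) {
    it_used <- it
    cd <- component_densities(prep, kappa)
    num_t <- w[1] * cd$f_t
    num_nt <- w[2] * cd$f_nt
    num_u <- w[3] * cd$f_u
    tot <- num_t + num_nt + num_u
    ll <- sum(log(tot))
    if (trace) ll_path <- c(ll_path, ll)
    r_t <- num_t / tot
    r_nt <- num_nt / tot
    r_u <- num_u / tot
    # per-distractor responsibilities, for the kappa update
    r_long <- (w[2] / prep$m[prep$d_trial]) * cd$f_d_long / tot[prep$d_trial]
    w <- c(mean(r_t), mean(r_nt), mean(r_u))
    denom <- sum(r_t) + sum(r_nt)
    Rbar <- if (denom > 0) {
      (sum(r_t * cos(prep$err_t)) + sum(r_long * cos(prep$err_d))) / denom
    } else 0
    kappa <- a_inv(Rbar, kappa_bounds)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # evaluate the likelihood at the parameters actually returned
  cd <- component_densities(prep, kappa)
  ll_final <- sum(log(w[1] * cd$f_t + w[2] * cd$f_nt + w[3] * cd$f_u))
  if (trace) ll_path <- c(ll_path, ll_final)
  list(w = w, kappa = kappa, ll = ll_final, iter = it_used,
       converged = converged, ll_path = ll_path)
}

#' Fit the three-component mixture by EM with multiple restarts
#'
#' The E-step computes per-trial component responsibilities (swap
#' responsibility split uniformly over that trial's distractors); the
#' M-step updates the weights by responsibility means and the shared
#' concentration by inverting the Bessel ratio `A(kappa) = I1/I0` at the
#' responsibility-weighted mean resultant length of the target- and
#' distractor-aligned deviations. Starting weights are Dirichlet(1,1,1)
#' draws and starting concentrations cycle through SDs of 5, 15, 30 and 60
#' degrees; each start runs a short EM burst and the best is refined to
#' convergence.
#'
#' Fits on fewer than `min_trials` trials are refused (returned
#' non-converged with an `exclusion_reason`), mirroring the exclusion of
#' subjects with too little usable data. A concentration that ends on its
#' bound is flagged via `kappa_at_bound` and treated as unusable by
#' downstream exclusion rules.
#'
#' @param trials Trial tibble (typically identity-correct trials only; see
#'   [filter_identity_correct()]).
#' @param n_starts Number of random restarts.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations for the final refinement.
#' @param start_iter EM iterations per exploratory start.
#' @param min_trials Minimum trials required to attempt a fit.
#' @param kappa_bounds Allowed concentration range.
#' @param seed Optional integer seed (controls the restarts).
#' @param trace Keep the log-likelihood path of the final refinement
#'   (for diagnostics).
#' @return A `locbind_fit` with elements `params` ([mixture_params()] or
#'   `NULL`), `log_likelihood`, `converged`, `kappa_at_bound`, `n_trials`,
#'   `n_starts_used`, `n_iter`, `exclusion_reason`, and `ll_path` when
#'   traced.
#' @examples
#' cfg <- display_config(8, "continuous")
#' tr <- generate_displays(cfg, 200, seed = 1)
#' tr <- simulate_responses(tr, observer_params(1, 0.7, 0.15, 0.15, sd_deg = 18),
#'                          cfg, seed = 2)
#' fit_mixture(tr, seed = 3)
#' @export
fit_mixture <- function(trials, n_starts = 10L, tol = 1e-8, max_iter = 1000L,
                        start_iter = 50L, min_trials = 20L,
                        kappa_bounds = c(0.1, 500), seed = NULL,
                        trace = FALSE) {
  n <- nrow(trials)
  if (n < min_trials) {
    return(structure(list(params = NULL, log_likelihood = NA_real_,
                          converged = FALSE, kappa_at_bound = FALSE,
                          n_trials = n, n_starts_used = 0L, n_iter = 0L,
                          exclusion_reason = sprintf(
                            "only %d trials (< %d required)", n, min_trials),
                          ll_path = NULL),
                     class = "locbind_fit"))
  }
  prep <- prep_mixture_data(trials)
  run <- function() {
    sd_starts <- rep_len(c(5, 15, 30, 60), n_starts)
    starts <- lapply(seq_len(n_starts), function(i) {
      g <- stats::rgamma(3, 1)
      list(w = g / sum(g), kappa = sd_to_k(sd_starts[i]))
    })
    bursts <- lapply(starts, function(s) {
      em_run(prep, s$w, s$kappa, tol, start_iter, kappa_bounds)
    })
    lls <- vapply(bursts, `[[`, numeric(1), "ll")
    best <- bursts[[which.max(lls)]]
    final <- em_run(prep, best$w, best$kappa, tol, max_iter, kappa_bounds,
                    trace = trace)
    at_bound <- final$kappa <= kappa_bounds[1] + 1e-9 ||
      final$kappa >= kappa_bounds[2] - 1e-9
    params <- tryCatch(
      mixture_params(final$w[1], final$w[2], final$w[3], final$kappa),
      error = function(e) NULL)
    structure(list(params = params,
                   log_likelihood = final$ll,
                   converged = final$converged && !is.null(params),
                   kappa_at_bound = at_bound,
                   n_trials = n, n_starts_used = n_starts,
                   n_iter = final$iter,
                   exclusion_reason = if (final$converged) NULL else
                     "EM did not converge within max_iter",
                   ll_path = if (trace) final$ll_path else NULL),
              class = "locbind_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.locbind_fit <- function(x, ...) {
  cat("Three-component circular mixture fit\n")
  cat(sprintf("  trials: %d   converged: %s%s\n", x$n_trials,
              x$converged,
              if (isTRUE(x$kappa_at_bound)) " (kappa at bound)" else ""))
  if (!is.null(x$exclusion_reason)) {
    cat("  excluded: ", x$exclusion_reason, "\n", sep = "")
  }
  if (!is.null(x$params)) {
    print(x$params)
    cat(sprintf("  log-likelihood: %.3f (%d iterations, %d starts)\n",
                x$log_likelihood, x$n_iter, x$n_starts_used))
  }
  invisible(x)
}

#' Is a fit usable for downstream inference?
#'
#' A fit counts as usable when EM converged and the concentration did not
#' end on a bound. Subjects with unusable fits are excluded from paired
#' tests, with the degrees of freedom reduced accordingly.
#'
#' @param fit A `locbind_fit`.
#' @return Logical.
#' @export
fit_usable <- function(fit) {
  inherits(fit, "locbind_fit") && isTRUE(fit$converged) &&
    !isTRUE(fit$kappa_at_bound)
}

#' Per-trial component responsibilities
#'
#' Posterior probabilities, under `params`, that each trial's response came
#' from the target, swap, or uniform component, plus the per-trial
#' log-likelihood of the (weighted) swap component,
#' `log(pNT * mean_j vM(err_Dj))`, the quantity whose histogram separates
#' datasets with and without genuine swap responses.
#'
#' @param trials Trial tibble.
#' @param params A [mixture_params()].
#' @return Tibble with `r_target`, `r_nontarget`, `r_uniform` (summing to 1
#'   per trial) and `nt_loglik`.
#' @export
responsibilities <- function(trials, params) {
  stopifnot(inherits(params, "mixture_params"))
  prep <- prep_mixture_data(trials)
  cd <- component_densities(prep, params$kappa)
  num_t <- params$p_target * cd$f_t
  num_nt <- params$p_nontarget * cd$f_nt
  num_u <- params$p_uniform * cd$f_u
  tot <- num_t + num_nt + num_u
  tibble::tibble(r_target = num_t / tot,
                 r_nontarget = num_nt / tot,
                 r_uniform = num_u / tot,
                 nt_loglik = log(num_nt))
}
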