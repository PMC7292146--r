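# Generative observer: display geometry and simulated identity + location
# responses with the mixture structure the analyses assume.

#' Letter pool from which targets are drawn
#'
#' Fifteen capital letters used as target identities; reports are made from
#' the full 26-letter alphabet, so an uninformed identity guess is correct
#' with probability 1/26.
#' @export
target_letter_pool <- c("R", "L", "C", "P", "F", "K", "B", "G", "Y", "V",
                        "H", "X", "T", "J", "D")

#' Display geometry configuration
#'
#' Describes one display: how many items, whether they sit on evenly spaced
#' discrete slots or at random angles on an invisible circle, and (for
#' continuous layouts) the minimum angular separation between items.
#'
#' The default minimum separation of 12.6 degrees of arc corresponds to a
#' 1-degree visual-angle gap on a circle of 9.1-degree diameter
#' (360 / (pi * 9.1) ~ 12.6).
#'
#' @param n_items Number of items on the circle (target + distractors).
#' @param layout `"discrete_slots"` (items at `i * 360 / n_items`) or
#'   `"continuous"` (random angles with a minimum separation).
#' @param min_separation Minimum pairwise angular distance in degrees of
#'   arc, continuous layouts only.
#' @param alphabet_size Number of identity alternatives a report is chosen
#'   from (26 letters).
#' @param target_pool_size Number of letters targets are drawn from.
#' @return A `display_config` list.
#' @examples
#' display_config(6, "discrete_slots")
#' display_config(10, "continuous")
#' @export
display_config <- function(n_items,
                           layout = c("continuous", "discrete_slots"),
                           min_separation = 12.6,
                           alphabet_size = 26,
                           target_pool_size = length(target_letter_pool)) {
  layout <- match.arg(layout)
  stopifnot(is.numeric(n_items), length(n_items) == 1L, n_items >= 2,
            n_items == round(n_items),
            alphabet_size >= 2, target_pool_size >= 1,
            target_pool_size <= length(target_letter_pool))
  if (layout == "continuous" && n_items * min_separation >= 360) {
    stop(sprintf(
      "infeasible geometry: %d items with %.1f-degree separation need %.1f > 360 degrees",
      n_items, min_separation, n_items * min_separation), call. = FALSE)
  }
  structure(list(n_items = as.integer(n_items), layout = layout,
                 min_separation = if (layout == "continuous") min_separation else NA_real_,
                 alphabet_size = as.integer(alphabet_size),
                 target_pool_size = as.integer(target_pool_size)),
            class = "display_config")
}

#' Generative observer parameters
#'
#' The observer knows the target identity with probability
#' `p_identity_known`; otherwise the identity report is a uniform draw from
#' the alphabet (and may be correct by luck). When the identity is known,
#' the location report comes from a three-component mixture: a kernel
#' centred at the target (weight `p_target`), a kernel centred at a
#' uniformly chosen distractor (`p_nontarget`, a "swap"), or a uniform draw
#' on the circle (`p_uniform`). When the identity is guessed the location
#' is uniform by default (`guess_location = "uniform"`, the conservative
#' assumption); `"item_centered"` instead centres it on a random item, for
#' sensitivity analysis.
#'
#' @param p_identity_known Probability the identity is actually known.
#' @param p_target,p_nontarget,p_uniform Mixture weights, must sum to 1.
#' @param kappa von Mises concentration of the response kernel. Exactly one
#'   of `kappa` / `sd_deg` must be given.
#' @param sd_deg Circular SD of the kernel in degrees (alternative
#'   parameterisation; converted via [sd_to_k()]).
#' @param error_kernel `"von_mises"` or `"wrapped_normal"`. The wrapped
#'   normal draws `N(0, sd_deg)` noise and wraps it onto the circle.
#' @param guess_location Location behaviour on identity-guess trials.
#' @return An `observer_params` list with both `kappa` and `sd_deg` filled.
#' @examples
#' observer_params(0.43, 0.68, 0.16, 0.16, sd_deg = 18.4)
#' @export
observer_params <- function(p_identity_known, p_target, p_nontarget, p_uniform,
                            kappa = NULL, sd_deg = NULL,
                            error_kernel = c("von_mises", "wrapped_normal"),
                            guess_location = c("uniform", "item_centered")) {
  error_kernel <- match.arg(error_kernel)
  guess_location <- match.arg(guess_location)
  w <- c(p_target, p_nontarget, p_uniform)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1) ||
      abs(sum(w) - 1) > 1e-9) {
    stop("`p_target`, `p_nontarget`, `p_uniform` must be probabilities summing to 1",
         call. = FALSE)
  }
  if (!is.finite(p_identity_known) || p_identity_known < 0 || p_identity_known > 1) {
    stop("`p_identity_known` must be a probability", call. = FALSE)
  }
  if (is.null(kappa) == is.null(sd_deg)) {
    stop("give exactly one of `kappa` or `sd_deg`", call. = FALSE)
  }
  if (is.null(kappa)) kappa <- sd_to_k(sd_deg)
  if (is.null(sd_deg)) sd_deg <- k_to_sd(kappa)
  structure(list(p_identity_known = p_identity_known,
                 p_target = p_target, p_nontarget = p_nontarget,
                 p_uniform = p_uniform, kappa = kappa, sd_deg = sd_deg,
                 error_kernel = error_kernel, guess_location = guess_location),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Generative observer parameters\n")
  cat(sprintf("  identity known: %.3f\n", x$p_identity_known))
  cat(sprintf("  location mixture: pT = %.3f, pNT = %.3f, pU = %.3f\n",
              x$p_target, x$p_nontarget, x$p_uniform))
  cat(sprintf("  kernel: %s, kappa = %.3f (SD %.2f deg)\n",
              x$error_kernel, x$kappa, x$sd_deg))
  cat(sprintf("  identity-guess locations: %s\n", x$guess_location))
  invisible(x)
}

# Batch rejection sampler: rows of item angles with all pairwise circular
# distances >= sep. Column 1 is the target.
sample_separated_angles <- function(n_trials, n_items, sep) {
  out <- matrix(NA_real_, 0L, n_items)
  while (nrow(out) < n_trials) {
    m <- max(64L, 2L * (n_trials - nrow(out)))
    cand <- matrix(stats::runif(m * n_items, 0, 360), m, n_items)
    srt <- t(apply(cand, 1, sort))
    gaps <- cbind(srt[, -1, drop = FALSE] - srt[, -n_items, drop = FALSE],
                  360 - (srt[, n_items] - srt[, 1]))
    ok <- apply(gaps, 1, min) >= sep
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n_trials), , drop = FALSE]
}

#' Generate stimulus displays (trials with empty response fields)
#'
#' Continuous layouts draw item angles uniformly on the circle and accept a
#' display only if every pairwise circular distance is at least
#' `min_separation` (rejection sampling). Discrete layouts place items on
#' the `n_items` evenly spaced slots with the target slot uniform.
#'
#' @param config A [display_config()].
#' @param n_trials Trials per subject.
#' @param n_subjects Number of simulated subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per trial: `subject_id`, `trial_id`,
#'   `layout`, `n_items`, `target_identity`, `target_angle_deg`,
#'   `distractor_angles_deg` (list column), `target_slot` (discrete only,
#'   else `NA`), and empty response columns `reported_identity`,
#'   `reported_angle_deg`, `reported_slot`, `identity_correct`.
#' @examples
#' generate_displays(display_config(6, "discrete_slots"), n_trials = 4, seed = 1)
#' @export
generate_displays <- function(config, n_trials, n_subjects = 1L, seed = NULL) {
  stopifnot(inherits(config, "display_config"), n_trials >= 1, n_subjects >= 1)
  run <- function() {
    n <- n_trials * n_subjects
    k <- config$n_items
    if (config$layout == "discrete_slots") {
      step <- 360 / k
      tslot <- sample.int(k, n, replace = TRUE)
      tangle <- (tslot - 1) * step
      dang <- lapply(tslot, function(s) ((setdiff(seq_len(k), s)) - 1) * step)
    } else {
      ang <- sample_separated_angles(n, k, config$min_separation)
      tslot <- rep(NA_integer_, n)
      tangle <- ang[, 1]
      dang <- lapply(seq_len(n), function(i) ang[i, -1])
    }
    tibble::tibble(
      subject_id = rep(seq_len(n_subjects), each = n_trials),
      trial_id = rep(seq_len(n_trials), times = n_subjects),
      layout = config$layout,
      n_items = k,
      target_identity = sample(target_letter_pool[seq_len(config$target_pool_size)],
                               n, replace = TRUE),
      target_angle_deg = tangle,
      distractor_angles_deg = dang,
      target_slot = tslot,
      reported_identity = NA_character_,
      reported_angle_deg = NA_real_,
      reported_slot = NA_integer_,
      identity_correct = NA_integer_
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Kernel noise centred at 0, signed degrees.
kernel_noise <- function(n, params) {
  if (params$error_kernel == "von_mises") {
    rvonmises_deg(n, params$kappa)
  } else {
    rwrappednormal_deg(n, params$sd_deg)
  }
}

#' Simulate identity and location responses for a set of displays
#'
#' Fills the response fields of trials produced by [generate_displays()]
#' according to an [observer_params()] generative model. For discrete-slot
#' layouts the continuous response is snapped to the nearest slot, so a
#' single generative path serves both paradigms.
#'
#' @param trials Trial tibble with display fields populated.
#' @param params An [observer_params()].
#' @param config The [display_config()] used to build the trials (supplies
#'   the alphabet size).
#' @param seed Optional integer seed.
#' @return The trial tibble with `reported_identity`, `reported_angle_deg`,
#'   `reported_slot` and `identity_correct` filled, plus a `component`
#'   column recording the true generating component (`"target"`,
#'   `"nontarget"`, `"uniform"`, or `"identity_guess"`).
#' @examples
#' cfg <- display_config(8, "continuous")
#' tr <- generate_displays(cfg, 10, seed = 1)
#' simulate_responses(tr, observer_params(1, 1, 0, 0, kappa = 50), cfg, seed = 2)
#' @export
simulate_responses <- function(trials, params, config = NULL, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  alphabet_size <- if (is.null(config)) 26L else config$alphabet_size
  run <- function() {
    n <- nrow(trials)
    if (n == 0L) stop("no trials to simulate", call. = FALSE)
    known <- stats::runif(n) < params$p_identity_known
    guessed_id <- sample(LETTERS[seq_len(alphabet_size)], n, replace = TRUE)
    reported_identity <- ifelse(known, trials$target_identity, guessed_id)

    comp <- character(n)
    comp[!known] <- "identity_guess"
    comp[known] <- sample(c("target", "nontarget", "uniform"), sum(known),
                          replace = TRUE,
                          prob = c(params$p_target, params$p_nontarget,
                                   params$p_uniform))
    centre <- rep(NA_real_, n)
    centre[comp == "target"] <- trials$target_angle_deg[comp == "target"]
    idx_nt <- which(comp == "nontarget")
    if (length(idx_nt)) {
      centre[idx_nt] <- vapply(idx_nt, function(i) {
        d <- trials$distractor_angles_deg[[i]]
        d[sample.int(length(d), 1L)]
      }, numeric(1))
    }
    if (params$guess_location == "item_centered") {
      idx_g <- which(comp == "identity_guess")
      if (length(idx_g)) {
        centre[idx_g] <- vapply(idx_g, function(i) {
          items <- c(trials$target_angle_deg[i], trials$distractor_angles_deg[[i]])
          items[sample.int(length(items), 1L)]
        }, numeric(1))
        comp[idx_g] <- "identity_guess"
      }
    }
    kerneled <- !is.na(centre)
    ang <- stats::runif(n, 0, 360)   # uniform component (and uniform guesses)
    if (any(kerneled)) {
      ang[kerneled] <- wrap_angle(centre[kerneled] +
                                    kernel_noise(sum(kerneled), params))
    }
    out <- trials
    out$reported_identity <- reported_identity
    out$identity_correct <- as.integer(reported_identity == trials$target_identity)
    if (all(trials$layout == "discrete_slots")) {
      k <- trials$n_items[1]
      step <- 360 / k
      slot <- (round(ang / step) %% k) + 1L
      out$reported_slot <- as.integer(slot)
      out$reported_angle_deg <- (slot - 1) * step
    } else {
      out$reported_angle_deg <- ang
      out$reported_slot <- NA_integer_
    }
    out$component <- comp
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Location-report errors relative to the target
#'
#' @param trials Trial tibble with responses filled.
#' @return Signed errors in degrees, `(-180, 180]`.
#' @export
report_errors <- function(trials) {
  wrap_error(trials$reported_angle_deg, trials$target_angle_deg)
}

#' Generate the model-validation sweep of simulated datasets
#'
#' Re-uses the stimulus geometry of a set of template trials and, for each
#' swap level in `nt_grid` (percent), replaces every response: a swap
#' response is wrapped-normal noise (SD `sd_deg`) around a randomly chosen
#' distractor, a guess is uniform on the circle, and a target response is
#' wrapped-normal noise around the target. The non-swap mass is split
#' between guessing and target responding in `ratio_guess_to_target`
#' (default 1:4). Identity reports are set correct, since the sweep mimics
#' the identity-correct trial set.
#'
#' @param template_trials Trial tibble supplying target and distractor
#'   angles (responses ignored).
#' @param sd_deg Kernel SD in degrees for target and swap responses.
#' @param ratio_guess_to_target Length-2 numeric, guess : target split of
#'   the non-swap mass.
#' @param nt_grid Swap percentages to simulate (default 0 to 100 in steps
#'   of 1, i.e. 101 datasets).
#' @param seed Optional integer seed.
#' @return A list of class `validation_sweep`; each element is
#'   `list(nt_true = <percent>, trials = <tibble>)`.
#' @examples
#' cfg <- display_config(10, "continuous")
#' tpl <- generate_displays(cfg, 50, seed = 1)
#' sw <- generate_validation_sweep(tpl, nt_grid = c(0, 50, 100), seed = 2)
#' length(sw)
#' @export
generate_validation_sweep <- function(template_trials, sd_deg = 18.4,
                                      ratio_guess_to_target = c(1, 4),
                                      nt_grid = 0:100, seed = NULL) {
  if (is.null(template_trials) || nrow(template_trials) == 0L) {
    stop("`template_trials` must contain at least one trial", call. = FALSE)
  }
  stopifnot(length(ratio_guess_to_target) == 2L, all(ratio_guess_to_target >= 0),
            sum(ratio_guess_to_target) > 0, all(nt_grid >= 0), all(nt_grid <= 100))
  run <- function() {
    n <- nrow(template_trials)
    share_guess <- ratio_guess_to_target[1] / sum(ratio_guess_to_target)
    out <- lapply(nt_grid, function(nt) {
      p_nt <- nt / 100
      probs <- c(nontarget = p_nt,
                 uniform = (1 - p_nt) * share_guess,
                 target = (1 - p_nt) * (1 - share_guess))
      comp <- sample(names(probs), n, replace = TRUE, prob = probs)
      centre <- rep(NA_real_, n)
      centre[comp == "target"] <- template_trials$target_angle_deg[comp == "target"]
      idx_nt <- which(comp == "nontarget")
      if (length(idx_nt)) {
        centre[idx_nt] <- vapply(idx_nt, function(i) {
          d <- template_trials$distractor_angles_deg[[i]]
          d[sample.int(length(d), 1L)]
        }, numeric(1))
      }
      ang <- stats::runif(n, 0, 360)
      kerneled <- !is.na(centre)
      if (any(kerneled)) {
        ang[kerneled] <- wrap_angle(centre[kerneled] +
                                      rwrappednormal_deg(sum(kerneled), sd_deg))
      }
      tr <- template_trials
      tr$reported_identity <- tr$target_identity
      tr$identity_correct <- 1L
      tr$reported_angle_deg <- ang
      tr$component <- comp
      list(nt_true = nt, trials = tr)
    })
    structure(out, class = "validation_sweep")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
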