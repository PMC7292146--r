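# Trial CSV reader/writer and experiment run configurations.

trial_csv_cols <- c("subject_id", "trial_id", "layout", "n_items",
                    "target_identity", "target_angle_deg",
                    "distractor_angles_deg", "reported_identity",
                    "reported_angle_deg", "identity_correct")

#' Write trials to CSV
#'
#' Distractor angles are joined with semicolons into a single column so the
#' file is a plain rectangular CSV.
#'
#' @param trials Trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$distractor_angles_deg <- vapply(trials$distractor_angles_deg,
                                      function(d) paste(format(d, digits = 10, trim = TRUE),
                                                        collapse = ";"),
                                      character(1))
  out$component <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' Read trials from CSV
#'
#' Reads the documented trial schema, splits the semicolon-joined
#' distractor column back into a list column, canonicalizes all angles to
#' `[0, 360)`, and rejects malformed rows (wrong distractor count for
#' `n_items`, non-finite angles) with a warning naming their line numbers.
#' Missing required columns are an error listing them.
#'
#' @param path CSV path.
#' @return Trial tibble.
#' @export
read_trials <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(trial_csv_cols, names(raw))
  if (length(miss)) {
    stop("trial file is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dang <- lapply(strsplit(as.character(raw$distractor_angles_deg), ";",
                          fixed = TRUE),
                 function(s) suppressWarnings(as.numeric(s)))
  bad <- vapply(seq_len(nrow(raw)), function(i) {
    d <- dang[[i]]
    anyNA(d) || any(!is.finite(d)) ||
      length(d) != raw$n_items[i] - 1L ||
      !is.finite(raw$target_angle_deg[i]) ||
      (!is.na(raw$reported_angle_deg[i]) && !is.finite(raw$reported_angle_deg[i]))
  }, logical(1))
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
  }
  raw <- raw[!bad, , drop = FALSE]
  dang <- dang[!bad]
  out <- tibble::as_tibble(raw)
  out$target_angle_deg <- wrap_angle(out$target_angle_deg)
  out$reported_angle_deg <- ifelse(is.na(out$reported_angle_deg),
                                   NA_real_, out$reported_angle_deg %% 360)
  out$distractor_angles_deg <- lapply(dang, wrap_angle)
  if (!"target_slot" %in% names(out)) out$target_slot <- NA_integer_
  if (!"reported_slot" %in% names(out)) out$reported_slot <- NA_integer_
  out
}

#' Keep only trials with a correct identity report
#'
#' Location analyses condition on correct identity; this filter is applied
#' once, centrally, before any location fit.
#'
#' @param trials Trial tibble.
#' @return The correct-identity subset.
#' @export
filter_identity_correct <- function(trials) {
  trials[!is.na(trials$identity_correct) & trials$identity_correct == 1, ,
         drop = FALSE]
}

# Observed identity accuracy -> probability the identity was actually
# known, inverting obs = p + (1 - p) / alternatives.
p_known_from_observed <- function(obs, alternatives = 26) {
  correct_forced_choice(obs, 1 / alternatives)
}

# Fitted mixture weights (estimated on all correct-identity trials) ->
# intrinsic weights of the identity-known observer. Lucky identity guesses
# carry uniform locations, so the fitted uniform weight is contaminated:
# pU_fit = pU_known * (1 - L) + L and pNT_fit = pNT_known * (1 - L), with
# L the lucky-guess share of correct-identity reports. The presets invert
# this so that simulating and refitting reproduces the fitted values.
intrinsic_observer <- function(obs_accuracy, fitted_pnt, fitted_pu, kappa,
                               alternatives = 26) {
  p_known <- p_known_from_observed(obs_accuracy, alternatives)
  L <- lucky_guess_share(obs_accuracy, 1 / alternatives)
  pu <- max(0, (fitted_pu - L) / (1 - L))
  pnt <- fitted_pnt / (1 - L)
  observer_params(p_known, 1 - pu - pnt, pnt, pu, kappa = kappa)
}

#' Experiment run configuration
#'
#' Presets encode the design constants of the six experiment profiles: six
#' evenly spaced slots and 96 trials for the discrete letter-among-digits
#' displays (`"1a"`, `"1b"`); eight items and 144 trials for the first
#' continuous display (`"2a"`) and its colour-target variant (`"3"`); ten
#' items and 140 trials for the higher-load continuous displays (`"2b"`,
#' `"2c"`, the latter with 60 subjects). The bundled observer parameters
#' are the generative settings the simulator uses for that profile (the
#' identity-knowledge rate inverts the observed identity accuracy through
#' the guessing model; mixture weights and concentration follow the fitted
#' values for that profile).
#'
#' @param profile One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"2c"`, `"3"`.
#' @param n_subjects,n_trials Optional overrides of the preset sizes.
#' @param observer Optional [observer_params()] override.
#' @param n_starts Restarts for mixture fits.
#' @param n_boot Bootstrap resamples in the pipeline (0 disables the
#'   bootstrap stage).
#' @return A `run_config` list.
#' @examples
#' experiment_config("2c")
#' experiment_config("2a", n_subjects = 5, n_trials = 40)
#' @export
experiment_config <- function(profile = c("1a", "1b", "2a", "2b", "2c", "3"),
                              n_subjects = NULL, n_trials = NULL,
                              observer = NULL, n_starts = 10L, n_boot = 0L) {
  profile <- match.arg(profile)
  preset <- switch(profile,
    "1a" = list(display = display_config(6, "discrete_slots"),
                n_trials = 96L, n_subjects = 20L,
                observer = observer_params(p_known_from_observed(0.70),
                                           0.635, 0.10, 0.265, sd_deg = 15)),
    "1b" = list(display = display_config(6, "discrete_slots"),
                n_trials = 96L, n_subjects = 20L,
                observer = observer_params(p_known_from_observed(0.627),
                                           0.545, 0.12, 0.335, sd_deg = 15)),
    "2a" = list(display = display_config(8, "continuous"),
                n_trials = 144L, n_subjects = 20L,
                observer = intrinsic_observer(0.455, 0.1382, 0.1046,
                                              kappa = 12.37)),
    "2b" = list(display = display_config(10, "continuous"),
                n_trials = 140L, n_subjects = 20L,
                observer = intrinsic_observer(0.409, 0.1304, 0.1546,
                                              kappa = 11.78)),
    "2c" = list(display = display_config(10, "continuous"),
                n_trials = 140L, n_subjects = 60L,
                observer = intrinsic_observer(0.354, 0.1657, 0.1646,
                                              kappa = 10.22)),
    "3" = list(display = display_config(8, "continuous"),
               n_trials = 144L, n_subjects = 20L,
               observer = intrinsic_observer(0.27, 0.0562, 0.0996,
                                             kappa = 19.79))
  )
  structure(list(profile = profile,
                 display = preset$display,
                 n_trials = as.integer(n_trials %||% preset$n_trials),
                 n_subjects = as.integer(n_subjects %||% preset$n_subjects),
                 observer = observer %||% preset$observer,
                 chance_identity = 1 / preset$display$alphabet_size,
                 chance_location = if (preset$display$layout == "discrete_slots")
                   1 / preset$display$n_items else NA_real_,
                 n_starts = as.integer(n_starts),
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: profile %s, %d subjects x %d trials, %d items (%s)\n",
              x$profile, x$n_subjects, x$n_trials, x$display$n_items,
              x$display$layout))
  invisible(x)
}
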