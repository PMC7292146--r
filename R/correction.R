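# Forced-choice guessing corrections and discrete-display descriptives.
#
# The correction chain assumes the standard high-threshold guessing model:
# with probability `true` the observer knows the answer, otherwise a
# uniform guess over the alternatives is correct with probability `chance`,
# so observed = true + (1 - true) * chance. Solving for `true` gives
# (observed - chance) / (1 - chance). The chain below (identity correction,
# lucky-guess share, location correction, and their combination) is the
# unique simple composition of that model that reproduces every published
# step of the 6-slot experiment's analysis; it was reconstructed from those
# printed values rather than taken from a stated formula.

#' Correct a forced-choice accuracy for lucky guessing
#'
#' `true = (observed - chance) / (1 - chance)`, clamped at 0 when the
#' observed accuracy is at or below chance.
#'
#' @param obs Observed proportion(s) correct, in `[0, 1]`.
#' @param chance Chance level(s), `0 <= chance < 1` (e.g. `1/26` for a
#'   26-letter identity report, `1/6` for a 6-slot location report).
#' @return Estimated true proportion(s) known.
#' @examples
#' correct_forced_choice(0.70, 1 / 26)   # 0.688
#' correct_forced_choice(0.627, 1 / 26)  # 0.6121
#' @export
correct_forced_choice <- function(obs, chance) {
  if (any(!is.finite(chance)) || any(chance < 0) || any(chance >= 1)) {
    stop("`chance` must satisfy 0 <= chance < 1", call. = FALSE)
  }
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs > 1)) {
    stop("`obs` must be a proportion in [0, 1]", call. = FALSE)
  }
  pmax(0, (obs - chance) / (1 - chance))
}

#' Share of correct reports attributable to lucky guessing
#'
#' Under the guessing model, a fraction `(1 - true) * chance` of all trials
#' are lucky-guess hits; as a share of the observed correct reports that is
#' `(1 - true) * chance / obs`.
#'
#' @inheritParams correct_forced_choice
#' @return Proportion(s) of correct reports that are lucky guesses.
#' @examples
#' lucky_guess_share(0.70, 1 / 26)  # ~0.017
#' lucky_guess_share(1.0, 1 / 26)   # 0: a perfect observer never guesses
#' @export
lucky_guess_share <- function(obs, chance) {
  if (any(!is.finite(obs)) || any(obs <= 0)) {
    stop("`obs` must be > 0 to define a share of correct reports",
         call. = FALSE)
  }
  (1 - correct_forced_choice(obs, chance)) * chance / obs
}

#' Combined identity + location guessing correction
#'
#' Builds the full correction chain for conditional location accuracy among
#' correct-identity trials: first the location accuracy is corrected for
#' location guessing over `chance_location` alternatives, then the share of
#' "correct identity" trials that were lucky identity guesses (whose
#' location reports carry no information) is subtracted. The complement of
#' the doubly corrected accuracy is the true location-error rate among
#' genuinely identified targets.
#'
#' @param loc_given_id_obs Observed location accuracy on correct-identity
#'   trials.
#' @param id_obs Observed identity accuracy.
#' @param chance_location Location chance level (default `1/6`, six slots).
#' @param chance_identity Identity chance level (default `1/26`).
#' @return A `correction_table` list: `id_obs`, `id_true`, `lucky_share`,
#'   `loc_given_id_obs`, `loc_corrected`, `loc_both_corrected`,
#'   `true_location_error`.
#' @examples
#' combined_location_error(0.71, 0.70)
#' @export
combined_location_error <- function(loc_given_id_obs, id_obs,
                                    chance_location = 1 / 6,
                                    chance_identity = 1 / 26) {
  loc_corrected <- correct_forced_choice(loc_given_id_obs, chance_location)
  id_true <- correct_forced_choice(id_obs, chance_identity)
  lucky <- lucky_guess_share(id_obs, chance_identity)
  loc_both <- loc_corrected - lucky
  structure(list(id_obs = id_obs,
                 id_true = id_true,
                 lucky_share = lucky,
                 loc_given_id_obs = loc_given_id_obs,
                 loc_corrected = loc_corrected,
                 loc_both_corrected = loc_both,
                 true_location_error = 1 - loc_both),
            class = "correction_table")
}

# Percent with one decimal, rounding half away from zero (matching how the
# published chain is displayed).
format_pct <- function(x, digits = 1) {
  p <- x * 100
  scale <- 10^digits
  sprintf(paste0("%.", digits, "f%%"), sign(p) * floor(abs(p) * scale + 0.5) / scale)
}

#' @export
print.correction_table <- function(x, ...) {
  cat("Guessing-corrected performance (correct-identity trials)\n")
  cat(sprintf("  identity: observed %s, true %s (lucky-guess share %s)\n",
              format_pct(x$id_obs), format_pct(x$id_true),
              format_pct(x$lucky_share)))
  cat(sprintf("  location | identity: observed %s\n",
              format_pct(x$loc_given_id_obs)))
  cat(sprintf("    after location-guessing correction: %s\n",
              format_pct(x$loc_corrected)))
  cat(sprintf("    after both corrections:             %s\n",
              format_pct(x$loc_both_corrected)))
  cat(sprintf("  true location-error rate:             %s\n",
              format_pct(x$true_location_error)))
  invisible(x)
}

#' Ratio of adjacent to adjacent-plus-distant slot reports
#'
#' For 6-slot displays: among erroneous location reports, compares the two
#' slots adjacent to the target with the two slots flanking the opposite
#' slot (the directly opposite slot is excluded). A ratio near 0.5 means
#' errors carry no coarse-grained (correct-half) information.
#'
#' @param adjacent,distant Report frequencies (any common unit).
#' @return `adjacent / (adjacent + distant)`, `NA` if both are zero.
#' @examples
#' adjacent_distant_ratio(14, 10.5)  # ~0.571
#' adjacent_distant_ratio(16, 14)    # ~0.533
#' @export
adjacent_distant_ratio <- function(adjacent, distant) {
  tot <- adjacent + distant
  ifelse(tot > 0, adjacent / tot, NA_real_)
}

#' Descriptive summary of a discrete-slot experiment
#'
#' Computes identity and location accuracy, the two conditional accuracies,
#' and — within correct-identity trials — the report frequencies at the
#' target slot, the two adjacent slots, and the two distant slots (the
#' slot directly opposite the target is excluded), plus the
#' adjacent/(adjacent+distant) ratio probing coarse-grained location
#' memory.
#'
#' @param trials Trial tibble from a discrete-slot layout with
#'   `target_slot`, `reported_slot`, `identity_correct` filled.
#' @return A `discrete_summary` list.
#' @export
summarize_discrete <- function(trials) {
  need <- c("target_slot", "reported_slot", "identity_correct")
  if (!all(need %in% names(trials)) ||
      anyNA(trials$target_slot) || anyNA(trials$reported_slot)) {
    stop("`trials` must be discrete-slot trials with slot reports present",
         call. = FALSE)
  }
  if (!all(trials$layout == "discrete_slots")) {
    stop("`summarize_discrete()` only applies to discrete-slot layouts",
         call. = FALSE)
  }
  k <- trials$n_items[1]
  id_acc <- mean(trials$identity_correct == 1)
  loc_ok <- trials$reported_slot == trials$target_slot
  loc_acc <- mean(loc_ok)
  idc <- trials$identity_correct == 1
  p_id_given_loc <- if (any(loc_ok)) mean(idc[loc_ok]) else NA_real_
  p_loc_given_id <- if (any(idc)) mean(loc_ok[idc]) else NA_real_
  # slot offsets within correct-identity trials; 6-slot geometry:
  # +-1 adjacent, +-2 distant, +3 opposite (ignored)
  off <- ((trials$reported_slot - trials$target_slot) %% k)[idc]
  freq_target <- mean(off == 0)
  freq_adjacent <- mean(off %in% c(1, k - 1))
  freq_distant <- mean(off %in% c(2, k - 2))
  structure(list(n_trials = nrow(trials),
                 identity_accuracy = id_acc,
                 location_accuracy = loc_acc,
                 p_identity_given_location = p_id_given_loc,
                 p_location_given_identity = p_loc_given_id,
                 freq_target = freq_target,
                 freq_adjacent = freq_adjacent,
                 freq_distant = freq_distant,
                 adjacent_ratio = adjacent_distant_ratio(freq_adjacent,
                                                         freq_distant)),
            class = "discrete_summary")
}

#' @export
print.discrete_summary <- function(x, ...) {
  cat(sprintf("Discrete-slot summary (%d trials)\n", x$n_trials))
  cat(sprintf("  identity accuracy: %s   location accuracy: %s\n",
              format_pct(x$identity_accuracy), format_pct(x$location_accuracy)))
  cat(sprintf("  P(identity | location): %s   P(location | identity): %s\n",
              format_pct(x$p_identity_given_location),
              format_pct(x$p_location_given_identity)))
  cat(sprintf("  correct-identity reports at target %s, adjacent %s, distant %s\n",
              format_pct(x$freq_target), format_pct(x$freq_adjacent),
              format_pct(x$freq_distant)))
  if (is.na(x$adjacent_ratio)) {
    cat("  adjacent ratio: undefined (no erroneous flanking reports)\n")
  } else {
    cat(sprintf("  adjacent ratio adj/(adj+dist): %.3f\n", x$adjacent_ratio))
  }
  invisible(x)
}
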