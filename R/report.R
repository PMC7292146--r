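# Polar error histograms and the end-to-end pipeline.

#' Log-scaled polar histogram of location-report errors
#'
#' Bins signed errors into `n_bins` equal bins centred on 0 degrees (the
#' target-aligned frame) and draws a polar histogram with a
#' `log10(count + 1)` radial axis, which makes low-count bins visible next
#' to the central peak. The binned counts are returned alongside the plot
#' so reports and tests can use the numbers rather than the image.
#'
#' @param errors Signed errors in degrees (from [report_errors()]).
#' @param n_bins Number of angular bins (default 36, i.e. 10-degree bins).
#' @return A `polar_histogram` list: `counts` (tibble `bin_center`,
#'   `count`, `log_count`; counts sum to `length(errors)`) and `plot`
#'   (a ggplot).
#' @examples
#' h <- polar_log_histogram(rnorm(500, 0, 20))
#' sum(h$counts$count)
#' @export
polar_log_histogram <- function(errors, n_bins = 36L) {
  if (length(errors) == 0L) stop("no errors to bin", call. = FALSE)
  if (anyNA(errors) || any(!is.finite(errors))) {
    stop("errors must be finite", call. = FALSE)
  }
  width <- 360 / n_bins
  idx <- round(errors / width) %% n_bins        # bin 0 centred on 0 degrees
  counts <- tabulate(idx + 1L, nbins = n_bins)
  centre <- (seq_len(n_bins) - 1L) * width
  centre <- ifelse(centre > 180, centre - 360, centre)
  tab <- tibble::tibble(bin_center = centre, count = counts,
                        log_count = log10(counts + 1))
  tab <- tab[order(tab$bin_center), ]
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin_center,
                                         y = .data$log_count)) +
    ggplot2::geom_col(width = width, fill = "grey30") +
    ggplot2::coord_polar(start = pi) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 135, by = 45)) +
    ggplot2::labs(x = "error relative to target (deg)",
                  y = "log10(count + 1)") +
    ggplot2::theme_minimal()
  structure(list(counts = tab, plot = p), class = "polar_histogram")
}

#' @export
print.polar_histogram <- function(x, ...) {
  cat(sprintf("Polar error histogram: %d bins, %d responses\n",
              nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

# Per-subject mixture fits on identity-correct trials -> tidy tibble.
fit_per_subject <- function(id_trials, n_starts) {
  subs <- sort(unique(id_trials$subject_id))
  rows <- lapply(subs, function(s) {
    fit <- fit_mixture(id_trials[id_trials$subject_id == s, , drop = FALSE],
                       n_starts = n_starts)
    p <- fit$params
    tibble::tibble(
      subject_id = s, n_trials = fit$n_trials,
      kappa = if (is.null(p)) NA_real_ else p$kappa,
      sd_deg = if (is.null(p)) NA_real_ else k_to_sd(p$kappa),
      p_target = if (is.null(p)) NA_real_ else p$p_target,
      p_nontarget = if (is.null(p)) NA_real_ else p$p_nontarget,
      p_uniform = if (is.null(p)) NA_real_ else p$p_uniform,
      loglik = fit$log_likelihood,
      converged = fit_usable(fit))
  })
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline for one experiment profile
#'
#' Simulates the experiment (or ingests provided trials), filters to
#' correct-identity trials, and then: for continuous layouts fits the
#' mixture model pooled and per subject, compares each subject's fitted
#' uniform weight against their estimated identity lucky-guess rate
#' (paired t-test + Bayes factor), and optionally bootstraps the pooled
#' swap weight at the trial level; for discrete layouts computes the slot
#' descriptives and the full guessing-correction chain, and optionally
#' bootstraps the corrected location-error rate at the subject level. The
#' binned polar histogram of identity-correct errors is always produced.
#'
#' All randomness flows from `seed`: two runs with the same config and
#' seed write byte-identical reports.
#'
#' @param config A [experiment_config()].
#' @param seed Integer seed.
#' @param trials Optional pre-loaded trial tibble (skips simulation).
#' @param out_dir Optional directory; when given, writes `trials.csv`,
#'   `fits.csv` (continuous), `corrections.yaml`, `inference.yaml`
#'   (continuous), `bins.csv` and `log.yaml`.
#' @return A `pipeline_result` bundle (invisibly the written paths in
#'   `$paths`).
#' @export
run_pipeline <- function(config, seed = 1L, trials = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  withr::with_seed(seed, {
    stage <- "simulate"
    res <- tryCatch({
      if (is.null(trials)) {
        trials <- generate_displays(config$display, config$n_trials,
                                    config$n_subjects)
        trials <- simulate_responses(trials, config$observer, config$display)
      }
      stage <- "filter"
      id_trials <- filter_identity_correct(trials)
      if (nrow(id_trials) == 0L) stop("no correct-identity trials")
      id_obs <- mean(trials$identity_correct == 1)
      discrete <- config$display$layout == "discrete_slots"

      stage <- "fit"
      pooled_fit <- NULL
      fits <- NULL
      if (!discrete) {
        pooled_fit <- fit_mixture(id_trials, n_starts = config$n_starts)
        fits <- fit_per_subject(id_trials, config$n_starts)
      }

      stage <- "correct"
      summary_discrete <- NULL
      correction <- NULL
      if (discrete) {
        summary_discrete <- summarize_discrete(trials)
        correction <- combined_location_error(
          summary_discrete$p_location_given_identity, id_obs,
          config$chance_location, config$chance_identity)
      } else {
        correction <- list(
          id_obs = id_obs,
          id_true = correct_forced_choice(id_obs, config$chance_identity),
          lucky_share = lucky_guess_share(id_obs, config$chance_identity))
      }

      stage <- "bootstrap"
      boot <- NULL
      if (config$n_boot > 0) {
        boot <- if (discrete) {
          bootstrap_ci(trials, function(d) {
            s <- summarize_discrete(d)
            combined_location_error(s$p_location_given_identity,
                                    mean(d$identity_correct == 1),
                                    config$chance_location,
                                    config$chance_identity)$true_location_error
          }, scheme = "subjects", n_boot = config$n_boot)
        } else {
          bootstrap_ci(id_trials, function(d) {
            f <- fit_mixture(d, n_starts = max(2L, config$n_starts %/% 2L))
            if (is.null(f$params)) stop("fit failed")
            f$params$p_nontarget
          }, scheme = "trials", n_boot = config$n_boot)
        }
      }

      stage <- "infer"
      inference <- NULL
      if (!discrete && !is.null(fits) && nrow(fits) >= 3L) {
        acc <- vapply(split(trials$identity_correct, trials$subject_id), mean,
                      numeric(1))
        acc <- acc[as.character(fits$subject_id)]
        guess <- lucky_guess_share(pmax(acc, 1e-6), config$chance_identity)
        if (sum(fits$converged) >= 3L) {
          inference <- paired_t_and_bf(fits$p_uniform, unname(guess),
                                       include = fits$converged)
        }
      }

      stage <- "plot"
      hist <- polar_log_histogram(report_errors(id_trials))

      list(trials = trials, id_trials = id_trials, pooled_fit = pooled_fit,
           fits = fits, summary_discrete = summary_discrete,
           correction = correction, bootstrap = boot, inference = inference,
           histogram = hist)
    }, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })

    res$config <- config
    res$seed <- seed
    res$paths <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      pth <- function(f) file.path(out_dir, f)
      write_trials(res$trials, pth("trials.csv"))
      readr::write_csv(res$histogram$counts, pth("bins.csv"))
      written <- c("trials.csv", "bins.csv")
      if (!is.null(res$fits)) {
        readr::write_csv(res$fits, pth("fits.csv"))
        written <- c(written, "fits.csv")
      }
      corr <- lapply(unclass(res$correction), function(v) unname(v))
      if (!is.null(res$summary_discrete)) {
        corr$discrete <- lapply(unclass(res$summary_discrete), unname)
      }
      if (!is.null(res$bootstrap)) {
        corr$bootstrap <- res$bootstrap[c("point", "lower", "upper", "level",
                                          "n_boot", "scheme")]
      }
      yaml::write_yaml(corr, pth("corrections.yaml"))
      written <- c(written, "corrections.yaml")
      if (!is.null(res$inference)) {
        yaml::write_yaml(unclass(res$inference), pth("inference.yaml"))
        written <- c(written, "inference.yaml")
      }
      yaml::write_yaml(list(package = "locbind",
                            version = as.character(utils::packageVersion("locbind")),
                            r_version = paste(R.version$major, R.version$minor,
                                              sep = "."),
                            profile = config$profile, seed = seed,
                            n_subjects = config$n_subjects,
                            n_trials = config$n_trials,
                            n_starts = config$n_starts,
                            n_boot = config$n_boot),
                      pth("log.yaml"))
      written <- c(written, "log.yaml")
      res$paths <- file.path(out_dir, written)
    }
    class(res) <- "pipeline_result"
    res
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: profile %s, seed %d, %d trials (%d identity-correct)\n",
              x$config$profile, x$seed, nrow(x$trials), nrow(x$id_trials)))
  if (!is.null(x$pooled_fit)) print(x$pooled_fit)
  if (!is.null(x$summary_discrete)) print(x$summary_discrete)
  if (!is.null(x$inference)) print(x$inference)
  invisible(x)
}
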