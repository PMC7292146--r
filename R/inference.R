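# Percentile bootstrap, recruitment power analysis, paired t-test with a
# default JZS Bayes factor, and the swap-recovery validation study.

#' Percentile bootstrap confidence interval
#'
#' Resamples units with replacement `n_boot` times, recomputes the
#' statistic on each resample, and takes the empirical `(1 - level)/2` and
#' `(1 + level)/2` quantiles. Units are either subjects (rows sharing a
#' `subject_id` are resampled together) or trials/rows; for a plain vector
#' the elements are the units.
#'
#' @param data A numeric vector, or a tibble/data frame.
#' @param stat_fn Function mapping a resample of `data` to a single number.
#' @param scheme `"subjects"` (requires a `subject_id` column) or
#'   `"trials"`.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A `bootstrap_result`: `point`, `lower`, `upper`, `level`,
#'   `n_boot`, `scheme`, `n_failed`.
#' @examples
#' bootstrap_ci(rnorm(50), mean, scheme = "trials", n_boot = 200, seed = 1)
#' @export
bootstrap_ci <- function(data, stat_fn, scheme = c("subjects", "trials"),
                         n_boot = 500L, level = 0.95, seed = NULL) {
  scheme <- match.arg(scheme)
  is_tab <- is.data.frame(data)
  n_units <- if (is_tab && scheme == "subjects") {
    length(unique(data$subject_id))
  } else if (is_tab) nrow(data) else length(data)
  if (n_units < 2L) stop("need at least 2 resampling units", call. = FALSE)
  resample <- if (is_tab && scheme == "subjects") {
    groups <- split(seq_len(nrow(data)), data$subject_id)
    function() {
      take <- sample(length(groups), replace = TRUE)
      data[unlist(groups[take], use.names = FALSE), , drop = FALSE]
    }
  } else if (is_tab) {
    function() data[sample(nrow(data), replace = TRUE), , drop = FALSE]
  } else {
    function() sample(data, replace = TRUE)
  }
  run <- function() {
    point <- tryCatch(as.numeric(stat_fn(data)), error = function(e) NA_real_)
    stats_b <- vapply(seq_len(n_boot), function(i) {
      tryCatch(as.numeric(stat_fn(resample())), error = function(e) NA_real_)
    }, numeric(1))
    n_failed <- sum(is.na(stats_b))
    if (is.na(point) || n_failed > 0.2 * n_boot) {
      stop(sprintf("statistic failed on %d of %d resamples%s", n_failed, n_boot,
                   if (is.na(point)) " (and on the full data)" else ""),
           call. = FALSE)
    }
    qs <- stats::quantile(stats_b, c((1 - level) / 2, (1 + level) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(list(point = point, lower = qs[1], upper = qs[2], level = level,
                   n_boot = n_boot, scheme = scheme, n_failed = n_failed),
              class = "bootstrap_result")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Percentile bootstrap (%s, %d resamples%s)\n", x$scheme,
              x$n_boot,
              if (x$n_failed > 0) sprintf(", %d failed", x$n_failed) else ""))
  cat(sprintf("  point %.4f, %d%% CI [%.4f, %.4f]\n", x$point,
              round(x$level * 100), x$lower, x$upper))
  invisible(x)
}

#' Recruitment power analysis by nested resampling
#'
#' Emulates a pilot-based sample-size justification: from a pool of
#' per-subject statistics (e.g. corrected location-error rates), draw
#' `n_outer` pseudo-samples of each candidate size with replacement; for
#' each pseudo-sample, a percentile bootstrap (`n_inner` resamples) of the
#' mean gives a confidence interval, and the proportion of pseudo-samples
#' whose interval excludes zero is reported per size.
#'
#' @param pool Numeric vector of per-subject statistics (length >= 5).
#' @param sizes Candidate sample sizes.
#' @param n_outer Pseudo-samples per size.
#' @param n_inner Bootstrap resamples per pseudo-sample.
#' @param level Confidence level of the inner interval.
#' @param seed Optional integer seed.
#' @return Tibble with `size` and `prop_excluding_zero`.
#' @examples
#' power_analysis(rnorm(20, 0.3, 0.15), seed = 1)
#' @export
power_analysis <- function(pool, sizes = c(5, 10, 20), n_outer = 100L,
                           n_inner = 100L, level = 0.95, seed = NULL) {
  if (!is.numeric(pool) || length(pool) < 5L) {
    stop("`pool` must hold at least 5 per-subject statistics", call. = FALSE)
  }
  probs <- c((1 - level) / 2, (1 + level) / 2)
  run <- function() {
    prop <- vapply(sizes, function(sz) {
      excl <- vapply(seq_len(n_outer), function(i) {
        s <- sample(pool, sz, replace = TRUE)
        boots <- colMeans(matrix(sample(s, sz * n_inner, replace = TRUE), sz))
        ci <- stats::quantile(boots, probs, names = FALSE)
        ci[1] > 0 || ci[2] < 0
      }, logical(1))
      mean(excl)
    }, numeric(1))
    tibble::tibble(size = as.integer(sizes), prop_excluding_zero = prop)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default (JZS) Bayes factor for a one-sample / paired t statistic
#'
#' Jeffreys-Zellner-Siow Bayes factor comparing H1 (standardised effect
#' size with a Cauchy(0, `rscale`) prior) against H0 (effect 0), computed
#' by numerical integration of the noncentral-t likelihood over the prior:
#' `BF10 = \int t_df(t; ncp = delta * sqrt(n)) Cauchy(delta; 0, r) d delta
#' / t_df(t; ncp = 0)`. The default scale `sqrt(2)/2` is the conventional
#' default for paired designs.
#'
#' @param t Observed t statistic.
#' @param n Number of (paired) observations; `df = n - 1`.
#' @param rscale Cauchy prior scale on the standardised effect size.
#' @return The Bayes factor BF10 (evidence for a nonzero effect).
#' @examples
#' jzs_bf(-2.38, 20)  # moderate evidence for an effect
#' jzs_bf(0.1, 20)    # < 1: data favour the null
#' @export
jzs_bf <- function(t, n, rscale = sqrt(2) / 2) {
  stopifnot(is.finite(t), n >= 2)
  df <- n - 1
  # dt() warns about reduced precision at extreme noncentrality; those tail
  # contributions are negligible here
  integrand <- function(delta) {
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, rscale)
  }
  num <- stats::integrate(integrand, -Inf, 0, rel.tol = 1e-9)$value +
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  num / stats::dt(t, df)
}

#' Paired t-test with a default Bayes factor
#'
#' Two-tailed paired t-test comparing two per-subject vectors (typically
#' the fitted uniform-component weight against the estimated identity
#' lucky-guess rate), with the JZS Bayes factor for the same contrast.
#' Subjects whose mixture fit was unusable can be excluded first via
#' `include`; the degrees of freedom shrink accordingly.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param include Optional logical vector marking subjects to keep (e.g.
#'   `vapply(fits, fit_usable, logical(1))`).
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return An `inference_result`: `t_stat`, `df`, `p_value`, `bf10`,
#'   `n_subjects`, `n_excluded`, `mean_x`, `mean_y`.
#' @examples
#' set.seed(1)
#' paired_t_and_bf(rnorm(20, 0.15, 0.1), rnorm(20, 0.06, 0.04))
#' @export
paired_t_and_bf <- function(x, y, include = NULL, rscale = sqrt(2) / 2) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  n_total <- length(x)
  if (!is.null(include)) {
    stopifnot(length(include) == n_total)
    x <- x[include]
    y <- y[include]
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 usable pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("paired differences have zero variance; t is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 bf10 = jzs_bf(unname(tt$statistic), n, rscale),
                 n_subjects = n, n_excluded = n_total - n,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.2f, p = %.4f, BF10 = %.2f\n",
              x$df, x$t_stat, x$p_value, x$bf10))
  cat(sprintf("  means: %.4f vs %.4f over %d subjects (%d excluded)\n",
              x$mean_x, x$mean_y, x$n_subjects, x$n_excluded))
  invisible(x)
}

#' Swap-rate recovery study over a validation sweep
#'
#' Fits the mixture model to each dataset of a
#' [generate_validation_sweep()] and compares the estimated swap
#' probability with the generating one: the recovery table, the Pearson
#' correlation, and the least-squares slope and intercept of estimated on
#' actual swap percentage. Non-converged fits are recorded, not fatal.
#'
#' @param sweep A `validation_sweep`.
#' @param ... Passed to [fit_mixture()] (e.g. `n_starts`, `seed`).
#' @return An `nt_recovery` list: `table` (tibble `nt_true`, `nt_est`,
#'   `converged`), `pearson_r`, `slope`, `intercept`, `n_failed`.
#' @export
nt_recovery_study <- function(sweep, ...) {
  stopifnot(inherits(sweep, "validation_sweep"))
  rows <- lapply(sweep, function(el) {
    fit <- fit_mixture(el$trials, ...)
    tibble::tibble(
      nt_true = el$nt_true,
      nt_est = if (!is.null(fit$params)) 100 * fit$params$p_nontarget else NA_real_,
      converged = fit$converged)
  })
  tab <- dplyr::bind_rows(rows)
  ok <- !is.na(tab$nt_est)
  r <- stats::cor(tab$nt_true[ok], tab$nt_est[ok])
  coefs <- stats::coef(stats::lm(nt_est ~ nt_true, data = tab[ok, ]))
  structure(list(table = tab, pearson_r = r,
                 slope = unname(coefs[2]), intercept = unname(coefs[1]),
                 n_failed = sum(!ok)),
            class = "nt_recovery")
}

#' @export
print.nt_recovery <- function(x, ...) {
  cat(sprintf("Swap-rate recovery over %d datasets (%d failed fits)\n",
              nrow(x$table), x$n_failed))
  cat(sprintf("  estimated vs actual: r = %.3f, slope = %.3f, intercept = %.2f\n",
              x$pearson_r, x$slope, x$intercept))
  invisible(x)
}
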