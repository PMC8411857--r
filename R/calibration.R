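## Control-cohort calibration of the meaningful-weight threshold: decompose a
## normal cohort against the disease model, form per-archetype 95% CIs for the
## mean weight and the mean weight change, and derive the smallest integer
## percentage that clears every abnormal archetype's upper limit.

#' Decompose a control cohort against a fitted model
#'
#' @param controls a `vf_cohort` of normal eyes (repeated visits).
#' @param model an `archetype_model`.
#' @return data.frame with `eye_id`, `visit`, and one percent-weight column
#'   per archetype.
#' @export
decompose_controls <- function(controls, model) {
  if (!length(controls)) stop("empty control cohort")
  d <- decompose(model, controls)
  cbind(d$meta[, c("eye_id", "visit")], as.data.frame(d$weights))
}

#' Per-archetype weight statistics across control eyes
#'
#' Each eye's weights are first averaged over its visits; the mean and its
#' 95% confidence interval (normal approximation, mean +/- 1.96 SE) are then
#' taken across eyes, so repeated testing of one eye does not shrink the
#' interval.  The weight change for an eye is the mean absolute difference
#' between each follow-up visit's weight and that eye's first (baseline)
#' visit; `change` statistics are across eyes likewise.  A seeded bootstrap
#' (percentile, 2000 resamples of eyes) is available as an alternative CI.
#'
#' @param table per-eye weight table from [decompose_controls()].
#' @param model the `archetype_model` the table was computed against (used to
#'   identify normal archetypes by average TD).
#' @param normal_td_cutoff archetypes with average TD at or above this value
#'   (dB) count as normal and are excluded from the abnormal maximum
#'   (default -1).
#' @param normal_ids optional explicit character vector of normal archetype
#'   names overriding the cutoff.
#' @param ci_method `"normal"` (default) or `"bootstrap"`.
#' @param boot_n,boot_seed bootstrap resamples (default 2000) and seed.
#' @return object of class `control_calibration`: list with `stats` (per
#'   archetype: mean weight, CI, mean absolute change, change CI, is_normal),
#'   `max_abnormal_upper` (percent, pooled over weight and change upper
#'   limits of abnormal archetypes), `n_eyes`.
#' @export
weight_statistics <- function(table, model, normal_td_cutoff = -1,
                              normal_ids = NULL,
                              ci_method = c("normal", "bootstrap"),
                              boot_n = 2000L, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  at_names <- rownames(model$archetypes)
  eyes <- unique(table$eye_id)
  if (length(eyes) < 2L) stop("confidence intervals need at least 2 eyes")

  per_eye_mean <- matrix(NA_real_, length(eyes), length(at_names),
                         dimnames = list(eyes, at_names))
  per_eye_change <- matrix(NA_real_, length(eyes), length(at_names),
                           dimnames = list(eyes, at_names))
  for (i in seq_along(eyes)) {
    w <- as.matrix(table[table$eye_id == eyes[i], at_names, drop = FALSE])
    per_eye_mean[i, ] <- colMeans(w)
    if (nrow(w) > 1L) {
      base <- w[1L, ]
      per_eye_change[i, ] <- colMeans(abs(w[-1L, , drop = FALSE] -
                                            matrix(base, nrow(w) - 1L,
                                                   ncol(w), byrow = TRUE)))
    }
  }
  has_change <- stats::complete.cases(per_eye_change)
  if (!any(has_change)) per_eye_change <- NULL

  ci_of <- function(m) {
    mu <- colMeans(m)
    if (ci_method == "normal") {
      se <- apply(m, 2, sd) / sqrt(nrow(m))
      list(mean = mu, lo = mu - 1.96 * se, hi = mu + 1.96 * se)
    } else {
      set.seed(boot_seed)
      boot <- replicate(boot_n,
                        colMeans(m[sample.int(nrow(m), replace = TRUE), ,
                                   drop = FALSE]))
      list(mean = mu,
           lo = apply(boot, 1, quantile, 0.025),
           hi = apply(boot, 1, quantile, 0.975))
    }
  }

  wci <- ci_of(per_eye_mean)
  cci <- if (!is.null(per_eye_change)) {
    ci_of(per_eye_change[has_change, , drop = FALSE])
  } else {
    list(mean = rep(NA_real_, length(at_names)),
         lo = rep(NA_real_, length(at_names)),
         hi = rep(NA_real_, length(at_names)))
  }

  is_normal <- if (!is.null(normal_ids)) {
    at_names %in% normal_ids
  } else {
    model$average_td >= normal_td_cutoff
  }
  if (!any(is_normal)) {
    # no archetype clears the cutoff (can happen for models fit to purely
    # abnormal cohorts): treat the least abnormal one as the normal reference
    is_normal <- seq_along(at_names) == which.max(model$average_td)
    warning("no archetype has average TD >= ", normal_td_cutoff,
            " dB; using the highest-average-TD archetype (",
            at_names[is_normal], ") as the normal reference")
  }
  stats_df <- data.frame(
    archetype = at_names,
    mean_weight = wci$mean, weight_ci_lo = wci$lo, weight_ci_hi = wci$hi,
    mean_abs_change = cci$mean, change_ci_lo = cci$lo, change_ci_hi = cci$hi,
    is_normal = as.logical(is_normal),
    row.names = NULL
  )
  upper_pool <- c(stats_df$weight_ci_hi[!stats_df$is_normal],
                  stats_df$change_ci_hi[!stats_df$is_normal])
  upper_pool <- upper_pool[is.finite(upper_pool)]
  structure(list(
    stats = stats_df,
    max_abnormal_upper = if (length(upper_pool)) max(upper_pool) else NA_real_,
    n_eyes = length(eyes),
    ci_method = ci_method,
    threshold = NA_real_,
    margin = NA_real_
  ), class = "control_calibration")
}

#' Derive the meaningful-weight threshold
#'
#' The smallest integer percentage exceeding every abnormal archetype's upper
#' 95% limit, plus a safety margin guarding against multiplicity across the
#' archetypes: `ceiling(max_abnormal_upper) + margin`.  With the published
#' control inputs (largest abnormal upper limit 7%) and the default margin of
#' 2 points this yields the canonical threshold of 9%.
#'
#' @param cal a `control_calibration` from [weight_statistics()].
#' @param margin nonnegative safety margin in percentage points (default 2).
#' @return the updated `control_calibration` with `threshold` and `margin`
#'   set; the threshold itself is in `$threshold` (percent).
#' @export
derive_threshold <- function(cal, margin = 2) {
  stopifnot(inherits(cal, "control_calibration"))
  if (margin < 0) stop("margin must be nonnegative")
  if (!is.finite(cal$max_abnormal_upper)) {
    stop("max_abnormal_upper is undefined (no abnormal archetypes?)")
  }
  cal$margin <- margin
  cal$threshold <- ceiling(cal$max_abnormal_upper) + margin
  cal
}

#' One-shot control calibration
#'
#' Convenience wrapper: [decompose_controls()] then [weight_statistics()] then
#' [derive_threshold()].
#'
#' @inheritParams decompose_controls
#' @inheritParams weight_statistics
#' @inheritParams derive_threshold
#' @return a `control_calibration` with the threshold set.
#' @export
calibrate_controls <- function(controls, model, margin = 2,
                               normal_td_cutoff = -1, normal_ids = NULL,
                               ci_method = c("normal", "bootstrap")) {
  tab <- decompose_controls(controls, model)
  cal <- weight_statistics(tab, model, normal_td_cutoff = normal_td_cutoff,
                           normal_ids = normal_ids, ci_method = ci_method)
  derive_threshold(cal, margin = margin)
}

#' @export
print.control_calibration <- function(x, ...) {
  cat(sprintf("Control calibration over %d eyes (%s CIs)\n", x$n_eyes,
              x$ci_method))
  print(x$stats, digits = 3)
  cat(sprintf("\nmax abnormal upper 95%% limit: %.2f%%\n", x$max_abnormal_upper))
  if (is.finite(x$threshold)) {
    cat(sprintf("meaningful-weight threshold: %g%% (margin %g)\n",
                x$threshold, x$margin))
  }
  invisible(x)
}
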