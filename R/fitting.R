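# Parameter recovery from morphometric tables: the proliferation-feedback
# line, exponential branch-count fits, tip-speed regression, and the
# cell-count comparison between mean-field prediction and observations.

#' Fit the proliferation--width feedback line
#'
#' Ordinary least squares of the normalized volumetric growth rate on
#' branch width. Under the model the points fall on
#' \eqn{k_d(w) = k_d^0 (1 - w/w_0)}, so the intercept estimates the
#' maximal division rate `kd0` and the width-axis crossing
#' `-intercept/slope` estimates `w0`, the width at which proliferation is
#' abrogated. The fit uses unbinned pairs; binning by width is a plotting
#' device only.
#'
#' @param pairs A data frame with columns `width` (um) and `growth_rate`
#'   (1/day), e.g. from [growth_rate_pairs()]; at least 3 pairs spanning
#'   at least 2 distinct widths.
#' @param bootstrap Number of nonparametric bootstrap resamples for the
#'   95% confidence intervals of `kd0` and `w0` (0 disables). Default 0;
#'   use 1000 for reporting.
#' @param seed RNG seed for the bootstrap.
#' @return A `feedback_fit` object with elements `slope`, `intercept`,
#'   `kd0`, `w0`, `stderr_slope`, `stderr_intercept`, `r2`, `n`,
#'   `w0_valid` (FALSE when the slope is non-negative, in which case `w0`
#'   is `NA`), and bootstrap intervals `ci_kd0`, `ci_w0` when requested.
#' @examples
#' w <- c(10, 20, 40, 55)
#' fit_proliferation_feedback(
#'   data.frame(width = w, growth_rate = 1.0 * (1 - w / 60)))
#' @export
fit_proliferation_feedback <- function(pairs, bootstrap = 0, seed = 1L) {
  stopifnot(is.data.frame(pairs),
            all(c("width", "growth_rate") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$width) & is.finite(pairs$growth_rate), ]
  if (nrow(pairs) < 3) {
    if (nrow(pairs) == 2 && length(unique(pairs$width)) == 2) {
      # two points at distinct widths: the exact interpolating line
    } else {
      stop("need at least 3 (width, growth rate) pairs", call. = FALSE)
    }
  }
  if (length(unique(pairs$width)) < 2) {
    stop("degenerate design: all widths identical", call. = FALSE)
  }
  fit <- stats::lm(growth_rate ~ width, data = pairs)
  co <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  slope <- unname(co[2]); intercept <- unname(co[1])
  w0_valid <- slope < 0 && intercept > 0
  out <- list(
    slope = slope, intercept = intercept,
    kd0 = intercept,
    w0 = if (w0_valid) -intercept / slope else NA_real_,
    w0_valid = w0_valid,
    stderr_slope = unname(se[2]), stderr_intercept = unname(se[1]),
    r2 = suppressWarnings(summary(fit)$r.squared),
    n = nrow(pairs),
    lm = fit
  )
  if (bootstrap > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, bootstrap, 2)
    for (b in seq_len(bootstrap)) {
      idx <- sample.int(nrow(pairs), replace = TRUE)
      cb <- tryCatch(stats::coef(stats::lm(growth_rate ~ width,
                                           data = pairs[idx, ])),
                     error = function(e) c(NA, NA))
      bs[b, ] <- c(unname(cb[1]), -unname(cb[1]) / unname(cb[2]))
    }
    out$ci_kd0 <- unname(stats::quantile(bs[, 1], c(0.025, 0.975),
                                         na.rm = TRUE))
    out$ci_w0 <- unname(stats::quantile(bs[, 2], c(0.025, 0.975),
                                        na.rm = TRUE))
    out$bootstrap <- bootstrap
    out$seed <- seed
  }
  structure(out, class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat("<feedback_fit>  kd(w) = kd0 (1 - w / w0)\n")
  cat(sprintf("  kd0 = %.4g /day (se %.3g)\n", x$kd0, x$stderr_intercept))
  if (x$w0_valid) {
    cat(sprintf("  w0  = %.4g um\n", x$w0))
  } else {
    cat("  w0  = <invalid: non-negative slope>\n")
  }
  cat(sprintf("  slope = %.4g /(day um), r2 = %.3f, n = %d\n",
              x$slope, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.feedback_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd0", "w0", "slope", "intercept"),
    estimate = c(x$kd0, x$w0, x$slope, x$intercept),
    std.error = c(x$stderr_intercept, NA, x$stderr_slope, x$stderr_intercept)
  )
}

#' @export
glance.feedback_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n, w0.valid = x$w0_valid)
}

#' Fit an exponential growth rate to branch counts
#'
#' Least squares of `log(count)` on time. The model predicts exponential
#' growth of the mean branch count at the branching rate `kb`, invariant
#' throughout the extension phase. The intercept is left free by default
#' (observed early structures may start from more than one branch); the
#' fixed-intercept variant (regression through `log(count0)` at `t = 0`)
#' is reported alongside.
#'
#' @param counts A data frame with columns `time` (day) and `count`
#'   (branch count or ensemble-mean branch count); at least 3 rows, all
#'   counts > 0.
#' @param count0 Intercept anchor for the fixed-intercept variant.
#'   Default 1 (one initial branch).
#' @return An `exponential_fit` with `rate` (1/day), `log_intercept`,
#'   `ci95_rate`, `rate_fixed_intercept`, `r2`, `n`.
#' @examples
#' fit_branching_rate(data.frame(time = 0:9, count = exp(0.55 * (0:9))))
#' @export
fit_branching_rate <- function(counts, count0 = 1) {
  stopifnot(is.data.frame(counts),
            all(c("time", "count") %in% names(counts)))
  bad <- which(!is.finite(counts$count) | counts$count <= 0)
  if (length(bad) > 0) {
    stop("non-positive branch count in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(counts) < 3) {
    stop("need at least 3 time points with positive counts", call. = FALSE)
  }
  fit <- stats::lm(log(count) ~ time, data = counts)
  co <- stats::coef(fit)
  ci <- tryCatch(suppressWarnings(stats::confint(fit))["time", ],
                 error = function(e) c(NA_real_, NA_real_))
  # fixed-intercept variant: slope of (log count - log count0) ~ time + 0
  rate_fixed <- unname(stats::coef(stats::lm(
    I(log(count) - log(count0)) ~ time + 0, data = counts))[1])
  structure(list(
    rate = unname(co[2]), log_intercept = unname(co[1]),
    ci95_rate = unname(ci),
    rate_fixed_intercept = rate_fixed,
    r2 = suppressWarnings(summary(fit)$r.squared), n = nrow(counts), lm = fit
  ), class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat("<exponential_fit>  count ~ exp(rate * t)\n")
  cat(sprintf("  rate = %.4g /day (95%% CI %.4g..%.4g), intercept exp(%.3g)\n",
              x$rate, x$ci95_rate[1], x$ci95_rate[2], x$log_intercept))
  cat(sprintf("  fixed-intercept rate = %.4g /day, r2 = %.3f, n = %d\n",
              x$rate_fixed_intercept, x$r2, x$n))
  invisible(x)
}

#' @export
tidy.exponential_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "log_intercept", "rate_fixed_intercept"),
    estimate = c(x$rate, x$log_intercept, x$rate_fixed_intercept),
    conf.low = c(x$ci95_rate[1], NA, NA),
    conf.high = c(x$ci95_rate[2], NA, NA)
  )
}

#' @export
glance.exponential_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n)
}

#' Fit the tip elongation speed from displacement tracks
#'
#' Per-track least-squares slope of cumulative arc-length displacement
#' versus time, averaged across tracks. Because displacement is measured
#' along the path, the slope recovers the invasion speed `v0` regardless
#' of directional noise.
#'
#' @param tracks A data frame with columns `track_id` (or `branch_id`),
#'   `time` (day), `position` (cumulative path length, um; `path_length`
#'   also accepted). Tracks with fewer than 3 samples are skipped with a
#'   warning.
#' @return A `tip_speed_fit` with `v0_hat` (mean slope, um/day), `sd`
#'   (across tracks), `n_tracks`, and the per-track slopes.
#' @export
fit_tip_speed <- function(tracks) {
  stopifnot(is.data.frame(tracks))
  if (!"track_id" %in% names(tracks)) {
    if ("branch_id" %in% names(tracks)) {
      tracks$track_id <- tracks$branch_id
      if ("organoid_id" %in% names(tracks)) {
        tracks$track_id <- paste(tracks$organoid_id, tracks$branch_id,
                                 sep = "/")
      }
    } else stop("tracks must have a track_id or branch_id column",
                call. = FALSE)
  }
  if (!"position" %in% names(tracks)) {
    if ("path_length" %in% names(tracks)) {
      tracks$position <- tracks$path_length
    } else stop("tracks must have a position or path_length column",
                call. = FALSE)
  }
  # per-track least-squares slope, computed group-wise in closed form
  slopes <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      slope = {
        tc <- .data$time - mean(.data$time)
        if (sum(tc^2) > 0) sum(tc * .data$position) / sum(tc^2) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(slope = ifelse(.data$n < 3, NA_real_, .data$slope)) |>
    dplyr::pull(.data$slope)
  skipped <- sum(is.na(slopes))
  if (skipped > 0) {
    warning(skipped, " track(s) with fewer than 3 samples skipped",
            call. = FALSE)
  }
  slopes <- slopes[!is.na(slopes)]
  if (length(slopes) == 0) {
    stop("no track has the 3 samples required for a slope", call. = FALSE)
  }
  structure(list(
    v0_hat = mean(slopes),
    sd = if (length(slopes) > 1) stats::sd(slopes) else NA_real_,
    n_tracks = length(slopes),
    slopes = slopes
  ), class = "tip_speed_fit")
}

#' @export
print.tip_speed_fit <- function(x, ...) {
  cat(sprintf("<tip_speed_fit>  v0 = %.4g um/day (sd %.3g, %d tracks)\n",
              x$v0_hat, x$sd, x$n_tracks))
  invisible(x)
}

#' @export
tidy.tip_speed_fit <- function(x, ...) {
  tibble::tibble(term = "v0", estimate = x$v0_hat, std.error = x$sd /
                   sqrt(x$n_tracks))
}

#' @export
glance.tip_speed_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_tracks, sd = x$sd)
}

#' Compare a mean-field cell-count prediction with observations
#'
#' Matches observation times against a mean-field trajectory and reports
#' the log-scale root-mean-square error and the coverage — the fraction
#' of times at which the prediction lies within the observed mean +/- sd
#' band (boundary counted in).
#'
#' @param traj A `meanfield_trajectory` from [integrate_meanfield()].
#' @param observed A data frame with columns `time`, `mean_nc`, `sd_nc`.
#' @return A list with `rmse_log` (log-cells), `coverage` (fraction), `n`.
#' @export
compare_cellcount_prediction <- function(traj, observed) {
  stopifnot(inherits(traj, "meanfield_trajectory"),
            all(c("time", "mean_nc", "sd_nc") %in% names(observed)))
  inside <- observed$time >= min(traj$t) - 1e-9 &
    observed$time <= max(traj$t) + 1e-9
  obs <- observed[inside, ]
  if (nrow(obs) == 0) {
    stop("no observation times overlap the trajectory span", call. = FALSE)
  }
  pred <- stats::approx(traj$t, traj$Nc, xout = obs$time)$y
  rmse_log <- sqrt(mean((log(pred) - log(obs$mean_nc))^2))
  covered <- pred >= obs$mean_nc - obs$sd_nc - 1e-9 &
    pred <= obs$mean_nc + obs$sd_nc + 1e-9
  list(rmse_log = rmse_log, coverage = mean(covered), n = nrow(obs))
}

#' Fit all model parameters from a synthetic (or measured) dataset
#'
#' Runs the three regression stages on the tables of a dataset — the
#' proliferation-feedback line for `(kd0, w0)`, the exponential
#' branch-count fit for `kb`, and the tip-track regression for `v0` —
#' and returns the combined estimates.
#'
#' @param dataset A `synthetic_dataset` from
#'   [generate_morphometric_dataset()], or a list with elements
#'   `growth_pairs`, `branch_counts` (columns `time`, `count` or per-
#'   organoid counts to average), `tip_tracks`.
#' @param count_window Optional `c(t0, t1)` restricting the times used for
#'   the branching-rate fit (day).
#' @param bootstrap Bootstrap resamples passed to
#'   [fit_proliferation_feedback()].
#' @param seed Seed for the bootstrap.
#' @return A `parameter_fit`: list with `feedback`, `branching`, `tip`
#'   sub-fits and an `estimates` tibble (`v0`, `kb`, `kd0`, `w0`).
#' @export
fit_growth_parameters <- function(dataset, count_window = NULL,
                                  bootstrap = 0, seed = 1L) {
  stopifnot(is.list(dataset))
  need <- c("growth_pairs", "branch_counts", "tip_tracks")
  missing <- setdiff(need, names(dataset))
  if (length(missing) > 0) {
    stop("dataset is missing table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fb <- fit_proliferation_feedback(dataset$growth_pairs,
                                   bootstrap = bootstrap, seed = seed)
  counts <- dataset$branch_counts
  if (!"count" %in% names(counts)) {
    stopifnot(all(c("time", "n_terminal") %in% names(counts)))
    counts <- counts |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(count = mean(.data$n_terminal), .groups = "drop")
  }
  if (!is.null(count_window)) {
    counts <- counts[counts$time >= count_window[1] - 1e-9 &
                       counts$time <= count_window[2] + 1e-9, ]
  }
  br <- fit_branching_rate(counts)
  # drop tracks too short to carry a slope before fitting, so routine
  # datasets (where many tips branch away mid-window) fit quietly
  tr <- dataset$tip_tracks
  key_cols <- intersect(c("organoid_id", "branch_id", "track_id"),
                        names(tr))
  key <- do.call(paste, tr[key_cols])
  tr <- tr[key %in% names(which(table(key) >= 3)), ]
  tip <- fit_tip_speed(tr)
  est <- tibble::tibble(
    term = c("v0", "kb", "kd0", "w0"),
    estimate = c(tip$v0_hat, br$rate, fb$kd0, fb$w0)
  )
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    est$truth <- c(tr$v0, tr$kb, tr$kd0, tr$w0)
    est$rel_error <- est$estimate / est$truth - 1
  }
  structure(list(feedback = fb, branching = br, tip = tip,
                 estimates = est), class = "parameter_fit")
}

#' @export
print.parameter_fit <- function(x, ...) {
  cat("<parameter_fit>\n")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.parameter_fit <- function(x, ...) x$estimates

#' @export
glance.parameter_fit <- function(x, ...) {
  tibble::tibble(
    feedback_r2 = x$feedback$r2, feedback_n = x$feedback$n,
    branching_r2 = x$branching$r2, n_tracks = x$tip$n_tracks
  )
}
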