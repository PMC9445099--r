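#' Observation noise model for synthetic datasets
#'
#' Multiplicative lognormal measurement noise for strictly positive
#' quantities (widths, growth rates, counts) and additive Gaussian jitter
#' for tip-track positions. Lognormal factors are mean-one
#' (`meanlog = -sigma^2/2`), so noised measurements are unbiased for the
#' noiseless value. The magnitudes are declared assumptions of the
#' generator, not measured values.
#'
#' @param width_cv Coefficient of variation of width measurements.
#' @param growth_rate_cv CV of normalized volumetric growth rates.
#' @param count_cv CV of branch/cell-count measurements.
#' @param track_jitter_sd Additive jitter on tip-track positions, um.
#' @param seed Master integer seed: organoid `i` is simulated with seed
#'   `seed + i`, noise uses a fixed offset of this seed.
#' @return An `observation_noise` object.
#' @export
observation_noise <- function(width_cv = 0.1, growth_rate_cv = 0.1,
                              count_cv = 0.1, track_jitter_sd = 2,
                              seed = 1L) {
  stopifnot(width_cv >= 0, growth_rate_cv >= 0, count_cv >= 0,
            track_jitter_sd >= 0)
  if (is.null(seed) || is.na(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  structure(list(width_cv = width_cv, growth_rate_cv = growth_rate_cv,
                 count_cv = count_cv, track_jitter_sd = track_jitter_sd,
                 seed = as.integer(seed)),
            class = "observation_noise")
}

# mean-one lognormal factors with coefficient of variation cv
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic morphometric dataset
#'
#' The stand-in for the study's measured tables: simulates `n_organoids`
#' independent organoids (distinct sub-seeds `seed + i`), measures them,
#' and applies the observation noise model. Emulated observables:
#' \describe{
#'   \item{growth_pairs}{per-branch (width, normalized volumetric growth
#'     rate) pairs sampled on a fine grid in `pair_window` (live-imaging
#'     window, default day 7--10) — the input of the feedback fit,}
#'   \item{branch_counts}{per-organoid terminal/total branch counts at
#'     `t_grid`,}
#'   \item{cell_counts}{per-organoid cell-number time series at `t_grid`,}
#'   \item{tip_tracks}{cumulative tip path-length tracks sampled every
#'     `track_dt` in `track_window`.}
#' }
#' The generating parameters and noise model are embedded in the returned
#' object, so every dataset is self-documenting.
#'
#' @param truth [growth_params()] used as ground truth.
#' @param noise [observation_noise()].
#' @param n_organoids Number of simulated organoids (>= 1).
#' @param t_grid Observation days for counts and cell numbers.
#' @param pair_window Observation window (day) for the growth-rate pairs.
#' @param pair_dt Length of each rate-measurement interval, day; short, so
#'   the finite-difference rate stays close to the instantaneous one.
#' @param pair_anchor_dt Spacing of the measurement anchors inside
#'   `pair_window`: every branch is measured over `[a, a + pair_dt]` at
#'   each anchor `a`.
#' @param track_window,track_dt Window and sampling interval for tip
#'   tracks.
#' @param track_organoids Number of organoids whose tips are tracked
#'   (live imaging covers a few organoids, not the whole collection).
#' @param n_pairs Optional cap: subsample this many growth pairs (seeded).
#' @param sim_overrides Named list of [sim_config()] fields to override
#'   (e.g. `dt`, `dtheta`).
#' @return A `synthetic_dataset` list with the four tables plus `truth`,
#'   `noise`, `config`.
#' @export
generate_morphometric_dataset <- function(truth = growth_params(),
                                          noise = observation_noise(),
                                          n_organoids = 60,
                                          t_grid = 0:9,
                                          pair_window = c(7, 10),
                                          pair_dt = 0.05,
                                          pair_anchor_dt = 0.5,
                                          track_window = c(7, 9),
                                          track_dt = 0.1,
                                          track_organoids = 3,
                                          n_pairs = NULL,
                                          sim_overrides = list()) {
  stopifnot(inherits(truth, "growth_params"),
            inherits(noise, "observation_noise"),
            n_organoids >= 1)
  duration <- max(t_grid, pair_window, track_window)
  if (min(t_grid) < 0 || any(diff(sort(t_grid)) == 0)) {
    stop("t_grid must be non-negative distinct times", call. = FALSE)
  }
  cfg_args <- utils::modifyList(
    list(params = truth, duration = duration, seed = noise$seed),
    sim_overrides
  )
  cfg <- do.call(sim_config, cfg_args)
  anchors <- seq(pair_window[1], pair_window[2] - pair_dt,
                 by = pair_anchor_dt)
  pair_times <- sort(unique(round(c(anchors, anchors + pair_dt), 9)))
  sample_times <- sort(unique(c(t_grid, pair_times)))
  track_times <- seq(track_window[1], track_window[2], by = track_dt)

  ens <- simulate_ensemble(
    cfg, n_organoids,
    keep = c("summary", "branch_samples", "tip_tracks"),
    sample_times = sample_times, track_times = track_times,
    record_nodes = FALSE
  )

  # growth pairs: only the [anchor, anchor + pair_dt] intervals
  on_pair_grid <- round(ens$branch_samples$time, 6) %in% round(pair_times, 6)
  pairs <- growth_rate_pairs(ens$branch_samples[on_pair_grid, ])
  pairs <- pairs[abs(pairs$delta_t - pair_dt) < 1e-6, ]

  # per-organoid counts and cell numbers at t_grid
  on_grid <- round(ens$summary$time, 6) %in% round(t_grid, 6)
  counts <- ens$summary[on_grid,
                        c("organoid_id", "time", "n_terminal", "n_branches")]
  cells <- ens$summary[on_grid, c("organoid_id", "time", "n_cells")]
  tracks <- dplyr::rename(ens$tip_tracks, position = "path_length")
  tracks <- tracks[tracks$organoid_id <= track_organoids, ]

  # observation noise (seeded independently of the simulations)
  set.seed(noise$seed + 700001L)
  pairs$width <- pairs$width * lognormal_factor(nrow(pairs), noise$width_cv)
  pairs$growth_rate <- pairs$growth_rate *
    lognormal_factor(nrow(pairs), noise$growth_rate_cv)
  counts$n_terminal <- counts$n_terminal *
    lognormal_factor(nrow(counts), noise$count_cv)
  counts$n_branches <- counts$n_branches *
    lognormal_factor(nrow(counts), noise$count_cv)
  cells$n_cells <- cells$n_cells *
    lognormal_factor(nrow(cells), noise$count_cv)
  tracks$position <- tracks$position +
    stats::rnorm(nrow(tracks), 0, noise$track_jitter_sd)

  if (!is.null(n_pairs) && nrow(pairs) > n_pairs) {
    pairs <- pairs[sample.int(nrow(pairs), n_pairs), ]
  }

  cell_stats <- cells |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean_nc = mean(.data$n_cells),
                     sd_nc = stats::sd(.data$n_cells), .groups = "drop")

  structure(list(
    growth_pairs = pairs,
    branch_counts = counts,
    cell_counts = cells,
    cellcount_stats = cell_stats,
    tip_tracks = tracks,
    truth = truth, noise = noise, config = cfg,
    n_organoids = n_organoids, t_grid = t_grid
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d organoids, seed %d\n",
              x$n_organoids, x$noise$seed))
  cat(sprintf("  growth_pairs: %d, branch_counts: %d rows, tip_tracks: %d rows\n",
              nrow(x$growth_pairs), nrow(x$branch_counts),
              nrow(x$tip_tracks)))
  invisible(x)
}

#' Small deterministic worked dataset
#'
#' A tiny fixed-seed dataset (3 organoids, observation days 1--9) used in
#' the documentation and fast tests; its fit report is committed with the
#' package and asserted stable.
#'
#' @param seed Integer seed. The default (42) reproduces the committed
#'   fixture; an explicit seed is mandatory.
#' @return A `synthetic_dataset`.
#' @export
generate_worked_fixture <- function(seed = 42L) {
  generate_morphometric_dataset(
    truth = growth_params(),
    noise = observation_noise(seed = seed),
    n_organoids = 3,
    t_grid = 1:9,
    pair_window = c(7, 9),
    track_window = c(7, 9)
  )
}

#' Write a synthetic dataset to delimited files
#'
#' Writes the four observation tables as CSV (unit-bearing headers) plus a
#' `truth.json` sidecar holding the generating parameters, noise model and
#' seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name, header) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(paste0("# ", header), con)
    utils::write.csv(tbl, con, row.names = FALSE)
    close(con)
  }
  wr(dataset$growth_pairs, "growth_pairs.csv",
     "width [um], growth_rate [1/day], time [day]")
  wr(dataset$branch_counts, "branch_counts.csv",
     "time [day], counts [dimensionless]")
  wr(dataset$cell_counts, "cell_counts.csv",
     "time [day], n_cells [cells]")
  wr(dataset$tip_tracks, "tip_tracks.csv",
     "time [day], position [um]")
  jsonlite::write_json(
    list(truth = unclass(dataset$truth),
         noise = unclass(dataset$noise),
         n_organoids = dataset$n_organoids,
         t_grid = dataset$t_grid),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV tables and `truth.json`.
#' @return A `synthetic_dataset` (without the simulation config).
#' @export
read_dataset <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      stop("dataset is missing table: ", name, call. = FALSE)
    }
    tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  }
  truth_path <- file.path(dir, "truth.json")
  meta <- if (file.exists(truth_path)) {
    jsonlite::read_json(truth_path, simplifyVector = TRUE)
  } else NULL
  cells <- rd("cell_counts.csv")
  structure(list(
    growth_pairs = rd("growth_pairs.csv"),
    branch_counts = rd("branch_counts.csv"),
    cell_counts = cells,
    cellcount_stats = cells |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(mean_nc = mean(.data$n_cells),
                       sd_nc = stats::sd(.data$n_cells), .groups = "drop"),
    tip_tracks = rd("tip_tracks.csv"),
    truth = if (!is.null(meta)) do.call(growth_params, meta$truth) else NULL,
    noise = if (!is.null(meta)) do.call(observation_noise, meta$noise)
            else NULL,
    n_organoids = meta$n_organoids, t_grid = meta$t_grid
  ), class = "synthetic_dataset")
}
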