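#' Simulate an ensemble of organoids
#'
#' Runs [simulate_organoid()] `n_runs` times with distinct sub-seeds
#' (`seed + i` for organoid `i`, a counter scheme so any organoid can be
#' regenerated alone) and row-binds the requested components with an
#' `organoid_id` column.
#'
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param n_runs Number of organoids.
#' @param keep Character vector of components to retain, from
#'   `"summary"`, `"branch_samples"`, `"tip_tracks"`, `"events"`,
#'   `"divisions"`, `"trees"`. Default keeps the cheap summary only.
#' @param schedule Optional [perturbation_schedule()] applied to every run.
#' @inheritParams simulate_organoid
#' @return A list of tibbles (and, if requested, a list of tree lists),
#'   one element per kept component, each with an `organoid_id` column.
#' @export
simulate_ensemble <- function(config, n_runs,
                              keep = "summary",
                              schedule = NULL,
                              save_times = NULL,
                              sample_times = seq(0, config$duration, by = 0.1),
                              track_times = NULL,
                              record_nodes = FALSE,
                              node_every = 10L) {
  stopifnot(inherits(config, "sim_config"), n_runs >= 1)
  keep <- match.arg(keep, c("summary", "branch_samples", "tip_tracks",
                            "events", "divisions", "trees"),
                    several.ok = TRUE)
  runs <- purrr::map(seq_len(n_runs), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    sim <- simulate_organoid(
      cfg, schedule = schedule,
      save_times = if (is.null(save_times)) numeric() else save_times,
      sample_times = sample_times, track_times = track_times,
      record_nodes = record_nodes, node_every = node_every
    )
    out <- purrr::map(setdiff(keep, "trees"), function(nm) {
      dplyr::mutate(sim[[nm]], organoid_id = i, .before = 1)
    })
    names(out) <- setdiff(keep, "trees")
    if ("trees" %in% keep) out$trees <- sim$trees
    out
  })
  out <- purrr::map(setdiff(keep, "trees"), function(nm) {
    dplyr::bind_rows(purrr::map(runs, nm))
  })
  names(out) <- setdiff(keep, "trees")
  if ("trees" %in% keep) out$trees <- purrr::map(runs, "trees")
  out$config <- config
  out$n_runs <- n_runs
  structure(out, class = "organoid_ensemble")
}

#' Branch-count statistics across an ensemble
#'
#' Sample mean and standard deviation of the branch count per organoid at
#' each requested time. For a pure-birth (Yule) branching process at rate
#' `kb` the mean grows as \eqn{e^{k_b t}} and the standard deviation as
#' \eqn{\sqrt{m(m-1)}} with \eqn{m = e^{k_b t}} — of the same order as the
#' mean itself, the signature of stochastic tip branching.
#'
#' @param ensemble An ensemble as returned by [simulate_ensemble()] (needs
#'   the `summary` component), or a tibble with columns `organoid_id`,
#'   `time`, `n_terminal` (and `n_branches`).
#' @param times Times (day) at which to report; must be present in the
#'   ensemble's sample grid for every run.
#' @param count `"terminal"` (default) counts elongating tips — the branch
#'   count `Nb` of the mean-field model and the unit of the Yule
#'   statistics; `"all"` counts terminal plus non-terminal branches.
#' @return A tibble `time, mean_nb, sd_nb, var_nb, n`.
#' @export
branch_count_statistics <- function(ensemble, times,
                                    count = c("terminal", "all")) {
  count <- match.arg(count)
  tbl <- if (is.data.frame(ensemble)) ensemble else ensemble$summary
  if (is.null(tbl) || nrow(tbl) == 0) {
    stop("ensemble contains no summary records", call. = FALSE)
  }
  col <- if (count == "terminal") "n_terminal" else "n_branches"
  stopifnot(all(c("organoid_id", "time", col) %in% names(tbl)))
  out <- purrr::map_dfr(times, function(tt) {
    sub <- tbl[abs(tbl$time - tt) < 1e-9, ]
    if (nrow(sub) == 0) {
      stop(sprintf("no ensemble records at time %g", tt), call. = FALSE)
    }
    tibble::tibble(
      time = tt,
      mean_nb = mean(sub[[col]]),
      sd_nb = stats::sd(sub[[col]]),
      var_nb = stats::var(sub[[col]]),
      n = nrow(sub)
    )
  })
  out$sd_nb[out$n == 1] <- NA_real_
  out
}

#' Fraction of branching events preceded by a tip division
#'
#' For every branching event logged by the simulator, checks whether a
#' division occurred in the branch's tip compartment within the preceding
#' `window` days (inclusive of a division at the branching instant, which
#' is the triggering division under division-coupled branching).
#'
#' @param events A branching-event tibble (`time`, `branch_id`,
#'   `last_division_time`), e.g. `sim$events` or the bound `events` of an
#'   ensemble.
#' @param window Look-back window, day. Default 0.5.
#' @return A list with `fraction`, `n_events`, `n_preceded`.
#' @export
division_precedence <- function(events, window = 0.5) {
  stopifnot(is.data.frame(events),
            all(c("time", "last_division_time") %in% names(events)))
  if (nrow(events) == 0) stop("no branching events", call. = FALSE)
  preceded <- !is.na(events$last_division_time) &
    (events$time - events$last_division_time) <= window + 1e-12
  list(fraction = mean(preceded), n_events = nrow(events),
       n_preceded = sum(preceded))
}

#' Classify branching and division events
#'
#' Cross-tabulates branching against tip-compartment division the way live
#' branching events are scored: `true_yes` — branching preceded by a
#' division within `window`; `true_no` — branching with no preceding
#' division; `false_yes` — a division not followed by a branching of that
#' branch within `window`.
#'
#' @param events Branching-event tibble (`time`, `branch_id`,
#'   `last_division_time`).
#' @param divisions Division-event tibble (`time`, `branch_id`), e.g.
#'   `sim$divisions`.
#' @param window Pairing window, day. Default 0.5.
#' @return A tibble with one row: `true_yes`, `true_no`, `false_yes`.
#' @export
classify_branching_events <- function(events, divisions, window = 0.5) {
  stopifnot(is.data.frame(events), is.data.frame(divisions))
  preceded <- !is.na(events$last_division_time) &
    (events$time - events$last_division_time) <= window + 1e-12
  followed <- purrr::map_lgl(seq_len(nrow(divisions)), function(i) {
    dv <- divisions[i, ]
    any(events$branch_id == dv$branch_id &
          events$time >= dv$time - 1e-12 &
          events$time <= dv$time + window + 1e-12)
  })
  tibble::tibble(
    true_yes = sum(preceded),
    true_no = sum(!preceded),
    false_yes = sum(!followed)
  )
}
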