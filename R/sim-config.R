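#' Configuration of the stochastic spatial simulator
#'
#' @param params A [growth_params()] object.
#' @param dtheta Angular diffusion coefficient of the tip direction,
#'   rad^2/day. Each step the tip direction is perturbed by a Gaussian
#'   angle of variance `dtheta * dt`.
#' @param theta_b Branching half-angle, rad, in (0, pi/2): daughters leave
#'   at `+theta_b` and `-theta_b` around the mother direction (in a random
#'   plane containing it when `params$dim == 3`).
#' @param dt Time step, day.
#' @param duration Simulated duration, day.
#' @param seed Integer RNG seed; identical configurations (including seed)
#'   give bit-identical simulations.
#' @param couple_branching_to_division If `TRUE` (default), branching is
#'   triggered by divisions in the tip compartment (the leading
#'   `n_tip_cells` cells): divisions fire at rate `n_tip_cells * kd(w)` and
#'   each triggers a branching event with probability
#'   `kb / (n_tip_cells * kd(w))`, so the long-run branching rate per tip
#'   is exactly `kb` while every branching event follows a tip division.
#'   If `FALSE`, branching is an independent Poisson process at rate `kb`.
#' @param n_tip_cells Number of cells in the tip compartment used for
#'   division-coupled branching. Default 6.
#' @param split_mother_volume If `TRUE`, the seed volume of the two
#'   daughters is taken out of the mother branch; by default it is newly
#'   created (interpreted as tip proliferation feeding the new branches).
#' @param self_avoidance_distance Optional distance, um: an elongating tip
#'   that comes within this distance of another branch's centerline is
#'   arrested (stops elongating and branching but keeps proliferating).
#'   `NULL` (default) disables self-avoidance.
#' @param init_cells Number of cells in the initial branch (volume
#'   `init_cells * v_cell`). Default 1 (growth from a single cell); larger
#'   values emulate starting from an established multicellular structure,
#'   as in treatment experiments on developed organoids.
#'
#' @return A `sim_config` object (a named list).
#' @seealso [simulate_organoid()]
#' @export
sim_config <- function(params = growth_params(), dtheta = 0.2, theta_b = 0.6,
                       dt = 0.01, duration = 9, seed = 1L,
                       couple_branching_to_division = TRUE,
                       n_tip_cells = 6L,
                       split_mother_volume = FALSE,
                       self_avoidance_distance = NULL,
                       init_cells = 1) {
  stopifnot(
    inherits(params, "growth_params"),
    "dt must be > 0" = is.finite(dt) && dt > 0,
    "duration must be > 0" = is.finite(duration) && duration > 0,
    "theta_b must be in (0, pi/2)" = theta_b > 0 && theta_b < pi / 2,
    "dtheta must be >= 0" = is.finite(dtheta) && dtheta >= 0,
    "n_tip_cells must be >= 1" = n_tip_cells >= 1,
    "init_cells must be >= 1" = is.finite(init_cells) && init_cells >= 1,
    is.logical(couple_branching_to_division),
    is.logical(split_mother_volume)
  )
  if (is.null(seed)) {
    stop("an explicit integer seed is required for reproducibility",
         call. = FALSE)
  }
  stopifnot(is.finite(seed))
  structure(list(
    params = params, dtheta = dtheta, theta_b = theta_b, dt = dt,
    duration = duration, seed = as.integer(seed),
    couple_branching_to_division = isTRUE(couple_branching_to_division),
    n_tip_cells = as.integer(n_tip_cells),
    split_mother_volume = isTRUE(split_mother_volume),
    self_avoidance_distance = self_avoidance_distance,
    init_cells = as.numeric(init_cells)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  duration = %g day, dt = %g day, seed = %d, dim = %d\n",
              x$duration, x$dt, x$seed, x$params$dim))
  cat(sprintf("  dtheta = %g rad^2/day, theta_b = %g rad\n",
              x$dtheta, x$theta_b))
  cat(sprintf("  division-coupled branching: %s (tip compartment: %d cells)\n",
              x$couple_branching_to_division, x$n_tip_cells))
  print(x$params)
  invisible(x)
}

#' Perturbation schedule for in-silico drug treatments
#'
#' A schedule is a list of events; at each event time the named growth
#' parameters are overridden for the rest of the simulation (or until a
#' later event changes them again).
#'
#' @param times Numeric vector of event times, day (non-decreasing).
#' @param overrides A list of named lists, one per event, each naming
#'   [growth_params()] fields to override.
#' @return A `perturbation_schedule` object.
#' @examples
#' perturbation_schedule(times = 7, overrides = list(list(kd0 = 0)))
#' @seealso [perturbation_preset()], [apply_perturbation()]
#' @export
perturbation_schedule <- function(times = numeric(), overrides = list()) {
  stopifnot(length(times) == length(overrides))
  if (length(times) > 1 && any(diff(times) < 0)) {
    stop("event times must be non-decreasing", call. = FALSE)
  }
  known <- names(unclass(growth_params()))
  for (ov in overrides) {
    stopifnot(is.list(ov))
    bad <- setdiff(names(ov), known)
    if (length(bad) > 0) {
      stop("schedule overrides unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(times = as.numeric(times), overrides = overrides),
            class = "perturbation_schedule")
}

#' Preset perturbation schedules for batimastat and aphidicolin
#'
#' Two in-silico drug treatments mirroring the model's perturbation
#' predictions:
#' * `"batimastat"` (matrix-metalloproteinase inhibitor): abolishes tip
#'   invasion (`v0 -> 0`) and reduces volumetric growth to 23% of its
#'   unperturbed value (`kd0 -> 0.23 * kd0`, the measured -77% residual).
#'   Without elongation to thin them, branches thicken towards `w0`.
#' * `"aphidicolin"` (DNA-polymerase inhibitor): abolishes proliferation
#'   (`kd0 -> 0`). Continued tip elongation then thins branches over time,
#'   with nascent branches the most fragile (first to reach the breakage
#'   width).
#'
#' @param preset `"batimastat"` or `"aphidicolin"`.
#' @param at Treatment time, day.
#' @param params The [growth_params()] in force before treatment (used to
#'   compute the scaled `kd0` for batimastat).
#' @return A [perturbation_schedule()].
#' @export
perturbation_preset <- function(preset = c("batimastat", "aphidicolin"),
                                at, params = growth_params()) {
  preset <- match.arg(preset)
  stopifnot(is.finite(at), at >= 0, inherits(params, "growth_params"))
  ov <- switch(preset,
    batimastat = list(v0 = 0, kd0 = 0.23 * params$kd0),
    aphidicolin = list(kd0 = 0)
  )
  perturbation_schedule(times = at, overrides = list(ov))
}

#' Attach a perturbation schedule to a simulation configuration
#'
#' Validates the schedule against the configuration (event times inside
#' `[0, duration]`, known parameter names) and returns the configuration
#' with the schedule attached, ready for [simulate_organoid()].
#'
#' @param config A [sim_config()].
#' @param schedule A [perturbation_schedule()], or a preset name
#'   (`"batimastat"`/`"aphidicolin"`) together with `at`.
#' @param at Treatment time, day; required when `schedule` is a preset name.
#' @return The `sim_config` with a `schedule` element attached.
#' @export
apply_perturbation <- function(config, schedule, at = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(schedule)) {
    if (is.null(at)) stop("`at` is required for a preset name", call. = FALSE)
    schedule <- perturbation_preset(schedule, at = at, params = config$params)
  }
  stopifnot(inherits(schedule, "perturbation_schedule"))
  if (length(schedule$times) > 0 &&
      (min(schedule$times) < 0 || max(schedule$times) > config$duration)) {
    stop("schedule event times must lie within [0, duration]", call. = FALSE)
  }
  config$schedule <- schedule
  config
}
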