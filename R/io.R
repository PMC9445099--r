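# Configuration files and run artifacts. Units are days and micrometres
# everywhere; CSV headers carry unit annotations.

#' Load a run configuration from a YAML file
#'
#' The configuration is declarative and flat-ish: top-level sections
#' `params` ([growth_params()] fields), `sim` ([sim_config()] fields other
#' than `params`), `noise` ([observation_noise()] fields), `schedule`
#' (list of events with `time` and parameter overrides), `output_dir` and
#' `log_level`. Every field is optional — defaults are filled in and
#' reported — but unknown keys are a hard error, so misspelled settings
#' cannot be ignored silently.
#'
#' @param path Path to a YAML configuration file.
#' @param quiet Suppress the defaults-applied message.
#' @return A `run_config`: list with `params`, `sim`, `noise`, `schedule`,
#'   `output_dir`, `log_level`.
#' @export
load_run_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config parse failure in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(raw)) raw <- list()
  known_top <- c("params", "sim", "noise", "schedule", "output_dir",
                 "log_level")
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(section, known, where) {
    bad <- setdiff(names(section), known)
    if (length(bad) > 0) {
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    section
  }
  p_args <- check_keys(raw$params %||% list(),
                       names(formals(growth_params)), "params")
  params <- do.call(growth_params, p_args)
  sim_known <- setdiff(names(formals(sim_config)), "params")
  s_args <- check_keys(raw$sim %||% list(), sim_known, "sim")
  sim <- do.call(sim_config, c(list(params = params), s_args))
  n_args <- check_keys(raw$noise %||% list(),
                       names(formals(observation_noise)), "noise")
  noise <- do.call(observation_noise, n_args)
  schedule <- NULL
  if (!is.null(raw$schedule)) {
    evs <- raw$schedule
    times <- purrr::map_dbl(evs, function(e) {
      if (is.null(e$time)) stop("schedule event lacks a time", call. = FALSE)
      as.numeric(e$time)
    })
    overrides <- purrr::map(evs, function(e) e[setdiff(names(e), "time")])
    schedule <- perturbation_schedule(times, overrides)
  }
  defaults_used <- c(
    if (length(p_args) < length(formals(growth_params))) "params",
    if (length(s_args) < length(sim_known)) "sim",
    if (length(n_args) < length(formals(observation_noise))) "noise"
  )
  if (!quiet && length(defaults_used) > 0) {
    message("defaults applied for unspecified fields in: ",
            paste(defaults_used, collapse = ", "))
  }
  structure(list(params = params, sim = sim, noise = noise,
                 schedule = schedule,
                 output_dir = raw$output_dir %||% ".",
                 log_level = raw$log_level %||% "info"),
            class = "run_config")
}

#' Write a mean-field trajectory as CSV
#'
#' Columns `t [day], Nc [cells], Ltot [um], Nb [branches], w [um]`.
#'
#' @param traj A `meanfield_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "meanfield_trajectory"))
  out <- tibble::as_tibble(traj)
  names(out) <- c("t [day]", "Nc [cells]", "Ltot [um]", "Nb [branches]",
                  "w [um]")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a mean-field trajectory written by [write_trajectory_csv()]
#'
#' @param path CSV file path.
#' @param params Optional [growth_params()] to re-attach.
#' @return A `meanfield_trajectory` tibble.
#' @export
read_trajectory_csv <- function(path, params = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE)
  out <- tibble::tibble(t = raw[[1]], Nc = raw[[2]], Ltot = raw[[3]],
                        Nb = raw[[4]], w = raw[[5]])
  structure(out, params = params,
            class = c("meanfield_trajectory", class(out)))
}

#' Save a parameter-fit report as JSON
#'
#' Writes all estimates, intervals, sample sizes and the RNG seed of a
#' [fit_growth_parameters()] result.
#'
#' @param fit A `parameter_fit`.
#' @param path Output JSON path.
#' @param seed The RNG seed used to produce the fitted dataset (recorded
#'   in the report).
#' @return `path`, invisibly.
#' @export
save_fit_report <- function(fit, path, seed = NA_integer_) {
  stopifnot(inherits(fit, "parameter_fit"))
  fb <- fit$feedback; br <- fit$branching; tp <- fit$tip
  report <- list(
    estimates = list(
      v0 = tp$v0_hat, kb = br$rate, kd0 = fb$kd0, w0 = fb$w0
    ),
    feedback = list(
      slope = fb$slope, intercept = fb$intercept,
      stderr_slope = fb$stderr_slope,
      stderr_intercept = fb$stderr_intercept,
      r2 = fb$r2, n = fb$n, w0_valid = fb$w0_valid,
      ci_kd0 = fb$ci_kd0, ci_w0 = fb$ci_w0
    ),
    branching = list(
      rate = br$rate, log_intercept = br$log_intercept,
      ci95_rate = br$ci95_rate,
      rate_fixed_intercept = br$rate_fixed_intercept,
      r2 = br$r2, n = br$n
    ),
    tip_speed = list(v0_hat = tp$v0_hat, sd = tp$sd,
                     n_tracks = tp$n_tracks),
    seed = seed,
    package_version = as.character(utils::packageVersion("orgbranch"))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(path)
}
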