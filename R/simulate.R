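# Stochastic spatial branching simulator: R orchestration over the
# compiled stepping core (src/sim_core.cpp). The R layer owns seeding,
# perturbation schedules, snapshot assembly and the tidy outputs; the core
# advances the branch state between snapshot/schedule boundaries.

random_unit_vector <- function(d) {
  v <- stats::rnorm(d)
  n <- sqrt(sum(v^2))
  if (n < 1e-12) v <- c(1, rep(0, d - 1)) else v <- v / n
  v
}

new_sim_state <- function(config, record_nodes) {
  p <- config$params
  d <- p$dim
  d0 <- random_unit_vector(d)
  tip0 <- p$l_init * d0
  vol0 <- (config$init_cells %||% 1) * p$v_cell
  st <- list(
    n = 1L, dim = as.integer(d),
    parent = 0L,                       # 0 = no parent (root)
    birth = 0,
    length = p$l_init,
    volume = vol0,
    width = sqrt(4 * vol0 / (pi * p$l_init)),
    last_div = NA_real_,
    terminal = 1L, broken = 0L, arrested = 0L,
    dir = as.numeric(d0), tip = as.numeric(tip0),
    record_nodes = isTRUE(record_nodes)
  )
  if (record_nodes) st$nodes <- list(c(rep(0, d), tip0))
  st
}

par_for_core <- function(p) {
  list(v0 = p$v0, kb = p$kb, kd0 = p$kd0, w0 = p$w0, l_init = p$l_init,
       w_min = p$w_min)
}

cfg_for_core <- function(config, node_every) {
  list(dt = config$dt, dtheta = config$dtheta, theta_b = config$theta_b,
       n_tip_cells = config$n_tip_cells,
       couple_branching_to_division = config$couple_branching_to_division,
       split_mother_volume = config$split_mother_volume,
       sad = if (is.null(config$self_avoidance_distance)) -1 else
         config$self_avoidance_distance,
       node_every = as.integer(node_every))
}

#' Simulate a branching organoid
#'
#' Runs the stochastic spatial version of the growth model: elongating
#' tips advance at speed `v0` with angular diffusion of their direction,
#' every branch's volume grows at the width-dependent division rate
#' \eqn{k_d(w) = k_d^0\max(0, 1 - w/w_0)} (widths follow from the
#' cylindrical volume--length closure, so elongation thins a branch while
#' proliferation thickens it), and terminal branches branch stochastically
#' at rate `kb` — by default triggered by divisions in the tip compartment
#' (see [sim_config()]). A branch whose width falls below `w_min` ruptures:
#' it keeps its geometry but stops elongating and growing. Daughter
#' branches start with length `l_init` and the mother's tip width, at
#' `+/- theta_b` around the mother direction.
#'
#' Time stepping is fixed-step tau-leaping: per step, each admissible
#' event fires with probability `1 - exp(-rate * dt)`. Identical
#' configurations (including the seed) give bit-identical simulations.
#'
#' @param config A [sim_config()].
#' @param schedule An optional [perturbation_schedule()] (overrides any
#'   schedule attached to `config` by [apply_perturbation()]).
#' @param save_times Times (day) at which to snapshot the full tree; each
#'   is rounded to the step grid. Default: the final time.
#' @param sample_times Times at which per-branch width/volume/length
#'   records and the organoid summary are taken. Default
#'   `seq(0, duration, 0.1)`.
#' @param track_times Times at which each elongating tip's cumulative path
#'   length is sampled (for tip-speed regression). Default: none.
#' @param record_nodes If `FALSE`, centerline polylines are not stored
#'   (tree snapshots then carry only widths/volumes/topology); much faster
#'   for large ensembles. Default `TRUE`.
#' @param node_every Record a polyline node every this many steps (plus at
#'   every branching event and snapshot). Default 10.
#'
#' @return An `organoid_sim` object: a list with elements
#'   \describe{
#'     \item{trees}{list of [organoid_tree] snapshots at `save_times`,}
#'     \item{summary}{tibble `time, n_branches, n_terminal, n_nonterminal,
#'       n_broken, total_length, total_volume, n_cells` at `sample_times`,}
#'     \item{branch_samples}{tibble of per-branch records at
#'       `sample_times`,}
#'     \item{tip_tracks}{tibble `branch_id, time, path_length`,}
#'     \item{events}{tibble of branching events `time, branch_id,
#'       last_division_time`,}
#'     \item{divisions}{tibble of tip-compartment division events,}
#'     \item{config, schedule}{the inputs.}
#'   }
#' @examples
#' cfg <- sim_config(duration = 4, seed = 7)
#' sim <- simulate_organoid(cfg)
#' tail(sim$summary)
#' @export
simulate_organoid <- function(config, schedule = NULL,
                              save_times = config$duration,
                              sample_times = seq(0, config$duration, by = 0.1),
                              track_times = NULL,
                              record_nodes = TRUE,
                              node_every = 10L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(schedule)) schedule <- config$schedule
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "perturbation_schedule"))
    if (length(schedule$times) > 0 &&
        (min(schedule$times) < 0 || max(schedule$times) > config$duration)) {
      stop("schedule event times must lie within [0, duration]", call. = FALSE)
    }
  }
  p <- config$params
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  if (!is.null(config$self_avoidance_distance) && !record_nodes) {
    stop("self-avoidance requires record_nodes = TRUE", call. = FALSE)
  }

  step_set <- function(times) {
    if (is.null(times) || length(times) == 0) return(integer())
    sort(unique(pmin(pmax(as.integer(round(times / dt)), 0L), n_steps)))
  }
  save_steps <- step_set(save_times)
  sample_steps <- step_set(sample_times)
  track_steps <- step_set(track_times)
  sched_steps <- if (is.null(schedule)) integer() else
    pmin(pmax(as.integer(round(schedule$times / dt)), 0L), n_steps)

  set.seed(config$seed)
  st <- new_sim_state(config, record_nodes)
  core_cfg <- cfg_for_core(config, node_every)

  trees <- list()
  chunks <- list()

  sample0 <- function(st, t_now) {
    list(
      samples = list(
        time = t_now, branch_id = 1L, parent_id = 0L, birth_time = 0,
        width = st$width, volume = st$volume, length = st$length,
        terminal = 1L, broken = 0L),
      summary = c(t_now, 1, 1, 0, 0, st$length, st$volume),
      tracks = list(branch_id = 1L, time = t_now, path_length = st$length),
      events = list(time = numeric(), branch_id = integer(),
                    last_division_time = numeric()),
      divisions = list(time = numeric(), branch_id = integer())
    )
  }
  if (0L %in% sample_steps || 0L %in% track_steps) {
    ch0 <- sample0(st, 0)
    if (!(0L %in% sample_steps)) {
      ch0$samples <- NULL; ch0$summary <- NULL
    }
    if (!(0L %in% track_steps)) ch0$tracks <- NULL
    chunks[[length(chunks) + 1L]] <- ch0
  }
  if (0L %in% save_steps) {
    trees[[length(trees) + 1L]] <- snapshot_tree(st, 0, config)
  }

  # segment boundaries: schedule events (parameters change after the
  # event step) and snapshot steps
  bounds <- sort(unique(c(0L, sched_steps, save_steps, n_steps)))
  bounds <- bounds[bounds <= n_steps]
  if (bounds[length(bounds)] < n_steps) bounds <- c(bounds, n_steps)

  for (b in seq_len(length(bounds) - 1L)) {
    k0 <- bounds[b]; k1 <- bounds[b + 1L]
    # apply any schedule events at k0 (effective from step k0 + 1)
    due <- which(sched_steps == k0)
    for (j in due) {
      p <- suppressWarnings(do.call(
        growth_params,
        utils::modifyList(unclass(p), schedule$overrides[[j]])
      ))
    }
    if (k1 > k0) {
      res <- .sim_chunk(st, par_for_core(p), core_cfg, k0, k1,
                        sample_steps, track_steps)
      st <- res$state
      res$state <- NULL
      chunks[[length(chunks) + 1L]] <- res
    }
    if (k1 %in% save_steps && k1 > 0L) {
      trees[[length(trees) + 1L]] <- snapshot_tree(st, k1 * dt, config)
    }
  }

  gather <- function(component, cols) {
    parts <- purrr::map(chunks, component)
    parts <- parts[!purrr::map_lgl(parts, is.null)]
    tibble::as_tibble(rlang::set_names(
      purrr::map(cols, function(nm) {
        do.call(c, purrr::map(parts, ~ as.vector(.x[[nm]])))
      }), cols))
  }
  samples <- gather("samples", c("time", "branch_id", "parent_id",
                                 "birth_time", "width", "volume", "length",
                                 "terminal", "broken"))
  samples$terminal <- as.logical(samples$terminal)
  samples$broken <- as.logical(samples$broken)
  samples$parent_id <- ifelse(samples$parent_id == 0L, NA_integer_,
                              samples$parent_id)
  sums <- do.call(c, purrr::map(chunks, "summary"))
  summary_tbl <- if (length(sums) > 0) {
    m <- matrix(sums, ncol = 7, byrow = TRUE)
    tibble::tibble(time = m[, 1], n_branches = as.integer(m[, 2]),
                   n_terminal = as.integer(m[, 3]),
                   n_nonterminal = as.integer(m[, 4]),
                   n_broken = as.integer(m[, 5]),
                   total_length = m[, 6], total_volume = m[, 7],
                   n_cells = m[, 7] / config$params$v_cell)
  } else {
    tibble::tibble(time = numeric(), n_branches = integer(),
                   n_terminal = integer(), n_nonterminal = integer(),
                   n_broken = integer(), total_length = numeric(),
                   total_volume = numeric(), n_cells = numeric())
  }
  structure(list(
    trees = trees,
    summary = summary_tbl,
    branch_samples = samples,
    tip_tracks = gather("tracks", c("branch_id", "time", "path_length")),
    events = gather("events", c("time", "branch_id", "last_division_time")),
    divisions = gather("divisions", c("time", "branch_id")),
    config = config, schedule = schedule
  ), class = "organoid_sim")
}

#' @export
print.organoid_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<organoid_sim> duration %g day, seed %d\n",
              x$config$duration, x$config$seed))
  if (nrow(s) > 0) {
    last <- s[nrow(s), ]
    cat(sprintf("  final: %d branches (%d terminal, %d broken), Ltot = %.0f um, %.0f cells\n",
                last$n_branches, last$n_terminal, last$n_broken,
                last$total_length, last$n_cells))
  }
  invisible(x)
}
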