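write_run_metadata <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- list(
    params = unclass(config$params),
    sim = unclass(config$sim)[setdiff(names(unclass(config$sim)),
                                      c("params", "schedule"))],
    noise = unclass(config$noise),
    schedule = if (is.null(config$schedule)) NULL else
      purrr::map2(config$schedule$times, config$schedule$overrides,
                  function(tt, ov) c(list(time = tt), ov)),
    output_dir = config$output_dir,
    log_level = config$log_level,
    package_version = as.character(utils::packageVersion("orgbranch")),
    seeds = list(sim = config$sim$seed, noise = config$noise$seed)
  )
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  invisible(out_dir)
}

#' Run a pipeline stage
#'
#' Executes one stage of the simulate--measure--fit workflow from a
#' [load_run_config()] configuration, writing its artifacts into
#' `out_dir` (every run directory receives the resolved configuration,
#' the package version and all seeds, so a run is reproducible from its
#' directory alone).
#'
#' Stages:
#' \describe{
#'   \item{simulate}{one stochastic organoid; JSON tree archives at daily
#'     snapshots plus an index CSV,}
#'   \item{meanfield}{mean-field trajectory CSV,}
#'   \item{synth}{synthetic observation tables plus `truth.json`,}
#'   \item{fit}{parameter recovery on a dataset directory (`data_dir`,
#'     default `out_dir`) into `fit_report.json`,}
#'   \item{perturb}{paired unperturbed/perturbed runs with a pre/post
#'     width comparison table,}
#'   \item{report}{diagnostic figures (returned as ggplot objects).}
#' }
#'
#' @param config A `run_config` from [load_run_config()] (or built in
#'   code).
#' @param command One of `"simulate"`, `"meanfield"`, `"synth"`, `"fit"`,
#'   `"perturb"`, `"report"`.
#' @param out_dir Output directory; defaults to the config's
#'   `output_dir`.
#' @param n_organoids Organoids for `synth`. Default 60.
#' @param t_end End time for `meanfield`, day. Default the sim duration.
#' @param data_dir Dataset directory for `fit`; defaults to `out_dir`.
#' @param preset,at Perturbation preset name and treatment day for
#'   `perturb`.
#' @return The stage's main artifact, invisibly (paths for writers, the
#'   fit for `fit`, plot list for `report`).
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "meanfield", "synth",
                                     "fit", "perturb", "report"),
                         out_dir = NULL, n_organoids = 60,
                         t_end = NULL, data_dir = NULL,
                         preset = "batimastat", at = 8) {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output_dir
  write_run_metadata(config, out_dir)

  switch(command,
    simulate = {
      days <- seq(0, config$sim$duration, by = 1)
      sim <- simulate_organoid(config$sim, schedule = config$schedule,
                               save_times = days)
      idx <- sim$summary[sim$summary$time %in% days,
                         c("time", "n_branches", "total_length",
                           "total_volume")]
      names(idx) <- c("time [day]", "n_branches", "total_length [um]",
                      "total_volume [um^3]")
      utils::write.csv(idx, file.path(out_dir, "index.csv"),
                       row.names = FALSE)
      for (tr in sim$trees) {
        save_tree(tr, file.path(out_dir,
                                sprintf("tree_t%05.1f.json",
                                        attr(tr, "time"))))
      }
      invisible(sim)
    },
    meanfield = {
      t_end <- t_end %||% config$sim$duration
      traj <- integrate_meanfield(config$params, t_end = t_end)
      write_trajectory_csv(traj, file.path(out_dir, "meanfield.csv"))
      invisible(traj)
    },
    synth = {
      ds <- generate_morphometric_dataset(
        truth = config$params, noise = config$noise,
        n_organoids = n_organoids
      )
      write_dataset(ds, out_dir)
      invisible(ds)
    },
    fit = {
      ds <- read_dataset(data_dir %||% out_dir)
      fit <- fit_growth_parameters(ds, bootstrap = 1000,
                                   seed = config$noise$seed)
      save_fit_report(fit, file.path(out_dir, "fit_report.json"),
                      seed = config$noise$seed)
      invisible(fit)
    },
    perturb = {
      sched <- perturbation_preset(preset, at = at,
                                   params = config$params)
      base <- simulate_organoid(config$sim, record_nodes = FALSE)
      pert <- simulate_organoid(config$sim, schedule = sched,
                                record_nodes = FALSE)
      cmp <- dplyr::bind_rows(
        dplyr::mutate(width_by_class(base$branch_samples),
                      condition = "control"),
        dplyr::mutate(width_by_class(pert$branch_samples),
                      condition = preset)
      )
      utils::write.csv(cmp, file.path(out_dir, "perturbation_widths.csv"),
                       row.names = FALSE)
      invisible(cmp)
    },
    report = {
      ds <- generate_morphometric_dataset(
        truth = config$params, noise = config$noise,
        n_organoids = n_organoids
      )
      fit <- suppressWarnings(fit_growth_parameters(ds))
      traj <- integrate_meanfield(config$params,
                                  t_end = max(ds$t_grid))
      plots <- list(
        feedback = autoplot(fit$feedback, pairs = ds$growth_pairs),
        branch_counts = plot_branch_counts(ds$branch_counts,
                                           fit = fit$branching),
        cell_counts = plot_cellcounts(ds$cellcount_stats, traj)
      )
      invisible(plots)
    }
  )
}

#' Mean branch width by terminal/non-terminal class over time
#'
#' Summarises per-branch samples into the mean width of unbroken terminal
#' and non-terminal branches at each sampled time.
#'
#' @param branch_samples A `branch_samples` tibble from
#'   [simulate_organoid()] or an ensemble.
#' @return A tibble `time, class, mean_width, n`.
#' @export
width_by_class <- function(branch_samples) {
  branch_samples |>
    dplyr::filter(!.data$broken) |>
    dplyr::mutate(class = ifelse(.data$terminal, "terminal",
                                 "non-terminal")) |>
    dplyr::group_by(.data$time, .data$class) |>
    dplyr::summarise(mean_width = mean(.data$width), n = dplyr::n(),
                     .groups = "drop")
}
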