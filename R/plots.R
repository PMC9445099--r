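# ggplot2 figures for the main result types.

#' Plot an organoid tree
#'
#' Draws the centerline polylines (projected on the first two coordinates
#' for 3D trees) with line width proportional to branch width.
#'
#' @param object An [organoid_tree] with recorded nodes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.organoid_tree <- function(object, ...) {
  keep <- !purrr::map_lgl(object$nodes, is.null)
  if (!any(keep)) stop("tree has no recorded nodes to draw", call. = FALSE)
  seg <- purrr::map_dfr(which(keep), function(i) {
    nd <- object$nodes[[i]]
    tibble::tibble(branch_id = object$id[i], x = nd[, 1], y = nd[, 2],
                   width = object$width[i], broken = object$broken[i])
  })
  ggplot2::ggplot(seg, ggplot2::aes(.data$x, .data$y,
                                    group = .data$branch_id,
                                    linewidth = .data$width,
                                    colour = .data$broken)) +
    ggplot2::geom_path(lineend = "round", show.legend = FALSE) +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 3)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey20",
                                            `TRUE` = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [um]", y = "y [um]",
                  title = sprintf("organoid at day %g",
                                  attr(object, "time"))) +
    ggplot2::theme_minimal()
}

#' Plot a mean-field trajectory
#'
#' Cell number, total length, branch count and mean width against time,
#' with log scaling on the counts.
#'
#' @param object A `meanfield_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meanfield_trajectory <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("Nc", "Ltot", "Nb", "w"), names_to = "quantity",
                        values_to = "value") |>
    dplyr::mutate(quantity = factor(.data$quantity,
                                    c("Nc", "Ltot", "Nb", "w"),
                                    c("cells", "total length [um]",
                                      "branches", "mean width [um]")))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [day]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a proliferation-feedback fit
#'
#' Growth-rate versus width scatter with the fitted feedback line; the
#' width-axis crossing is the recovered `w0` and the intercept the
#' recovered `kd0`.
#'
#' @param object A `feedback_fit`.
#' @param pairs Optional pairs table to show as points (defaults to the
#'   data stored in the fit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feedback_fit <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) pairs <- object$lm$model
  names(pairs)[names(pairs) == "growth_rate"] <- "growth_rate"
  ggplot2::ggplot(pairs, ggplot2::aes(.data$width, .data$growth_rate)) +
    ggplot2::geom_point(alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope,
                         colour = "darkgreen", linetype = "dashed") +
    ggplot2::labs(x = "branch width [um]",
                  y = "normalized volumetric growth rate [1/day]",
                  subtitle = sprintf("kd0 = %.2f /day, w0 = %.1f um",
                                     object$kd0, object$w0)) +
    ggplot2::theme_minimal()
}

#' Plot branch counts over time with the exponential fit
#'
#' @param counts Per-organoid counts (`time`, `n_terminal`) or summary
#'   statistics (`time`, `mean_nb`, `sd_nb`).
#' @param fit Optional `exponential_fit` overlay.
#' @return A ggplot object.
#' @export
plot_branch_counts <- function(counts, fit = NULL) {
  if (!"mean_nb" %in% names(counts)) {
    counts <- counts |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(mean_nb = mean(.data$n_terminal),
                       sd_nb = stats::sd(.data$n_terminal),
                       .groups = "drop")
  }
  gp <- ggplot2::ggplot(counts, ggplot2::aes(.data$time, .data$mean_nb)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean_nb - .data$sd_nb, 1e-2),
      ymax = .data$mean_nb + .data$sd_nb), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [day]", y = "branches per organoid") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    gp <- gp + ggplot2::geom_function(
      fun = function(x) exp(fit$log_intercept + fit$rate * x),
      colour = "firebrick", linetype = "dashed")
  }
  gp
}

#' Plot observed cell counts against the mean-field prediction
#'
#' @param cell_stats Tibble `time, mean_nc, sd_nc`.
#' @param traj A `meanfield_trajectory` overlay.
#' @return A ggplot object.
#' @export
plot_cellcounts <- function(cell_stats, traj = NULL) {
  gp <- ggplot2::ggplot(cell_stats,
                        ggplot2::aes(.data$time, .data$mean_nc)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$mean_nc - .data$sd_nc, 1e-2),
      ymax = .data$mean_nc + .data$sd_nc), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time [day]", y = "cells per organoid") +
    ggplot2::theme_minimal()
  if (!is.null(traj)) {
    gp <- gp + ggplot2::geom_line(
      data = tibble::tibble(time = traj$t, mean_nc = traj$Nc),
      colour = "firebrick", linetype = "dashed")
  }
  gp
}

#' Plot mean branch width by class over time
#'
#' Terminal branches plateau at a smaller width than non-terminal
#' branches, which are not thinned by tip elongation.
#'
#' @param widths Output of [width_by_class()].
#' @param params Optional [growth_params()]; draws the mean-field plateau
#'   and `w0` as reference lines.
#' @return A ggplot object.
#' @export
plot_width_classes <- function(widths, params = NULL) {
  gp <- ggplot2::ggplot(widths, ggplot2::aes(.data$time, .data$mean_width,
                                             colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [day]", y = "mean branch width [um]",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(params)) {
    gp <- gp +
      ggplot2::geom_hline(yintercept = plateau_width(params),
                          linetype = "dotted") +
      ggplot2::geom_hline(yintercept = params$w0, linetype = "dashed")
  }
  gp
}
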