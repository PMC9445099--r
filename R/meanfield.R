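#' Initial state of the mean-field model
#'
#' The mean-field model starts from a single tip: one nascent branch of
#' length `Ltot` containing `Nc` cells. The mean width is not free — it
#' follows from the cylindrical closure
#' \eqn{N_c v_{cell} = (\pi/4) w^2 L_{tot}}.
#'
#' @param params A [growth_params()] object.
#' @param Nc Initial total cell number. Default 1.
#' @param Nb Initial branch (tip) count. Default 1.
#' @param Ltot Initial total length, um. Default `params$l_init`.
#' @return A one-row tibble with columns `t`, `Nc`, `Ltot`, `Nb`, `w`.
#' @export
meanfield_init <- function(params, Nc = 1, Nb = 1, Ltot = params$l_init) {
  stopifnot(inherits(params, "growth_params"),
            Nc >= 1, Nb >= 1, Ltot > 0)
  tibble::tibble(t = 0, Nc = as.numeric(Nc), Ltot = as.numeric(Ltot),
                 Nb = as.numeric(Nb),
                 w = closure_width(Nc, Ltot, params$v_cell))
}

#' Integrate the mean-field growth model
#'
#' Deterministic description of ensemble-average organoid growth. Total
#' organoid length grows with the (exponentially multiplying) tip
#' population,
#' \deqn{dL_{tot}/dt = v_0\, N_b(0)\, e^{k_b t},}
#' while cell number grows under the width feedback,
#' \deqn{dN_c/dt = k_d^0 \max(0,\, 1 - w/w_0)\, N_c,}
#' with the mean width `w` given at all times by the cylindrical closure
#' \eqn{N_c v_{cell} = (\pi/4) w^2 L_{tot}}. The model predicts two growth
#' phases: early near-maximal exponential growth of `Nc` at rate ~`kd0`
#' while branches are thin, then slower exponential growth at the branching
#' rate `kb` once the width has reached its plateau
#' \eqn{w_0(1-k_b/k_d^0)} (see [plateau_width()]).
#'
#' Integration uses an adaptive solver ([deSolve::ode()], `lsoda`, tight
#' tolerances) with dense output on the fixed reporting grid `{0, dt, ...,
#' t_end}`.
#'
#' @param params A [growth_params()] object.
#' @param init Initial state from [meanfield_init()] (or a compatible
#'   one-row data frame satisfying the width closure).
#' @param t_end End time, day (> 0).
#' @param dt Reporting grid spacing, day. Default 0.01.
#' @param closure Optional function `(Nc, Ltot) -> w` replacing the
#'   cylindrical closure (e.g. a sheet closure `w ~ Nc/Ltot`). The
#'   plateau width does not depend on this choice — the feedback's zero
#'   is at `kd(w) = kb` regardless of the geometry exponent — but the
#'   transient does. The default is the cylinder.
#' @return A `meanfield_trajectory`: a tibble with columns `t`, `Nc`,
#'   `Ltot`, `Nb`, `w` and the parameters attached as attribute `params`.
#' @examples
#' p <- growth_params()
#' traj <- integrate_meanfield(p, meanfield_init(p), t_end = 10)
#' tail(traj)
#' @export
integrate_meanfield <- function(params, init = meanfield_init(params),
                                t_end, dt = 0.01, closure = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  stopifnot(all(c("Nc", "Ltot", "Nb", "w") %in% names(init)), nrow(init) == 1)
  wfun <- closure %||% function(Nc, Ltot) {
    closure_width(Nc, Ltot, params$v_cell)
  }
  closure_err <- abs(init$w - wfun(init$Nc, init$Ltot)) / init$w
  if (closure_err > 1e-9) {
    stop("initial state violates the width closure ",
         "Nc*v_cell = (pi/4) w^2 Ltot", call. = FALSE)
  }

  Nb0 <- init$Nb
  rhs <- function(t, y, parms) {
    w <- wfun(y[["Nc"]], y[["Ltot"]])
    list(c(
      Nc = division_rate(w, params) * y[["Nc"]],
      Ltot = params$v0 * Nb0 * exp(params$kb * t)
    ))
  }
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  sol <- deSolve::ode(
    y = c(Nc = init$Nc, Ltot = init$Ltot), times = times, func = rhs,
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10
  )
  sol <- as.data.frame(sol)
  if (anyNA(sol) || any(!is.finite(as.matrix(sol)))) {
    bad <- which(apply(sol, 1, function(r) any(!is.finite(r))))[1]
    stop(sprintf("mean-field integration produced a non-finite state at t = %g",
                 sol$time[bad]), call. = FALSE)
  }
  out <- tibble::tibble(
    t = sol$time,
    Nc = sol$Nc,
    Ltot = sol$Ltot,
    Nb = Nb0 * exp(params$kb * sol$time),
    w = wfun(sol$Nc, sol$Ltot)
  )
  structure(out, params = params, init = init,
            class = c("meanfield_trajectory", class(out)))
}

#' Early and late exponential growth rates of cell number
#'
#' Fits least-squares lines to `log(Nc)` versus time on two windows of a
#' mean-field trajectory. In the two-phase regime the early slope
#' approaches the maximal division rate `kd0` (thin branches, feedback
#' negligible) and the late slope approaches the branching rate `kb`
#' (width at plateau, growth limited by tip multiplication).
#'
#' @param traj A `meanfield_trajectory` from [integrate_meanfield()].
#' @param early_window,late_window Length-2 numeric vectors `c(t0, t1)`,
#'   day; each must lie inside the trajectory span and contain at least 3
#'   grid points.
#' @return A tibble with columns `phase` (`"early"`, `"late"`), `rate`
#'   (1/day), `n` (grid points used).
#' @export
growth_phase_rates <- function(traj, early_window, late_window) {
  stopifnot(inherits(traj, "meanfield_trajectory"))
  slope_on <- function(win, label) {
    stopifnot(length(win) == 2, win[1] < win[2])
    if (win[1] < min(traj$t) - 1e-12 || win[2] > max(traj$t) + 1e-12) {
      stop(label, " window lies outside the trajectory span", call. = FALSE)
    }
    sub <- traj[traj$t >= win[1] - 1e-12 & traj$t <= win[2] + 1e-12, ]
    if (nrow(sub) < 3) {
      stop(label, " window contains fewer than 3 grid points", call. = FALSE)
    }
    fit <- stats::lm(log(Nc) ~ t, data = sub)
    tibble::tibble(phase = label, rate = unname(stats::coef(fit)[2]),
                   n = nrow(sub))
  }
  dplyr::bind_rows(slope_on(early_window, "early"),
                   slope_on(late_window, "late"))
}
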