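#' Growth parameters of the branching-organoid model
#'
#' Bundles the rate and geometry constants of the minimal model of branching
#' organoid morphogenesis: tips invade the matrix at constant speed `v0`,
#' every elongating tip branches stochastically at rate `kb`, and cells
#' proliferate at a rate that decreases linearly with local branch width,
#' \eqn{k_d(w) = k_d^0 \max(0, 1 - w/w_0)}. Widths follow from a cylindrical
#' closure between cell number (volume) and total length, so `v_cell` sets
#' the volume bookkeeping scale.
#'
#' The defaults are the calibrated extension-phase values for pancreatic
#' ductal adenocarcinoma (PDAC) organoids: `v0 = 80` um/day and
#' `kb = 0.55`/day measured directly, with `kd0 = 1.5`/day and `w0 = 60` um
#' as representative values of the proliferation feedback (the feedback
#' parameters are free parameters of the model, recovered by
#' [fit_proliferation_feedback()]).
#'
#' @param v0 Tip elongation (matrix invasion) speed, um/day.
#' @param kb Branching rate per elongating tip, 1/day.
#' @param kd0 Maximal per-cell division rate (at vanishing width), 1/day.
#' @param w0 Branch width at which proliferation is abrogated, um.
#' @param v_cell Volume per cell, um^3. Default 1000 um^3 (a ~12.4 um cell).
#' @param l_init Initial length of a nascent branch, um.
#' @param w_min Breakage width: a branch thinner than this ruptures and stops
#'   growing, um. Must satisfy `0 <= w_min < w0`.
#' @param dim Spatial dimension of the simulator, 2 or 3.
#'
#' @return A `growth_params` object (a named list).
#'
#' @details A finite positive plateau width \eqn{w_0(1 - k_b/k_d^0)} exists
#'   only when `kb < kd0`; construction with `kb >= kd0` is allowed (the
#'   width then decays towards breakage) but raises a warning.
#'
#' @examples
#' p <- growth_params()
#' plateau_width(p)
#' @seealso [plateau_width()], [integrate_meanfield()], [simulate_organoid()]
#' @export
growth_params <- function(v0 = 80, kb = 0.55, kd0 = 1.5, w0 = 60,
                          v_cell = 1000, l_init = 25, w_min = 0.5, dim = 3) {
  p <- list(v0 = as.numeric(v0), kb = as.numeric(kb), kd0 = as.numeric(kd0),
            w0 = as.numeric(w0), v_cell = as.numeric(v_cell),
            l_init = as.numeric(l_init), w_min = as.numeric(w_min),
            dim = as.integer(dim))
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  stopifnot(
    "v0 must be >= 0" = is.finite(p$v0) && p$v0 >= 0,
    "kb must be >= 0" = is.finite(p$kb) && p$kb >= 0,
    "kd0 must be >= 0" = is.finite(p$kd0) && p$kd0 >= 0,
    "w0 must be > 0" = !is.na(p$w0) && p$w0 > 0,
    "v_cell must be > 0" = is.finite(p$v_cell) && p$v_cell > 0,
    "l_init must be > 0" = is.finite(p$l_init) && p$l_init > 0,
    "w_min must satisfy 0 <= w_min < w0" =
      is.finite(p$w_min) && p$w_min >= 0 && p$w_min < p$w0,
    "dim must be 2 or 3" = p$dim %in% c(2L, 3L)
  )
  if (p$kb >= p$kd0) {
    warning("kb >= kd0: no positive plateau width exists; ",
            "branches thin towards breakage", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("<growth_params>\n")
  cat(sprintf("  v0     = %g um/day   (tip speed)\n", x$v0))
  cat(sprintf("  kb     = %g /day     (branching rate per tip)\n", x$kb))
  cat(sprintf("  kd0    = %g /day     (maximal division rate)\n", x$kd0))
  cat(sprintf("  w0     = %g um       (width abolishing proliferation)\n", x$w0))
  cat(sprintf("  v_cell = %g um^3, l_init = %g um, w_min = %g um, dim = %d\n",
              x$v_cell, x$l_init, x$w_min, x$dim))
  if (x$kd0 > 0 && x$kb < x$kd0) {
    cat(sprintf("  plateau width w* = %g um\n", plateau_width(x)))
  }
  invisible(x)
}

#' Update growth parameters
#'
#' Returns a copy of `params` with the named fields replaced; used by
#' perturbation schedules. Unknown field names are an error.
#'
#' @param params A [growth_params()] object.
#' @param overrides Named list of fields to replace.
#' @return A validated `growth_params` object.
#' @export
update_growth_params <- function(params, overrides) {
  stopifnot(inherits(params, "growth_params"), is.list(overrides))
  bad <- setdiff(names(overrides), names(unclass(params)))
  if (length(bad) > 0) {
    stop("unknown growth parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(unclass(params), overrides)
  do.call(growth_params, p)
}

#' Width-dependent division rate
#'
#' The proliferation feedback \eqn{k_d(w) = k_d^0 \max(0, 1 - w/w_0)}:
#' division is maximal in thin branches and abrogated at width `w0`
#' (contact inhibition / matrix-stress feedback). The rate is clamped at
#' zero; cell loss is not modelled.
#'
#' @param w Branch width, um (vectorised).
#' @param params A [growth_params()] object.
#' @return Division rate(s), 1/day.
#' @export
division_rate <- function(w, params) {
  params$kd0 * pmax(0, 1 - w / params$w0)
}

#' Plateau branch width of the mean-field model
#'
#' At long times proliferation catches up with branching-driven elongation
#' and the mean branch width settles at the fixed point
#' \eqn{w^* = w_0 (1 - k_b/k_d^0)}, where the division rate exactly balances
#' the branching rate. When `kb >= kd0` no positive plateau exists: the
#' function returns 0 with a warning.
#'
#' @param params A [growth_params()] object.
#' @return Plateau width, um.
#' @examples
#' plateau_width(growth_params(kd0 = 1.5, kb = 0.55, w0 = 60)) # 38 um
#' @export
plateau_width <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  if (params$kd0 == 0) {
    stop("plateau width is undefined for kd0 = 0", call. = FALSE)
  }
  if (params$kb >= params$kd0) {
    warning("kb >= kd0: branching consumes all proliferation; ",
            "plateau width is 0", call. = FALSE)
    return(0)
  }
  params$w0 * (1 - params$kb / params$kd0)
}

# Cylindrical closure between cell volume and geometry:
# Nc * v_cell = (pi/4) * w^2 * Ltot  =>  w = sqrt(4 Nc v_cell / (pi Ltot)).
closure_width <- function(Nc, Ltot, v_cell) {
  sqrt(4 * Nc * v_cell / (pi * Ltot))
}
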