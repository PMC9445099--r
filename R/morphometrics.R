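# Morphometric measurement of organoid trees, following the standard
# live/static measurement conventions: terminal width 30 um behind the tip
# (base fallback for nascent branches), body width at 100 um, non-terminal
# width 100 um after the base of the "Y", branch counting by
# terminal/non-terminal class.

branch_row <- function(tree, branch_id) {
  i <- match(branch_id, tree$id)
  if (is.na(i)) stop("no branch with id ", branch_id, call. = FALSE)
  i
}

# Width of a branch at arc length `s_from_tip` behind its distal end.
# Simulated branches carry one scalar width; fixtures may carry per-node
# widths (`node_widths` list-column), interpolated linearly along arc
# length.
width_at_offset <- function(tree, i, s_from_tip) {
  if (!is.null(tree[["node_widths"]]) && !is.null(tree$node_widths[[i]])) {
    nd <- tree$nodes[[i]]
    wds <- tree$node_widths[[i]]
    stopifnot(!is.null(nd), nrow(nd) == length(wds))
    seg <- sqrt(rowSums((nd[-1, , drop = FALSE] -
                           nd[-nrow(nd), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))                 # arc length from base
    s <- max(arc) - s_from_tip               # position measured from tip
    stats::approx(arc, wds, xout = s, rule = 2)$y
  } else {
    tree$width[i]
  }
}

#' Terminal branch width, measured behind the tip
#'
#' Width of a terminal branch evaluated `offset` um of arc length behind
#' the branch tip (default 30 um). Nascent branches shorter than the
#' offset are measured at the branch base instead, close to the branching
#' point.
#'
#' @param tree An [organoid_tree].
#' @param branch_id Branch id; must be a terminal, unbroken branch.
#' @param offset Arc-length offset behind the tip, um.
#' @return Width in um, with attribute `truncated = TRUE` when the base
#'   fallback was used.
#' @export
terminal_branch_width <- function(tree, branch_id, offset = 30) {
  stopifnot(inherits(tree, "organoid_tree"))
  i <- branch_row(tree, branch_id)
  if (!tree$terminal[i]) {
    stop("branch ", branch_id, " is not terminal; use nonterminal_width()",
         call. = FALSE)
  }
  if (tree$broken[i]) {
    stop("branch ", branch_id, " is broken", call. = FALSE)
  }
  len <- tree$length[i]
  if (len < offset) {
    w <- width_at_offset(tree, i, len)  # at the branch base
    attr(w, "truncated") <- TRUE
  } else {
    w <- width_at_offset(tree, i, offset)
    attr(w, "truncated") <- FALSE
  }
  w
}

#' Body width of a branch
#'
#' For a terminal branch: the width `offset` um (default 100) behind the
#' tip, with the same base fallback as [terminal_branch_width()]. For a
#' non-terminal branch: the width `offset` um after the branch base (the
#' base of the "Y" formed at its proximal branching point), measured from
#' the proximal end; branches shorter than the offset are measured at
#' their distal end with `truncated = TRUE`.
#'
#' @inheritParams terminal_branch_width
#' @param offset Arc-length offset, um. Default 100.
#' @return Width in um with attribute `truncated`.
#' @export
body_width <- function(tree, branch_id, offset = 100) {
  stopifnot(inherits(tree, "organoid_tree"))
  i <- branch_row(tree, branch_id)
  len <- tree$length[i]
  if (tree$terminal[i]) {
    return(terminal_branch_width(tree, branch_id, offset = offset))
  }
  # non-terminal: measure from the proximal end (the Y base)
  if (len < offset) {
    w <- width_at_offset(tree, i, 0)  # distal end
    attr(w, "truncated") <- TRUE
  } else {
    w <- width_at_offset(tree, i, len - offset)
    attr(w, "truncated") <- FALSE
  }
  w
}

#' Count terminal and non-terminal branches
#'
#' A branch is the segment between a tip and a branching point (terminal)
#' or between two branching points (non-terminal); the classification is
#' exhaustive and disjoint.
#'
#' @param tree An [organoid_tree].
#' @return A tibble with columns `n_terminal`, `n_nonterminal`.
#' @export
count_branches <- function(tree) {
  stopifnot(inherits(tree, "organoid_tree"))
  tibble::tibble(
    n_terminal = sum(tree$terminal),
    n_nonterminal = sum(!tree$terminal)
  )
}

#' Major axis length of an organoid tree
#'
#' The maximum Euclidean distance between any two centerline nodes — a
#' skeleton proxy for the major axis of an ellipse fitted to the organoid
#' outline (an upper bound on the skeleton, since no image mask exists for
#' a simulated tree).
#'
#' @param tree An [organoid_tree] with recorded nodes.
#' @return Length in um.
#' @export
major_axis_length <- function(tree) {
  stopifnot(inherits(tree, "organoid_tree"))
  nodes <- do.call(rbind, tree$nodes[!purrr::map_lgl(tree$nodes, is.null)])
  if (is.null(nodes) || nrow(nodes) == 0) {
    stop("tree has no recorded nodes", call. = FALSE)
  }
  if (nrow(nodes) == 1) return(0)
  max(stats::dist(nodes))
}

#' Normalized volumetric growth rate of a branch
#'
#' The relative volume increase per unit time,
#' \eqn{(V(t+\Delta) - V(t)) / (V(t)\,\Delta)}, the observable used to
#' expose the proliferation--width feedback: plotted against branch width
#' it falls on the line \eqn{k_d^0 (1 - w/w_0)}.
#'
#' @param v_start,v_end Branch volumes at the start and end of the
#'   observation interval, um^3 (vectorised).
#' @param delta_t Interval length, day (> 0).
#' @return Rate(s), 1/day.
#' @examples
#' normalized_volumetric_growth(100, 200, 1)   # 1.0 /day
#' normalized_volumetric_growth(100, 80, 0.5)  # -0.4 /day
#' @export
normalized_volumetric_growth <- function(v_start, v_end, delta_t) {
  if (any(delta_t <= 0)) stop("delta_t must be > 0", call. = FALSE)
  if (any(v_start <= 0)) stop("start volume must be > 0", call. = FALSE)
  (v_end - v_start) / (v_start * delta_t)
}

#' Measure a tree into a tidy morphometric table
#'
#' Applies the width and counting conventions to every branch of a tree
#' and returns tidy records, one measured quantity per row.
#'
#' @param tree An [organoid_tree].
#' @param organoid_id Identifier copied into the output.
#' @param tip_offset,body_offset Offsets for [terminal_branch_width()] and
#'   [body_width()], um.
#' @return A tibble `organoid_id, time, branch_id, kind, value, truncated`
#'   with kinds `terminal_width`, `body_width`, `nonterminal_width`,
#'   `branch_length`, `branch_count_terminal`, `branch_count_nonterminal`,
#'   `cell_count` and (when nodes are recorded) `major_axis`. Widths and
#'   lengths in um; counts dimensionless.
#' @export
measure_tree <- function(tree, organoid_id = 1L, tip_offset = 30,
                         body_offset = 100) {
  stopifnot(inherits(tree, "organoid_tree"))
  t_now <- attr(tree, "time")
  rec <- function(branch_id, kind, value, truncated = NA) {
    tibble::tibble(organoid_id = organoid_id, time = t_now,
                   branch_id = branch_id, kind = kind,
                   value = as.numeric(value), truncated = truncated)
  }
  rows <- list()
  for (i in seq_len(nrow(tree))) {
    id <- tree$id[i]
    if (tree$terminal[i] && !tree$broken[i]) {
      w <- terminal_branch_width(tree, id, offset = tip_offset)
      rows[[length(rows) + 1L]] <-
        rec(id, "terminal_width", w, attr(w, "truncated"))
      b <- body_width(tree, id, offset = body_offset)
      rows[[length(rows) + 1L]] <-
        rec(id, "body_width", b, attr(b, "truncated"))
    } else if (!tree$terminal[i]) {
      w <- body_width(tree, id, offset = body_offset)
      rows[[length(rows) + 1L]] <-
        rec(id, "nonterminal_width", w, attr(w, "truncated"))
    }
    rows[[length(rows) + 1L]] <- rec(id, "branch_length", tree$length[i])
  }
  cts <- count_branches(tree)
  rows[[length(rows) + 1L]] <-
    rec(NA_integer_, "branch_count_terminal", cts$n_terminal)
  rows[[length(rows) + 1L]] <-
    rec(NA_integer_, "branch_count_nonterminal", cts$n_nonterminal)
  v_cell <- attr(tree, "v_cell")
  if (!is.null(v_cell) && is.finite(v_cell)) {
    rows[[length(rows) + 1L]] <-
      rec(NA_integer_, "cell_count", sum(tree$volume) / v_cell)
  }
  if (!all(purrr::map_lgl(tree$nodes, is.null))) {
    rows[[length(rows) + 1L]] <-
      rec(NA_integer_, "major_axis", major_axis_length(tree))
  }
  dplyr::bind_rows(rows)
}

#' Width/growth-rate pairs from per-branch samples
#'
#' Builds the (width, normalized volumetric growth rate) observation pairs
#' that expose the proliferation feedback, from the per-branch time samples
#' recorded by [simulate_organoid()]: consecutive samples of each branch
#' give one pair per interval, with the width taken at the interval start.
#'
#' @param branch_samples Tibble with columns `time`, `branch_id`, `width`,
#'   `volume` (and optionally `organoid_id`, `broken`).
#' @param window Optional length-2 time window (day); only pairs whose
#'   start time falls inside it are kept.
#' @return A tibble `organoid_id?, branch_id, time, width, growth_rate,
#'   delta_t`.
#' @export
growth_rate_pairs <- function(branch_samples, window = NULL) {
  stopifnot(all(c("time", "branch_id", "width", "volume") %in%
                  names(branch_samples)))
  grp <- intersect(c("organoid_id", "branch_id"), names(branch_samples))
  tbl <- branch_samples
  if ("broken" %in% names(tbl)) tbl <- tbl[!tbl$broken, ]
  ord <- do.call(order, c(unname(as.list(tbl[grp])), list(tbl$time)))
  tbl <- tbl[ord, ]
  n <- nrow(tbl)
  if (n < 2) {
    return(tibble::tibble(!!!rlang::set_names(
      purrr::map(grp, ~ integer()), grp),
      time = numeric(), width = numeric(), growth_rate = numeric(),
      delta_t = numeric()))
  }
  # consecutive rows of the same (organoid, branch) form one pair
  same <- rep(TRUE, n - 1)
  for (g in grp) same <- same & (tbl[[g]][-n] == tbl[[g]][-1])
  i <- which(same)
  out <- tibble::tibble(
    !!!rlang::set_names(purrr::map(grp, ~ tbl[[.x]][i]), grp),
    time = tbl$time[i],
    width = tbl$width[i],
    growth_rate = normalized_volumetric_growth(
      tbl$volume[i], tbl$volume[i + 1], tbl$time[i + 1] - tbl$time[i]),
    delta_t = tbl$time[i + 1] - tbl$time[i]
  )
  if (!is.null(window)) {
    out <- out[out$time >= window[1] - 1e-9 & out$time <= window[2] + 1e-9, ]
  }
  out
}
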