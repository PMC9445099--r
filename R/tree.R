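#' Organoid tree objects
#'
#' An `organoid_tree` is a snapshot of a simulated organoid: a tibble with
#' one row per branch (`id`, `parent_id`, `birth_time`, `width`, `volume`,
#' `length`, `terminal`, `broken`, and a `nodes` list-column of centerline
#' polylines, one `k x dim` coordinate matrix per branch, um), carrying the
#' snapshot `time` (day) and the RNG `seed` as attributes. Parent links
#' form a single rooted tree. A tree produced without node recording has
#' `NULL` entries in `nodes`.
#'
#' @param branches A data frame with the columns above (`nodes` optional).
#' @param time Snapshot time, day.
#' @param seed RNG seed of the run that produced the tree (or `NA`).
#' @return An `organoid_tree`.
#' @name organoid_tree
#' @export
organoid_tree <- function(branches, time = NA_real_, seed = NA_integer_,
                          v_cell = NA_real_) {
  branches <- tibble::as_tibble(branches)
  req <- c("id", "parent_id", "birth_time", "width", "volume", "length",
           "terminal", "broken")
  missing <- setdiff(req, names(branches))
  if (length(missing) > 0) {
    stop("branches is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"nodes" %in% names(branches)) {
    branches$nodes <- vector("list", nrow(branches))
  }
  out <- structure(branches,
                   time = as.numeric(time), seed = seed,
                   v_cell = as.numeric(v_cell),
                   class = c("organoid_tree", class(tibble::tibble())))
  validate_organoid_tree(out)
  out
}

validate_organoid_tree <- function(tree) {
  stopifnot(nrow(tree) >= 1)
  roots <- which(is.na(tree$parent_id))
  if (length(roots) != 1) {
    stop("tree must have exactly one root branch", call. = FALSE)
  }
  known <- tree$id
  par <- tree$parent_id[!is.na(tree$parent_id)]
  if (!all(par %in% known)) {
    stop("tree has parent links to unknown branch ids", call. = FALSE)
  }
  # acyclic & connected: walk each branch to the root
  id_pos <- match(tree$id, tree$id)
  parent_pos <- match(tree$parent_id, tree$id)
  for (i in seq_len(nrow(tree))) {
    seen <- logical(nrow(tree))
    j <- i
    while (!is.na(parent_pos[j])) {
      if (seen[j]) stop("tree contains a cycle", call. = FALSE)
      seen[j] <- TRUE
      j <- parent_pos[j]
    }
  }
  if (any(tree$length <= 0)) stop("branch lengths must be > 0", call. = FALSE)
  if (any(tree$width[!tree$broken] <= 0)) {
    stop("unbroken branches must have width > 0", call. = FALSE)
  }
  has_child <- tree$id %in% tree$parent_id
  if (any(has_child & tree$terminal)) {
    stop("a branch with children cannot be terminal", call. = FALSE)
  }
  invisible(tree)
}

snapshot_tree <- function(st, t_now, config) {
  idx <- seq_len(st$n)
  d <- st$dim
  tip <- matrix(st$tip, ncol = d, byrow = TRUE)
  nodes <- vector("list", st$n)
  if (isTRUE(st$record_nodes)) {
    for (i in idx) {
      nd <- matrix(st$nodes[[i]], ncol = d, byrow = TRUE)
      # close the polyline at the current tip position
      if (st$terminal[i] && sum((nd[nrow(nd), ] - tip[i, ])^2) > 1e-18) {
        nd <- rbind(nd, tip[i, ])
      }
      nodes[[i]] <- unname(nd)
    }
  }
  organoid_tree(
    tibble::tibble(
      id = idx,
      parent_id = ifelse(st$parent[idx] == 0L, NA_integer_, st$parent[idx]),
      birth_time = st$birth[idx],
      width = st$width[idx], volume = st$volume[idx],
      length = st$length[idx], terminal = as.logical(st$terminal[idx]),
      broken = as.logical(st$broken[idx]), nodes = nodes
    ),
    time = t_now, seed = config$seed, v_cell = config$params$v_cell
  )
}

#' @export
print.organoid_tree <- function(x, ...) {
  cat(sprintf("<organoid_tree> t = %g day, %d branches (%d terminal, %d broken)\n",
              attr(x, "time"), nrow(x), sum(x$terminal), sum(x$broken)))
  NextMethod()
}

#' Save / load an organoid tree as a JSON archive
#'
#' Trees are archived as JSON with branches keyed by id; each branch
#' carries `parent_id`, its node coordinate array (um), `width`, `volume`,
#' `birth_time` and the `terminal`/`broken` flags, with the snapshot time
#' and seed at top level. `load_tree(save_tree(x))` restores ids, flags and
#' widths exactly and coordinates to better than 1e-9 um.
#'
#' @param tree An [organoid_tree].
#' @param path File path for the JSON archive.
#' @return `save_tree()` returns `path` invisibly; `load_tree()` returns an
#'   [organoid_tree].
#' @export
save_tree <- function(tree, path) {
  stopifnot(inherits(tree, "organoid_tree"))
  branches <- purrr::pmap(
    list(seq_len(nrow(tree))),
    function(i) {
      b <- tree[i, ]
      list(
        id = b$id, parent_id = if (is.na(b$parent_id)) NULL else b$parent_id,
        birth_time = b$birth_time, width = b$width, volume = b$volume,
        length = b$length, terminal = b$terminal, broken = b$broken,
        nodes = if (is.null(b$nodes[[1]])) NULL else b$nodes[[1]]
      )
    }
  )
  names(branches) <- as.character(tree$id)
  obj <- list(
    format = "orgbranch-tree",
    time = attr(tree, "time"),
    seed = attr(tree, "seed"),
    v_cell = attr(tree, "v_cell"),
    units = list(length = "um", time = "day", volume = "um^3"),
    branches = branches
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname save_tree
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "orgbranch-tree")) {
    stop("not an orgbranch tree archive: ", path, call. = FALSE)
  }
  rows <- purrr::map(obj$branches, function(b) {
    tibble::tibble(
      id = as.integer(b$id),
      parent_id = if (is.null(b$parent_id)) NA_integer_ else
        as.integer(b$parent_id),
      birth_time = as.numeric(b$birth_time),
      width = as.numeric(b$width),
      volume = as.numeric(b$volume),
      length = as.numeric(b$length),
      terminal = isTRUE(b$terminal),
      broken = isTRUE(b$broken),
      nodes = list(
        if (is.null(b$nodes)) NULL else
          do.call(rbind, purrr::map(b$nodes, ~ unlist(.x)))
      )
    )
  })
  branches <- dplyr::bind_rows(rows)
  branches <- branches[order(branches$id), ]
  organoid_tree(branches,
                time = as.numeric(obj$time %||% NA_real_),
                seed = if (is.null(obj$seed)) NA_integer_ else
                  as.integer(obj$seed),
                v_cell = as.numeric(obj$v_cell %||% NA_real_))
}
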