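# Shared fixtures built in code.

# hand-built tree: straight trunk along +x with optional daughters
toy_tree <- function(n_branchings = 0, width = 20, trunk_len = 100) {
  branches <- tibble::tibble(
    id = 1L, parent_id = NA_integer_, birth_time = 0,
    width = width, volume = (pi / 4) * width^2 * trunk_len,
    length = trunk_len, terminal = n_branchings == 0, broken = FALSE,
    nodes = list(rbind(c(0, 0), c(trunk_len, 0)))
  )
  next_id <- 2L
  tips <- 1L
  for (b in seq_len(n_branchings)) {
    mother <- tips[1]
    mrow <- match(mother, branches$id)
    mtip <- branches$nodes[[mrow]][nrow(branches$nodes[[mrow]]), ]
    for (s in c(1, -1)) {
      ang <- s * pi / 3
      tip <- mtip + 100 * c(cos(ang), sin(ang))
      branches <- dplyr::bind_rows(branches, tibble::tibble(
        id = next_id, parent_id = mother, birth_time = b,
        width = width, volume = (pi / 4) * width^2 * 100,
        length = 100, terminal = TRUE, broken = FALSE,
        nodes = list(rbind(mtip, tip))
      ))
      next_id <- next_id + 1L
    }
    branches$terminal[mrow] <- FALSE
    tips <- c(setdiff(tips, mother), next_id - 2L)
  }
  organoid_tree(branches, time = n_branchings, v_cell = 1000)
}

# single terminal branch with linearly tapered per-node widths
tapered_tree <- function(w_tip = 10, w_base = 30, len = 60, n_nodes = 61) {
  x <- seq(0, len, length.out = n_nodes)
  nodes <- cbind(x, 0)
  wds <- seq(w_base, w_tip, length.out = n_nodes) # base -> tip
  branches <- tibble::tibble(
    id = 1L, parent_id = NA_integer_, birth_time = 0,
    width = mean(wds), volume = (pi / 4) * mean(wds)^2 * len,
    length = len, terminal = TRUE, broken = FALSE,
    nodes = list(nodes), node_widths = list(wds)
  )
  organoid_tree(branches, time = 0)
}

quick_cfg <- function(duration = 4, seed = 1, ...) {
  sim_config(duration = duration, seed = seed, ...)
}
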