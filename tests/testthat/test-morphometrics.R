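test_that("uniform-width branches measure their scalar width", {
  tree <- toy_tree(0, width = 20, trunk_len = 100)
  w <- terminal_branch_width(tree, 1)
  expect_equal(as.numeric(w), 20)
  expect_false(attr(w, "truncated"))
  b <- body_width(tree, 1)
  expect_equal(as.numeric(b), 20)
})

test_that("nascent branches fall back to the base width", {
  tree <- toy_tree(0, width = 12, trunk_len = 20)
  w <- terminal_branch_width(tree, 1)  # shorter than the 30 um offset
  expect_equal(as.numeric(w), 12)
  expect_true(attr(w, "truncated"))
})

test_that("tapered widths interpolate along arc length", {
  # 10 um at the tip to 30 um at the base over 60 um: the midpoint of the
  # taper sits 30 um behind the tip
  tree <- tapered_tree(w_tip = 10, w_base = 30, len = 60)
  expect_equal(as.numeric(terminal_branch_width(tree, 1, offset = 30)), 20)
  expect_equal(as.numeric(terminal_branch_width(tree, 1, offset = 15)), 15)
  # body offset (100 um) exceeds the length: base width, flagged
  b <- body_width(tree, 1)
  expect_equal(as.numeric(b), 30)
  expect_true(attr(b, "truncated"))
})

test_that("non-terminal body width is measured from the Y base", {
  tree <- toy_tree(1, width = 20, trunk_len = 150)
  # trunk is non-terminal after the branching event
  b <- body_width(tree, 1)
  expect_equal(as.numeric(b), 20)
  expect_false(attr(b, "truncated"))
  expect_error(terminal_branch_width(tree, 1), "not terminal")
})

test_that("branch counting is exhaustive and disjoint", {
  expect_equal(count_branches(toy_tree(0)),
               tibble::tibble(n_terminal = 1L, n_nonterminal = 0L))
  expect_equal(count_branches(toy_tree(1)),
               tibble::tibble(n_terminal = 2L, n_nonterminal = 1L))
  expect_equal(count_branches(toy_tree(2)),
               tibble::tibble(n_terminal = 3L, n_nonterminal = 2L))
  tr <- toy_tree(3)
  cts <- count_branches(tr)
  expect_equal(cts$n_terminal + cts$n_nonterminal, nrow(tr))
})

test_that("major axis is the maximal pairwise node distance", {
  tree <- toy_tree(0, trunk_len = 400)
  expect_equal(major_axis_length(tree), 400)
  # symmetric Y: 100 um trunk, two 100 um daughters at +/- 60 degrees;
  # brute force over the node pairs gives the trunk-base-to-daughter-tip
  # distance
  y <- toy_tree(1, trunk_len = 100)
  nodes <- do.call(rbind, y$nodes)
  expect_equal(major_axis_length(y), max(stats::dist(nodes)))
  expect_equal(major_axis_length(y),
               sqrt((100 + 100 * cos(pi / 3))^2 + (100 * sin(pi / 3))^2),
               tolerance = 1e-9)
})

test_that("normalized volumetric growth is the relative volume rate", {
  expect_equal(normalized_volumetric_growth(100, 200, 1), 1)
  expect_equal(normalized_volumetric_growth(100, 100, 2), 0)
  expect_equal(normalized_volumetric_growth(100, 80, 0.5), -0.4)
  expect_error(normalized_volumetric_growth(0, 10, 1), "volume")
  expect_error(normalized_volumetric_growth(10, 10, 0), "delta_t")
})

test_that("width measurements are invariant under rigid motions", {
  tree <- tapered_tree()
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- tree
  moved$nodes <- purrr::map(tree$nodes, ~ sweep(.x %*% R, 2, c(50, -20)))
  moved <- organoid_tree(moved, time = 0)
  expect_equal(as.numeric(terminal_branch_width(moved, 1, 30)),
               as.numeric(terminal_branch_width(tree, 1, 30)),
               tolerance = 1e-9)
})

test_that("simulated trees measure their per-branch widths exactly", {
  sim <- simulate_organoid(quick_cfg(duration = 5, seed = 12))
  tree <- sim$trees[[1]]
  for (id in tree$id[tree$terminal & !tree$broken]) {
    expect_equal(as.numeric(terminal_branch_width(tree, id)),
                 tree$width[match(id, tree$id)])
  }
  m <- measure_tree(tree)
  expect_true(all(m$value[!is.na(m$value)] >= 0))
  expect_equal(m$value[m$kind == "branch_count_terminal"],
               sum(tree$terminal))
  expect_equal(m$value[m$kind == "cell_count"],
               sum(tree$volume) / 1000)
})

test_that("growth-rate pairs reproduce the division rate", {
  p <- growth_params(kb = 0)
  cfg <- sim_config(params = p, duration = 2, seed = 3)
  sim <- simulate_organoid(cfg, sample_times = seq(0, 2, 0.05),
                           record_nodes = FALSE)
  pairs <- growth_rate_pairs(sim$branch_samples)
  kd <- division_rate(pairs$width, p)
  # finite-difference rate exceeds the instantaneous rate by ~kd^2 dt / 2
  expect_equal(pairs$growth_rate, kd, tolerance = 0.05)
  expect_true(all(pairs$delta_t > 0))
})

test_that("degenerate trees are rejected", {
  expect_error(major_axis_length(organoid_tree(tibble::tibble(
    id = 1L, parent_id = NA_integer_, birth_time = 0, width = 1,
    volume = 1, length = 1, terminal = TRUE, broken = FALSE
  ))), "nodes")
  expect_error(terminal_branch_width(toy_tree(0), 99), "no branch")
})
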