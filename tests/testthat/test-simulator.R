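test_that("clusterings are partitions with the stated expected block count", {
  set.seed(101)
  expect_length(random_clustering(1), 1)
  for (i in 1:20) {
    blocks <- random_clustering(10)
    muts <- unlist(blocks)
    expect_identical(sort(muts), sprintf("M%02d", 1:10))
    expect_true(all(lengths(blocks) >= 1))
  }
  k <- replicate(4000, length(random_clustering(10)))
  expect_equal(mean(k), 1 + 0.75 * 9, tolerance = 0.015)
})

test_that("ground-truth trees satisfy branching cap and sum rule", {
  set.seed(103)
  cfg <- simulation_config(m = 12, n_trees = 1)
  for (i in 1:50) {
    truth <- random_true_tree(12, cfg)
    kids <- mtumortree:::children_map(truth$tree)
    expect_lte(max(lengths(kids)), 3)
    root <- mtumortree:::root_node(truth$tree)
    expect_equal(unname(truth$freq[[root]]), 1)
    for (v in truth$tree$nodes)
      expect_gte(truth$freq[[v]], sum(truth$freq[kids[[v]]]) - 1e-12)
    expect_true(all(truth$freq > 0 & truth$freq <= 1))
  }
})

test_that("perturbation is the identity when all operators are disabled", {
  set.seed(107)
  cfg <- simulation_config(m = 10, n_trees = 1, move_prob = 0,
                           expand_prob = 0, collapse = FALSE)
  for (i in 1:10) {
    truth <- random_true_tree(10, cfg)
    expect_true(trees_equal(perturb_tree(truth, cfg), truth$tree))
  }
})

test_that("expansion splits a multi-mutation node into parent and child", {
  set.seed(109)
  truth <- list(tree = parse_tree("1\t-\tA,B"), freq = c("1" = 1))
  cfg <- simulation_config(m = 2, n_trees = 1, move_prob = 0,
                           expand_prob = 1, collapse = FALSE)
  seen <- character(0)
  for (i in 1:40) seen <- c(seen, write_tree(perturb_tree(truth, cfg)))
  expect_identical(sort(unique(seen)),
                   c("1\t-\tA\n2\t1\tB\n", "1\t-\tB\n2\t1\tA\n"))
})

test_that("perturbed trees keep the mutation set and the input branching cap", {
  set.seed(113)
  cfg <- simulation_config(m = 10, n_trees = 5)
  for (i in 1:60) {
    trial <- generate_trial(cfg)
    expect_length(trial$inputs, 5)
    expect_silent(audit_trial(trial, cfg))
  }
})

test_that("datasets are reproducible from the seed, byte for byte", {
  cfg <- simulation_config(m = 8, n_trees = 3, n_trials = 4, seed = 991)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  ser <- function(d) lapply(d, function(tr)
    c(write_tree(tr$truth), unname(tr$frequencies),
      vapply(tr$inputs, write_tree, character(1))))
  expect_identical(ser(d1), ser(d2))
})

test_that("datasets survive a write/read round trip", {
  cfg <- simulation_config(m = 6, n_trees = 3, n_trials = 3, seed = 17)
  trials <- generate_dataset(cfg)
  dir <- tempfile("dataset")
  write_dataset(trials, dir, cfg)
  back <- read_dataset(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_true(trees_equal(back[[i]]$truth, trials[[i]]$truth))
    expect_equal(sort(unname(back[[i]]$frequencies)),
                 sort(unname(trials[[i]]$frequencies)), tolerance = 1e-9)
    for (j in seq_along(trials[[i]]$inputs))
      expect_true(trees_equal(back[[i]]$inputs[[j]], trials[[i]]$inputs[[j]]))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$m, 6)
  unlink(dir, recursive = TRUE)
})
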