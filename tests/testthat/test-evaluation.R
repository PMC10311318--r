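test_that("weighting schemes produce the documented rank weights", {
  set.seed(211)
  cfg <- simulation_config(m = 6, n_trees = 5)
  trial <- generate_trial(cfg)
  w <- weighting_scheme(trial$inputs, trial$truth, "linear")
  expect_equal(sort(w, decreasing = TRUE), c(0.30, 0.25, 0.20, 0.15, 0.10))
  d <- vapply(trial$inputs, function(t) ad_distance(t, trial$truth),
              numeric(1))
  expect_equal(order(w, decreasing = TRUE)[1], order(d)[1])

  expect_equal(weighting_scheme(trial$inputs[1:3], trial$truth, "constant"),
               rep(1 / 3, 3))

  wn <- weighting_scheme(trial$inputs, trial$truth, "naive")
  expect_equal(sort(wn), c(0, 0, 0, 0, 1))

  cfg10 <- simulation_config(m = 6, n_trees = 10)
  trial10 <- generate_trial(cfg10)
  w10 <- weighting_scheme(trial10$inputs, trial10$truth, "linear")
  expect_equal(sum(w10), 1)
  by_rank <- sort(w10, decreasing = TRUE)
  # renormalized from start 0.15, step 0.0111 (raw sum 1.0005)
  expect_equal(by_rank, (0.15 - 0.0111 * (0:9)) / 1.0005, tolerance = 1e-9)
  expect_true(all(diff(by_rank) < 0))

  expect_error(weighting_scheme(trial$inputs[1:3], trial$truth, "linear"),
               class = "mtt_instance_error")
  w3 <- weighting_scheme(trial$inputs[1:3], trial$truth, "linear",
                         start = 0.5, step = 0.1)
  expect_equal(sort(w3, decreasing = TRUE), c(0.5, 0.4, 0.3) / 1.2)
})

test_that("percent change reproduces the worked -50/0/+50 examples", {
  expect_equal(percent_change(5, 10), -50)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(15, 10), 50)
  expect_equal(percent_change(0, 0), 0)
  expect_warning(pc <- percent_change(3, 0))
  expect_true(is.nan(pc))
})

test_that("naive scheme via the ILP equals direct closest-tree selection", {
  set.seed(223)
  cfg <- simulation_config(m = 5, n_trees = 4)
  for (i in 1:5) {
    trial <- generate_trial(cfg)
    w <- weighting_scheme(trial$inputs, trial$truth, "naive")
    res <- consensus(trial$inputs, weights = w)
    expect_true(trees_equal(res$trees[[1]],
                            mtumortree:::closest_input(trial$inputs,
                                                       trial$truth)))
  }
})

test_that("run_experiment crosses schemes with trials and flags recovery", {
  set.seed(227)
  cfg <- simulation_config(m = 6, n_trees = 5, n_trials = 6, seed = 229)
  trials <- generate_dataset(cfg)
  res <- run_experiment(trials)
  expect_identical(nrow(res$per_trial), 18L)
  expect_identical(res$per_trial$recovered, res$per_trial$distance == 0)
  expect_identical(sort(res$aggregates$scheme),
                   c("constant", "linear", "naive"))
  # identical inputs equal to truth: zero distance, full recovery
  ident <- list(structure(list(truth = chain_abc(), frequencies = c(n1 = 1),
                               inputs = list(chain_abc(), chain_abc())),
                          class = "trial_record"))
  res0 <- run_experiment(ident, schemes = c("naive", "constant"))
  expect_true(all(res0$per_trial$distance == 0))
  expect_true(all(res0$aggregates$recovery == 1))
})

test_that("simplex grid enumerates compositions (66 points for n=3, step 0.1)", {
  g <- simplex_grid(3, 0.1)
  expect_identical(nrow(g), 66L)
  expect_true(all(abs(rowSums(g) - 1) < 1e-9))
  expect_identical(nrow(simplex_grid(2, 0.5)), 3L)
})

test_that("weight sweep maps dominance regions to the dominant input", {
  trees <- list(chain_abc(), chain_acb(), star_abc())
  sw <- weight_sweep(trees, step = 0.25, limit = 50)
  expect_identical(nrow(sw$grid), 15L)
  keys <- vapply(trees, write_tree, character(1))
  for (i in seq_len(nrow(sw$grid))) {
    w <- unlist(sw$grid[i, 1:3])
    if (max(w) > 0.5) {
      opt <- sw$optima_sets[[sw$grid$optima_set[i]]]
      expect_length(opt, 1)
      expect_identical(write_tree(opt[[1]]), keys[which.max(w)])
    }
  }
  # vertex of the simplex returns exactly that input tree
  vertex <- which(abs(sw$grid$w2 - 1) < 1e-9)
  opt <- sw$optima_sets[[sw$grid$optima_set[vertex]]]
  expect_true(trees_equal(opt[[1]], chain_acb()))
})
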