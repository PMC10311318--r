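test_that("support matrix holds weighted delta values and the constant term", {
  t1 <- chain_abc()
  sm1 <- support_matrix(weighted_instance(list(t1), 1))
  expect_equal(sm1$support["A", "B"], 1)
  expect_equal(sm1$support["B", "A"], 0)
  expect_equal(sm1$constant, 3)  # |phi_AD| of a 3-chain

  sm2 <- support_matrix(weighted_instance(list(chain_abc(), chain_acb()),
                                          c(0.5, 0.5)))
  expect_equal(sm2$support["B", "C"], 0.5)  # ancestral in exactly one tree
  expect_equal(sm2$support["A", "B"], 1)

  sm3 <- support_matrix(weighted_instance(list(t1, t1, t1)))
  expect_equal(sm3$constant, 3)
})

test_that("model has m(m-1) pair variables, m root variables, triple constraints", {
  mk <- function(m) {
    cands <- enumerate_m_tumor_trees(LETTERS[1:m], cap = 10)
    build_model(weighted_instance(cands[1]))
  }
  m3 <- mk(3)
  expect_equal(sum(!is.na(m3$xidx)), 6)
  expect_length(m3$ridx, 3)
  # 6 ordered distinct triples, two constraint families, plus root rows
  expect_equal(max(m3$con_i), 2 * 6 + 1 + 2 * 3)
  m2 <- mk(2)
  expect_equal(sum(!is.na(m2$xidx)), 2)
  expect_equal(max(m2$con_i), 1 + 2 * 2)  # no triples exist at m = 2
  expect_equal(sum(!is.na(mk(4)$xidx)), 12)
})

test_that("single-input consensus returns that tree at objective zero", {
  t1 <- chain_abc()
  sol <- solve_model(build_model(weighted_instance(list(t1))))
  expect_equal(sol$objective_value, 0)
  expect_identical(sol$x,
                   mtumortree:::pairs_to_relation(ad_pairs(t1), t1$mutations))
  res <- consensus(list(t1), all_optima = TRUE)
  expect_length(res$trees, 1)  # AD is a metric: unique zero
  expect_true(trees_equal(res$trees[[1]], t1))
  expect_false(res$truncated)
})

test_that("majority-weight input dominates the consensus", {
  res <- consensus(list(chain_abc(), chain_acb()), weights = c(0.9, 0.1),
                   all_optima = TRUE)
  expect_length(res$trees, 1)
  expect_true(trees_equal(res$trees[[1]], chain_abc()))
})

test_that("two opposed trees at equal weight tie with the merged node", {
  ab <- parse_tree("1\t-\tA\n2\t1\tB")
  ba <- parse_tree("1\t-\tB\n2\t1\tA")
  res <- consensus(list(ab, ba), weights = c(0.5, 0.5), all_optima = TRUE)
  expect_equal(res$objective, 1)
  expect_identical(canon(res$trees),
                   canon(list(ab, ba, parse_tree("1\t-\tA,B"))))
})

test_that("limit=1 enumeration flags truncation exactly when optima remain", {
  ab <- parse_tree("1\t-\tA\n2\t1\tB")
  ba <- parse_tree("1\t-\tB\n2\t1\tA")
  res <- consensus(list(ab, ba), weights = c(0.5, 0.5), all_optima = TRUE,
                   limit = 1)
  expect_length(res$trees, 1)
  expect_true(res$truncated)
  res1 <- consensus(list(ab), all_optima = TRUE, limit = 1)
  expect_false(res1$truncated)
})

test_that("solver objective equals the recomputed weighted AD distance", {
  set.seed(23)
  for (i in 1:10) {
    inst <- random_small_instance(4, 3)
    res <- consensus(inst)
    expect_equal(weighted_total_distance(res$trees[[1]], inst, "ad"),
                 res$objective, tolerance = 1e-6)
  }
})

test_that("returned solutions pass the integer constraint audit", {
  set.seed(29)
  inst <- random_small_instance(4, 5)
  sol <- solve_model(build_model(inst))
  expect_silent(audit_relation_solution(sol))
  # corrupt transitivity and expect the audit to catch it
  bad <- sol
  bad$x[] <- 0L
  bad$x["A", "B"] <- 1L; bad$x["B", "C"] <- 1L
  bad$r[] <- 0L; bad$r["A"] <- 1L
  expect_error(audit_relation_solution(bad), class = "mtt_audit_error")
})

test_that("m=1 instances are solved without invoking the solver", {
  one <- parse_tree("1\t-\tA")
  model <- build_model(weighted_instance(list(one, one)))
  expect_true(model$trivial)
  res <- consensus(list(one, one))
  expect_true(trees_equal(res$trees[[1]], one))
  expect_equal(res$objective, 0)
})
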