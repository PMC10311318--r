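test_that("majority rule keeps mutations in strictly more than half the trees", {
  ts <- list(parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tC"),
             parse_tree("1\t-\tA\n2\t1\tB"),
             parse_tree("1\t-\tA\n2\t1\tD"))
  expect_identical(majority_mutations(ts), c("A", "B"))
  same <- list(chain_abc(), chain_acb())
  expect_identical(majority_mutations(same), c("A", "B", "C"))
  disjoint <- list(parse_tree("1\t-\tA"), parse_tree("1\t-\tB"))
  expect_error(majority_mutations(disjoint), class = "mtt_harmonize_error")
})

test_that("restriction contracts emptied nodes and preserves kept relations", {
  restricted <- restrict_tree(chain_abc(), c("A", "C"))
  expect_true(trees_equal(restricted, parse_tree("1\t-\tA\n2\t1\tC")))
  expect_true(trees_equal(restrict_tree(chain_abc(), c("A", "B", "C", "Z")),
                          chain_abc()))
  expect_true(trees_equal(restrict_tree(parse_tree("1\t-\tA,B"), "A"),
                          parse_tree("1\t-\tA")))
  expect_error(restrict_tree(chain_abc(), "Z"), class = "mtt_harmonize_error")
})

test_that("restriction preserves AD pairs exactly for all m=3 keep subsets", {
  muts <- c("A", "B", "C")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(muts, k, simplify = FALSE)), recursive = FALSE)
  for (tree in enumerate_m_tumor_trees(muts)) {
    full <- pairs_to_matrix(ad_pairs(tree))
    for (keep in subsets) {
      expected <- full[full[, 1] %in% keep & full[, 2] %in% keep, ,
                       drop = FALSE]
      expected <- sort(mtumortree:::pair_key(expected[, 1], expected[, 2]))
      got <- restrict_ad_pairs(tree, keep)
      expect_identical(as.character(got), expected)
      # when the restriction admits a tree, its ad_pairs agree too
      rt <- tryCatch(restrict_tree(tree, keep),
                     mtt_forest_error = function(e) NULL)
      if (!is.null(rt))
        expect_identical(as.character(ad_pairs(rt)), expected)
    }
  }
})

test_that("removing the whole root label of a branching root yields a forest", {
  tree <- star_abc()  # root {A} with children {B}, {C}
  expect_error(restrict_tree(tree, c("B", "C")), class = "mtt_forest_error")
  # harmonized consensus still works on such inputs via the pair relations
  ts <- list(star_abc(),
             parse_tree("1\t-\tB\n2\t1\tC"),
             parse_tree("1\t-\tB\n2\t1\tC"))
  res <- consensus(ts, harmonize = TRUE)
  expect_identical(res$trees[[1]]$mutations, c("B", "C"))
  expect_true(trees_equal(res$trees[[1]], parse_tree("1\t-\tB\n2\t1\tC")))
})

test_that("harmonized consensus restricts inputs to the majority set", {
  ts <- list(parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tC"),
             parse_tree("1\t-\tA\n2\t1\tB,C"),
             parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tD"))
  res <- consensus(ts, harmonize = TRUE)
  expect_identical(res$trees[[1]]$mutations, c("A", "B", "C"))
})
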