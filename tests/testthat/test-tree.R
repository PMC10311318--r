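test_that("parse_tree reads the node/edge format and validates invariants", {
  t <- parse_tree("1\t-\tA\n2\t1\tB,C\n")
  expect_s3_class(t, "mtumor_tree")
  expect_identical(t$mutations, c("A", "B", "C"))
  expect_identical(sort(t$labels[["2"]]), c("B", "C"))
  # comments and blank lines are ignored
  t2 <- parse_tree("# a comment\n1\t-\tA\n\n2\t1\tB,C  # trailing")
  expect_true(trees_equal(t, t2))

  expect_error(parse_tree("1\t-\tA\n2\t1\tA\n"), class = "mtt_validation_error")
  expect_error(parse_tree("1\t-\tA\n2\t3\tB\n"), class = "mtt_validation_error")
  expect_error(parse_tree("1\t-\tA\n2\t1\tB\n3\t-\tC"),
               class = "mtt_validation_error")  # two roots
  expect_error(parse_tree("1\t2\tA\n2\t1\tB"), class = "mtt_validation_error")
  expect_error(parse_tree("1\t-\n"), class = "mtt_parse_error")
  expect_error(parse_tree("1\t-\tA\n1\t1\tB"), class = "mtt_parse_error")
})

test_that("write_tree is canonical: round trips and id-permutation stable", {
  expect_identical(write_tree(parse_tree("x\t-\tB,A")), "1\t-\tA,B\n")
  # same tree under different node ids serializes identically
  a <- parse_tree("r\t-\tA\nu\tr\tB\nv\tu\tC")
  b <- parse_tree("9\t7\tC\n7\t5\tB\n5\t-\tA")
  expect_identical(write_tree(a), write_tree(b))
  expect_true(trees_equal(a, parse_tree(write_tree(a))))
})

test_that("round trip through files preserves simulator-generated trees", {
  set.seed(7)
  cfg <- simulation_config(m = 8, n_trees = 2)
  for (i in 1:10) {
    tr <- generate_trial(cfg)
    for (t in c(list(tr$truth), tr$inputs)) {
      path <- tempfile(fileext = ".txt")
      write_tree_file(t, path)
      expect_true(trees_equal(t, read_tree_file(path)))
      unlink(path)
    }
  }
})

test_that("ad_pairs matches hand enumeration on chains, stars, single nodes", {
  expect_pairs(ad_pairs(chain_abc()), "A>B", "A>C", "B>C")
  expect_pairs(ad_pairs(parse_tree("1\t-\tA,B")), "A>B", "B>A")
  expect_pairs(ad_pairs(star_abc()), "A>B", "A>C")
})

test_that("pc_pairs uses the mutual same-node convention and nests in ad_pairs", {
  expect_pairs(pc_pairs(chain_abc()), "A>B", "B>C")
  expect_pairs(pc_pairs(parse_tree("1\t-\tA,B")), "A>B", "B>A")
  expect_pairs(pc_pairs(star_abc()), "A>B", "A>C")
})

test_that("ad pair counts hit the closed forms for paths and single nodes", {
  m <- 6
  path <- parse_tree(paste(sprintf("%d\t%s\tM%d", 1:m, c("-", 1:(m - 1)), 1:m),
                           collapse = "\n"))
  expect_length(ad_pairs(path), m * (m - 1) / 2)
  one <- parse_tree(paste0("1\t-\t", paste0("M", 1:m, collapse = ",")))
  expect_length(ad_pairs(one), m * (m - 1))
})

test_that("ad_pairs of random trees satisfy the pair-set invariants", {
  set.seed(11)
  for (i in 1:25) {
    tree <- random_true_tree(7)$tree
    p <- pairs_to_matrix(ad_pairs(tree))
    x <- mtumortree:::pairs_to_relation(ad_pairs(tree), tree$mutations)
    expect_true(all(p[, 1] != p[, 2]))  # no self pairs
    # transitivity: two-step reachability implies an edge
    x2 <- (x %*% x) > 0; diag(x2) <- FALSE
    expect_true(all(x[x2] == 1))
    # single-lineage closure: co-ancestors of any mutation are comparable
    for (cc in seq_len(ncol(x))) {
      anc <- which(x[, cc] == 1)
      if (length(anc) > 1) {
        cb <- utils::combn(anc, 2)
        expect_true(all(x[cbind(cb[1, ], cb[2, ])] +
                        x[cbind(cb[2, ], cb[1, ])] >= 1))
      }
    }
    # parent-child pairs are a subset of ancestor-descendant pairs
    expect_true(all(pc_pairs(tree) %in% ad_pairs(tree)))
  }
})
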