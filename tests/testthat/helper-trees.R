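# shared fixtures: small hand-built trees and random-instance generators

chain_abc <- function() parse_tree("1\t-\tA\n2\t1\tB\n3\t2\tC")
chain_acb <- function() parse_tree("1\t-\tA\n2\t1\tC\n3\t2\tB")
star_abc  <- function() parse_tree("1\t-\tA\n2\t1\tB\n3\t1\tC")

pair_set <- function(...) {
  # build a mutation_pairs vector from "a>b" strings
  keys <- vapply(list(...), function(s) {
    ab <- strsplit(s, ">", fixed = TRUE)[[1]]
    mtumortree:::pair_key(ab[1], ab[2])
  }, character(1))
  sort(keys)
}

expect_pairs <- function(pairs, ...) {
  expect_identical(as.character(pairs), pair_set(...))
}

# random instance over a small mutation set, sampled from the full
# enumerated tree space so the oracle can check it exhaustively
random_small_instance <- function(m, n, mutations = LETTERS[seq_len(m)]) {
  cands <- enumerate_m_tumor_trees(mutations)
  trees <- sample(cands, n, replace = TRUE)
  w <- stats::rexp(n)
  weighted_instance(trees, w / sum(w))
}

canon <- function(trees) sort(vapply(trees, write_tree, character(1)))
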