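test_that("nucleotide distances follow the generator word length", {
  expect_equal(nucleotide_distance("A", "A"), 0L)
  expect_equal(nucleotide_distance("A", "U"), 1L)  # one transversion step
  expect_equal(nucleotide_distance("A", "G"), 1L)  # one transition step
  expect_equal(nucleotide_distance("A", "C"), 2L)  # needs the composite ab
  # symmetry over all pairs, every variant
  for (v in cayley_variants()) {
    for (x in c("A", "C", "G", "U")) {
      for (y in c("A", "C", "G", "U")) {
        expect_equal(nucleotide_distance(x, y, v), nucleotide_distance(y, x, v))
      }
    }
  }
})

test_that("codon distance is a metric matching the graph-walk oracle", {
  expect_equal(codon_distance("AGC", "AGC"), 0L)
  expect_equal(codon_distance("AGC", "UUG"), 4L)
  cods <- codons()
  set.seed(42)
  pairs <- cbind(sample(cods, 40, TRUE), sample(cods, 40, TRUE))
  for (k in seq_len(nrow(pairs))) {
    expect_equal(codon_distance(pairs[k, 1], pairs[k, 2]),
                 oracle_distance(pairs[k, 1], pairs[k, 2]))
  }
  # triangle inequality on random triples
  z <- sample(cods, 40, TRUE)
  d12 <- codon_distance(pairs[, 1], pairs[, 2])
  d1z <- codon_distance(pairs[, 1], z)
  dz2 <- codon_distance(z, pairs[, 2])
  expect_true(all(d12 <= d1z + dz2))
})

test_that("binary coordinates biject with codons and linearize the metric", {
  cods <- codons()
  for (v in cayley_variants()) {
    B <- codon_to_binary(cods, v)
    expect_equal(binary_to_codon(B, v), cods)          # round trip
    expect_equal(nrow(unique(B)), 64)                  # bijection
    # distance equals Hamming distance over all pairs
    D_bits <- as.matrix(stats::dist(B, method = "manhattan"))
    D_met <- outer(cods, cods, function(x, y) codon_distance(x, y, v))
    expect_equal(unname(D_met), unname(D_bits), ignore_attr = TRUE)
  }
  # generator steps flip single bits: an a-step at position 2 flips bit 3
  b0 <- codon_to_binary("AUG")
  b1 <- codon_to_binary(act_codon(c("e", "a", "e"), "AUG"))
  expect_equal(which(b0 != b1), 3L)
  b2 <- codon_to_binary(act_codon(c("e", "b", "e"), "AUG"))
  expect_equal(which(b0 != b2), 4L)
  expect_error(binary_to_codon(c(0, 1, 2, 0, 1, 0)), "0/1")
})

test_that("the hypercube graph has the Q6 invariants", {
  g <- hypercube_graph()
  expect_equal(igraph::vcount(g), 64)
  expect_equal(igraph::ecount(g), 192)
  expect_true(all(igraph::degree(g) == 6))
  # matches the metric-level adjacency oracle
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  expect_equal(unname(A[codons(), codons()]), unname(oracle_adjacency()))
})

test_that("default and alternative variants give isomorphic graphs", {
  g1 <- hypercube_graph(cayley_variant("default"))
  g2 <- hypercube_graph(cayley_variant("ab-complement"))
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2)))
  expect_true(igraph::isomorphic(g1, g2))
})

test_that("automorphism membership agrees with the naive all-pairs oracle", {
  g <- hypercube_graph()
  # fixed-triple maps are isometries
  tm <- stats::setNames(act_codon(c("a", "b", "ab"), codons()), codons())
  r <- is_hypercube_automorphism(tm, g)
  expect_true(r$is_automorphism)
  expect_true(oracle_is_automorphism(tm))
  # a transposition of antipodal-ish vertices breaks adjacency
  swap <- stats::setNames(codons(), codons())
  swap[c("AAA", "UUU")] <- c("UUU", "AAA")
  expect_false(is_hypercube_automorphism(swap, g)$is_automorphism)
  expect_false(oracle_is_automorphism(swap))
  # identity passes
  expect_true(is_hypercube_automorphism(stats::setNames(codons(), codons()),
                                        g)$is_automorphism)
  # random maps: implementation and oracle always agree
  set.seed(7)
  for (k in seq_len(60)) {
    m <- random_codon_map()
    expect_equal(is_hypercube_automorphism(m, g)$is_automorphism,
                 oracle_is_automorphism(m))
  }
  expect_error(is_hypercube_automorphism(tm[1:10], g), "all 64")
})

test_that("violation reports name the offending codon pairs", {
  g <- hypercube_graph()
  swap <- stats::setNames(codons(), codons())
  swap[c("AAA", "UUU")] <- c("UUU", "AAA")
  r <- is_hypercube_automorphism(swap, g)
  expect_gt(nrow(r$violations), 0)
  expect_true(all(c("AAA", "UUU") %in% unlist(r$violations[, c("from", "to")])))
})

test_that("the full automorphism group has hyperoctahedral order 46080", {
  aut <- hypercube_automorphisms()
  expect_equal(length(aut), 64 * 720)
  expect_equal(anyDuplicated(aut$perm), 0)         # all maps distinct
  # soundness on a sample
  g <- hypercube_graph()
  set.seed(11)
  for (i in sample(length(aut), 25)) {
    expect_true(is_hypercube_automorphism(aut_as_map(aut, i), g)$is_automorphism)
  }
  # the 64 action-triple maps form a subgroup of the full group
  tp <- codonsym:::triple_perm_matrix()
  keys <- apply(aut$perm, 1, paste, collapse = ",")
  tkeys <- apply(tp, 1, paste, collapse = ",")
  expect_true(all(tkeys %in% keys))
  for (k in seq_len(4)) {                          # closure spot check
    ij <- sample(64, 2)
    comp <- tp[ij[1], tp[ij[2], ]]
    expect_true(paste(comp, collapse = ",") %in% tkeys)
  }
})

test_that("codon-anticodon separation is maximal under the prior-work variant", {
  cods <- codons()
  d_alt <- codon_distance(cods, codon_complement(cods), "ab-complement")
  expect_equal(max(d_alt), 6)
  expect_true(all(d_alt == 6))   # complement flips all six bits there
  d_def <- codon_distance(cods, codon_complement(cods), "default")
  expect_equal(max(d_def), 3)    # one generator step per position
})
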