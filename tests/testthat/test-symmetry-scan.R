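test_that("scan over action triples matches a naive per-map check", {
  pr <- codon_classification("pr-default")
  rep <- scan_symmetries(pr, "action-triples")
  # naive oracle: count triples preserving / permuting labels directly
  trips <- action_triples()
  labels <- pr$labels[codons()]
  naive_preserve <- 0
  naive_block <- 0
  blocks <- split(codons(), labels)
  for (k in seq_len(nrow(trips))) {
    img <- act_codon(trips[k, ], codons())
    if (all(labels[img] == labels)) naive_preserve <- naive_preserve + 1
    imgs_uniform <- vapply(blocks, function(b) {
      length(unique(labels[act_codon(trips[k, ], b)])) == 1
    }, TRUE)
    if (all(imgs_uniform)) naive_block <- naive_block + 1
  }
  expect_equal(rep$n_label_preserving, naive_preserve)
  expect_equal(rep$n_block_permuting, naive_block)
  expect_equal(rep$n_universe, 64)
  # label-preserving count equals the invariant-action count
  expect_equal(rep$n_label_preserving, nrow(invariant_actions(pr)))
})

test_that("a classification with all-distinct labels admits only the identity", {
  cls <- codonsym:::new_classification(
    stats::setNames(paste0("u", seq_len(64)), codons()), "all-distinct")
  rep <- scan_symmetries(cls, "action-triples")
  expect_equal(rep$n_label_preserving, 1)
  ia <- invariant_actions(cls)
  expect_equal(nrow(ia), 1)
  expect_equal(unname(ia[1, ]), c("e", "e", "e"))
})

test_that("invariant actions form a subgroup, for built-in and random labels", {
  check_subgroup <- function(tr) {
    keys <- apply(tr, 1, paste, collapse = ",")
    expect_true("e,e,e" %in% keys)
    for (i in seq_len(nrow(tr))) {
      for (j in seq_len(nrow(tr))) {
        prod <- k4_multiply(tr[i, ], tr[j, ])
        expect_true(paste(prod, collapse = ",") %in% keys)
      }
    }
  }
  fun <- codon_classification("aars-functional")
  ia <- invariant_actions(fun)
  check_subgroup(ia)
  expect_true("e,e,b" %in% apply(ia, 1, paste, collapse = ","))
  set.seed(3)
  for (r in seq_len(5)) {
    k <- sample(2:6, 1)
    cls <- codonsym:::new_classification(
      stats::setNames(paste0("c", sample.int(k, 64, TRUE)), codons()),
      "random")
    check_subgroup(invariant_actions(cls))
  }
  # one label: every triple is invariant
  uni <- codonsym:::new_classification(
    stats::setNames(rep("x", 64), codons()), "uniform")
  expect_equal(nrow(invariant_actions(uni)), 64)
})

test_that("hydropathy with UGA moderately hydrophobic admits the wobble transition", {
  hyd <- synthetic_hydropathy()
  keys <- apply(invariant_actions(hyd), 1, paste, collapse = ",")
  expect_true("e,e,b" %in% keys)
  # with UGA kept as its own stop category instead, UGA/UGG breaks the
  # wobble transition
  hyd_stop <- hyd
  hyd_stop$labels[["UGA"]] <- "stop"
  keys_stop <- apply(invariant_actions(hyd_stop), 1, paste, collapse = ",")
  expect_false("e,e,b" %in% keys_stop)
})

test_that("polarity with UGA non-polar and other stops polar gains (e,e,a)", {
  pol <- synthetic_polarity()
  keys <- apply(invariant_actions(pol), 1, paste, collapse = ",")
  expect_true(all(c("e,e,b", "e,e,a", "e,e,ab") %in% keys))
})

test_that("the null model is seeded, deterministic and degenerate cases work", {
  fun <- codon_classification("aars-functional")
  r1 <- null_distribution(fun, n = 30, seed = 9)
  r2 <- null_distribution(fun, n = 30, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1$null_counts, 30)
  expect_equal(r1$observed, 2)          # identity and the wobble transition
  # arrangement matters: random relabellings essentially never keep (e,e,b)
  expect_true(mean(r1$null_counts) < r1$observed)
  expect_error(null_distribution(fun, n = 0), ">= 1")
  uni <- codonsym:::new_classification(
    stats::setNames(rep("x", 64), codons()), "uniform")
  ru <- null_distribution(uni, n = 3, seed = 1)
  expect_equal(ru$observed, 64)
  expect_equal(ru$null_counts, rep(64L, 3))
})

test_that("strict and lenient handling of unlabelled codons differ as documented", {
  # four labels on 61 codons; stops unlabelled
  pr <- codon_classification("pr-default")
  labels <- pr$labels[setdiff(codons(), c("UAA", "UAG", "UGA"))]
  part <- codonsym:::new_classification(labels, "pr-sans-stops")
  strict <- scan_symmetries(part, "action-triples", strict = TRUE)
  lenient <- scan_symmetries(part, "action-triples", strict = FALSE)
  expect_lte(strict$n_label_preserving, lenient$n_label_preserving)
  expect_lte(strict$n_block_permuting, lenient$n_block_permuting)
})
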