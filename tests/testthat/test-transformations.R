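structural_violation_set <- sort(c("UUU", "UUC", "UCU", "UCC",
                                   "UAU", "UAC", "UGU", "UGC"))

test_that("T1 and T2 are total involutive isometries with the stated rules", {
  T1 <- make_T1()
  T2 <- make_T2()
  expect_equal(unname(apply_map(T1, "GCU")), "CUA")  # GCU in RNY via (a,b,a)
  expect_equal(unname(apply_map(T1, "AAA")), "AGA")  # AAA in RNR via (e,b,e)
  for (m in list(T1, T2)) {
    expect_setequal(names(m$map), codons())
    expect_setequal(unname(m$map), codons())                 # bijective
    expect_equal(unname(apply_map(m, unname(m$map))), codons())  # involution
    expect_true(verify_isometry(m)$is_automorphism)
  }
})

test_that("F realizes the block rules and the worked AGC example", {
  F <- make_F()
  expect_equal(unname(apply_map(F, "AGC")), "UUG")
  expect_equal(unname(apply_map(F, "UUG")), "AGC")
  expect_equal(unname(apply_map(F, unname(apply_map(F)))), codons())
  expect_true(verify_isometry(F)$is_automorphism)
  # restricted to each of the 16 blocks, F is the block's stated triple
  for (k in seq_len(nrow(F$rules))) {
    r <- F$rules[k, ]
    blk <- codonsym:::match_pattern(r$pattern)
    expect_equal(unname(apply_map(F, blk)),
                 act_codon(c(r$a1, r$a2, r$a3), blk))
  }
})

test_that("T1 o T2 collapses to the uniform wobble transition (e,e,b)", {
  T1 <- make_T1(); T2 <- make_T2(); T3 <- make_T3()
  c12 <- compose_maps(T1, T2)
  expect_equal(unname(c12$map), unname(T3$map))
  expect_equal(unname(apply_map(c12, "AUG")), "AUA")
  c21 <- compose_maps(T2, T1)
  expect_equal(unname(c21$map), unname(c12$map))      # abelian components
  ident <- compose_maps(T1, T1)
  expect_equal(unname(ident$map), codons())
  # the composite is re-expressed as the single-rule pattern NNN
  expect_equal(c12$rules$pattern, "NNN")
  expect_equal(unlist(c12$rules[1, c("a1", "a2", "a3")], use.names = FALSE),
               c("e", "e", "b"))
})

test_that("class interchange holds functionally and fails structurally", {
  T1 <- make_T1(); T2 <- make_T2()
  fun <- codon_classification("aars-functional")
  str <- codon_classification("aars-structural")
  for (m in list(T1, T2)) {
    r <- verify_class_interchange(m, fun)
    expect_true(r$interchanges)
    expect_equal(nrow(r$violations), 0)
    # structural mode: the Phe/Tyr ambiguity surfaces as a fixed violation set
    rs <- verify_class_interchange(m, str)
    expect_false(rs$interchanges)
    expect_equal(sort(rs$violations$codon), structural_violation_set)
  }
  ident <- piecewise_map(list(NNN = c("e", "e", "e")), "identity")
  expect_equal(nrow(verify_class_interchange(ident, fun)$violations), 64)
  one_label <- codonsym:::new_classification(
    stats::setNames(rep("x", 64), codons()), "uniform")
  expect_error(verify_class_interchange(T1, one_label), "two labels")
})

test_that("T3 is class-invariant for aaRS classes but separates wobble pairs", {
  T3 <- make_T3()
  fun <- codon_classification("aars-functional")
  expect_true(verify_class_invariance(T3, fun)$invariant)
  # a classification separating AUG from AUA is violated twice
  cls <- codonsym:::new_classification(
    stats::setNames(ifelse(codons() == "AUG", "start", "other"), codons()),
    "start-vs-rest")
  r <- verify_class_invariance(T3, cls)
  expect_equal(sort(r$violations$codon), c("AUA", "AUG"))
  ident <- piecewise_map(list(NNN = c("e", "e", "e")), "identity")
  expect_true(verify_class_invariance(ident, cls)$invariant)
  # partial classifications skip unlabelled images with a warning
  part <- codonsym:::new_classification(
    stats::setNames(rep("x", 2), c("AUG", "GGG")), "partial")
  expect_warning(rp <- verify_class_invariance(T3, part), "skipped")
  expect_true(rp$invariant)
})

test_that("F maps the middle-base partition onto the first/third-RY partition", {
  F <- make_F()
  r <- verify_partition_mapping(F, pattern_blocks("middle-base"),
                                pattern_blocks("first-third-RY"))
  expect_true(r$exact)
  expect_equal(r$block_image_map,
               c(NAN = "RNR", NGN = "YNR", NUN = "RNY", NCN = "YNY"))
  # identity maps any scheme to itself with the identity correspondence
  ident <- piecewise_map(list(NNN = c("e", "e", "e")), "identity")
  mb <- pattern_blocks("middle-base")
  ri <- verify_partition_mapping(ident, mb, mb)
  expect_true(ri$exact)
  expect_equal(ri$block_image_map, stats::setNames(names(mb), names(mb)))
  # the wobble transition never changes the middle base
  rt <- verify_partition_mapping(make_T3(), mb, mb)
  expect_true(rt$exact)
  expect_equal(rt$block_image_map, stats::setNames(names(mb), names(mb)))
  # T1 does not map middle-base blocks onto first/third-RY blocks
  rf <- verify_partition_mapping(make_T1(), mb, pattern_blocks("first-third-RY"))
  expect_false(rf$exact)
})

test_that("piecewise-map files round-trip in both formats and are validated", {
  T1 <- make_T1()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_piecewise_map(T1, tsv)
  back <- read_piecewise_map(tsv)
  expect_equal(back$map, T1$map)
  js <- withr::local_tempfile(fileext = ".json")
  write_piecewise_map(T1, js, format = "json")
  backj <- read_piecewise_map(js)
  expect_equal(backj$map, T1$map)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("RNY\ta,b,a", bad)
  expect_error(read_piecewise_map(bad), "do not cover 48 codons")
  writeLines(c("RNY\ta,b,a", "RNN\te,e,e", "YNN\te,e,e"), bad)
  expect_error(read_piecewise_map(bad), "overlap")
  writeLines(c("NNN\ta,b"), bad)
  expect_error(read_piecewise_map(bad), "three K4 elements")
  writeLines(c("NNN\ta,b,q"), bad)
  expect_error(read_piecewise_map(bad), "must be one of")
})
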