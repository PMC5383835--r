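# Scan automorphism universes for maps that preserve a classification or
# permute its label blocks; induced label-permutation groups; permutation
# null models.

# Label vector aligned to codons(); NA for unlabelled codons.
aligned_labels <- function(classes) {
  labels <- classification_labels(classes)
  out <- stats::setNames(rep(NA_character_, 64), codons())
  out[names(labels)] <- labels
  out
}

# Universe of automorphisms as an index permutation matrix (n x 64).
universe_perms <- function(universe = c("action-triples",
                                        "full-hypercube-automorphisms"),
                           variant = cayley_variant()) {
  universe <- match.arg(universe)
  if (universe == "action-triples") triple_perm_matrix(variant)
  else hypercube_automorphisms(variant)$perm
}

#' Scan an automorphism universe against a classification
#'
#' Classifies every automorphism in the universe as label-preserving (every
#' codon maps within its own label block), block-permuting (every label
#' block maps setwise onto some label block), or neither, and builds the
#' induced permutation group on the labels from the block-permuting maps.
#' For the default polar-requirement categories (four 16-codon 4D subcubes)
#' the induced label group under the full universe is the dihedral group of
#' the square (order 8) and the setwise stabilizer of one block restricts
#' to the 4D hyperoctahedral group S2 wr S4 (order 384) on that block.
#'
#' Unlabelled codons are by default required to map among themselves
#' (`strict = TRUE`); with `strict = FALSE` they are ignored.
#'
#' @param classes A `codon_classification`.
#' @param universe `"action-triples"` (the 64 triple maps) or
#'   `"full-hypercube-automorphisms"` (all 46080 maps of Q6).
#' @param variant A `cayley_variant` or its name.
#' @param strict Logical; treatment of unlabelled codons (see above).
#' @return An object of class `symmetry_report`: a list with
#'   `classification`, `universe`, `n_universe`, `n_label_preserving`,
#'   `n_block_permuting`, `induced_label_group` (matrix of label
#'   permutations, one row each), `induced_group_order`, and
#'   `block_stabilizer_order` (named: distinct restrictions to each block
#'   of its setwise stabilizer).
#' @export
scan_symmetries <- function(classes,
                            universe = c("action-triples",
                                         "full-hypercube-automorphisms"),
                            variant = cayley_variant(),
                            strict = TRUE) {
  universe <- match.arg(universe)
  labels <- aligned_labels(classes)
  P <- universe_perms(universe, variant)
  n <- nrow(P)
  ulab <- sort(unique(labels[!is.na(labels)]))
  lab_int <- match(labels, ulab)          # NA for unlabelled
  blocks <- lapply(seq_along(ulab), function(k) which(lab_int == k))
  na_block <- which(is.na(lab_int))

  img_lab <- matrix(lab_int[P], nrow = n)  # label of the image codon

  # label-preserving: image label equals own label on every labelled codon.
  # Strict mode additionally requires unlabelled codons to stay unlabelled
  # (and labelled codons never to land on unlabelled ones); non-strict mode
  # lets labelled codons map to unlabelled ones.
  own <- matrix(lab_int, nrow = n, ncol = 64, byrow = TRUE)
  eq <- img_lab == own
  eq[is.na(eq)] <- FALSE
  if (strict) {
    ok <- eq | (is.na(img_lab) & is.na(own))
    lp <- rowSums(ok) == 64
  } else {
    keep <- !is.na(lab_int)
    ok <- eq[, keep, drop = FALSE] | is.na(img_lab[, keep, drop = FALSE])
    lp <- rowSums(ok) == sum(keep)
  }

  # block-permuting: each label block's image carries one uniform label (in
  # strict mode the unlabelled block must also map to itself).
  bp <- rep(TRUE, n)
  induced <- matrix(NA_integer_, nrow = n, ncol = length(ulab))
  for (k in seq_along(blocks)) {
    sub <- img_lab[, blocks[[k]], drop = FALSE]
    if (strict) {
      first <- sub[, 1]
      uniform <- !is.na(first) &
        rowSums(sub == first, na.rm = TRUE) == ncol(sub)
    } else {
      first <- apply(sub, 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r) == 0) NA_integer_ else r[1]
      })
      uniform <- apply(sub, 1, function(r) {
        length(unique(r[!is.na(r)])) <= 1
      })
    }
    bp <- bp & uniform
    induced[, k] <- first
  }
  if (strict && length(na_block) > 0) {
    sub <- img_lab[, na_block, drop = FALSE]
    bp <- bp & rowSums(is.na(sub)) == ncol(sub)
  }
  # a qualifying map must induce a permutation of the labels
  is_perm <- apply(induced, 1, function(r) !anyNA(r) && !anyDuplicated(r))
  bp <- bp & is_perm

  perms <- unique(induced[bp, , drop = FALSE])
  colnames(perms) <- ulab
  perms_lab <- matrix(ulab[perms], nrow = nrow(perms),
                      dimnames = list(NULL, ulab))

  stab <- vapply(seq_along(blocks), function(k) {
    cols <- blocks[[k]]
    fixes <- bp & induced[, k] == k
    if (!any(fixes)) return(0L)
    restr <- P[fixes, cols, drop = FALSE]
    nrow(unique(restr))
  }, 1L)
  names(stab) <- ulab

  structure(list(
    classification = classes$name,
    universe = universe,
    strict = strict,
    n_universe = n,
    n_label_preserving = sum(lp),
    n_block_permuting = sum(bp),
    induced_label_group = perms_lab,
    induced_group_order = nrow(perms_lab),
    block_stabilizer_order = stab
  ), class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("Symmetry scan of \"%s\" over %s (%d maps)\n",
              x$classification, x$universe, x$n_universe))
  cat(sprintf("  label-preserving maps : %d\n", x$n_label_preserving))
  cat(sprintf("  block-permuting maps  : %d\n", x$n_block_permuting))
  cat(sprintf("  induced label group   : order %d\n", x$induced_group_order))
  cat(sprintf("  block stabilizers     : %s\n",
              paste(sprintf("%s=%d", names(x$block_stabilizer_order),
                            x$block_stabilizer_order), collapse = ", ")))
  invisible(x)
}

#' Action triples leaving a classification invariant
#'
#' Returns every action triple whose codon map carries each labelled codon
#' to a codon of the same label (zero violations under
#' [verify_class_invariance()]). The returned triples always form a
#' subgroup of K4^3. For the functional aaRS classification the wobble
#' transition (e, e, b) is invariant; a hydropathy classification becomes
#' (e, e, b)-invariant once UGA is labelled with the moderately hydrophobic
#' category of Trp.
#'
#' @param classes A `codon_classification` (total or partial).
#' @param variant A `cayley_variant` or its name.
#' @return A character matrix of invariant triples, one per row (columns
#'   `p1`, `p2`, `p3`).
#' @export
invariant_actions <- function(classes, variant = cayley_variant()) {
  labels <- aligned_labels(classes)
  lab_int <- match(labels, sort(unique(labels[!is.na(labels)])))
  P <- triple_perm_matrix(variant)
  img_lab <- matrix(lab_int[P], nrow = 64)
  keep <- !is.na(lab_int)
  ok <- vapply(seq_len(64), function(i) {
    il <- img_lab[i, keep]
    all(is.na(il) | il == lab_int[keep])
  }, TRUE)
  action_triples()[ok, , drop = FALSE]
}

#' Null distribution of the invariant-action count
#'
#' Scores how exceptional a classification's symmetry is: the labels are
#' randomly permuted across the labelled codons (preserving the label
#' multiset, so arrangement rather than composition is tested) and the
#' number of invariant action triples is recomputed for each replicate.
#'
#' @param classes A `codon_classification`.
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param variant A `cayley_variant` or its name.
#' @return A list with `observed` (invariant-action count of `classes`),
#'   `null_counts` (integer vector of length `n`) and `p_value` (fraction
#'   of replicates with a count at least as large as observed, with the
#'   +1 continuity correction).
#' @export
null_distribution <- function(classes, n = 100, seed = 1,
                              variant = cayley_variant()) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  observed <- nrow(invariant_actions(classes, variant))
  labels <- classification_labels(classes)
  counts <- integer(n)
  set.seed(seed)
  for (r in seq_len(n)) {
    shuffled <- new_classification(
      stats::setNames(sample(unname(labels)), names(labels)),
      sprintf("%s-null-%d", classes$name, r)
    )
    counts[r] <- nrow(invariant_actions(shuffled, variant))
  }
  list(
    observed = observed,
    null_counts = counts,
    p_value = (1 + sum(counts >= observed)) / (n + 1)
  )
}
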