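# Piecewise codon maps: the class-interchanging isometries T1 and T2, their
# composition T3, the model-converting map F, and verification utilities.

#' Construct a piecewise codon map
#'
#' A piecewise map is a total codon map defined block-wise: each rule pairs
#' a domain pattern (over A, C, G, U, R, Y, N) with an action triple, and a
#' codon is transformed by the unique rule whose pattern matches it.
#' Construction validates that the patterns are pairwise disjoint and cover
#' all 64 codons, so no runtime tie-breaking exists.
#'
#' @param rules A data frame with columns `pattern` and `a1`, `a2`, `a3`
#'   (K4 element names), or a named list mapping pattern strings to
#'   length-3 element vectors.
#' @param name Map name.
#' @param variant A `cayley_variant` or its name.
#' @return An object of class `piecewise_map`: a list with `name`, `rules`
#'   (data frame), `map` (named character vector over the 64 codons) and
#'   `variant`.
#' @export
piecewise_map <- function(rules, name = "map", variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  if (is.list(rules) && !is.data.frame(rules)) {
    rules <- data.frame(
      pattern = names(rules),
      a1 = vapply(rules, `[`, "", 1),
      a2 = vapply(rules, `[`, "", 2),
      a3 = vapply(rules, `[`, "", 3),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  stopifnot(is.data.frame(rules),
            all(c("pattern", "a1", "a2", "a3") %in% names(rules)))
  check_k4_element(c(rules$a1, rules$a2, rules$a3), "rules triples")
  domains <- lapply(rules$pattern, match_pattern)
  all_cod <- unlist(domains, use.names = FALSE)
  if (anyDuplicated(all_cod)) {
    stop(sprintf("overlapping rule patterns; codons matched twice: %s",
                 paste(sort(unique(all_cod[duplicated(all_cod)])),
                       collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(codons(), all_cod)
  if (length(missing) > 0) {
    stop(sprintf("rules do not cover %d codons: %s", length(missing),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  map <- character(0)
  for (k in seq_len(nrow(rules))) {
    dom <- domains[[k]]
    img <- act_codon(unlist(rules[k, c("a1", "a2", "a3")]), dom, v)
    map <- c(map, stats::setNames(img, dom))
  }
  structure(list(name = name, rules = rules, map = map[codons()],
                 variant = v$name),
            class = "piecewise_map")
}

#' @export
print.piecewise_map <- function(x, ...) {
  cat(sprintf("Piecewise codon map \"%s\" (variant \"%s\")\n", x$name, x$variant))
  for (k in seq_len(nrow(x$rules))) {
    r <- x$rules[k, ]
    cat(sprintf("  %s -> (%s, %s, %s)\n", r$pattern, r$a1, r$a2, r$a3))
  }
  invisible(x)
}

#' Apply a piecewise map to codons
#'
#' @param m A `piecewise_map`.
#' @param codon Codon string(s); defaults to all 64.
#' @return The image codon(s), named by input codon.
#' @export
apply_map <- function(m, codon = codons()) {
  stopifnot(inherits(m, "piecewise_map"))
  m$map[normalize_codons(codon)]
}

#' The class-interchanging isometries T1 and T2 and their composition T3
#'
#' `make_T1()` and `make_T2()` build the two piecewise hypercube
#' automorphisms that interchange the codons of aaRS class I with those of
#' class II (under the functional class map with stops attached to class
#' I). Their blocks and triples are
#' \preformatted{
#'   T1: RNY <-> (a,b,a)  YNR    T2: RNY <-> (a,b,ab) YNR
#'       RNR <-> (e,b,e)  RNR        RNR <-> (e,b,b)  RNR
#'       YNY <-> (e,b,e)  YNY        YNY <-> (e,b,b)  YNY
#' }
#' Both are involutions. Their composition `make_T3()` is the uniform
#' action triple (e, e, b) on every codon -- a transition in the wobble
#' position -- and is class-invariant.
#'
#' @param variant A `cayley_variant` or its name.
#' @return A `piecewise_map`.
#' @export
make_T1 <- function(variant = cayley_variant()) {
  piecewise_map(list(
    RNY = c("a", "b", "a"), YNR = c("a", "b", "a"),
    RNR = c("e", "b", "e"), YNY = c("e", "b", "e")
  ), name = "T1", variant = variant)
}

#' @rdname make_T1
#' @export
make_T2 <- function(variant = cayley_variant()) {
  piecewise_map(list(
    RNY = c("a", "b", "ab"), YNR = c("a", "b", "ab"),
    RNR = c("e", "b", "b"), YNY = c("e", "b", "b")
  ), name = "T2", variant = variant)
}

#' @rdname make_T1
#' @export
make_T3 <- function(variant = cayley_variant()) {
  piecewise_map(list(NNN = c("e", "e", "b")), name = "T3", variant = variant)
}

#' The isometry F converting the Rodin-Ohno sub-codes into the RNY model
#'
#' F is the piecewise hypercube automorphism, defined on the sixteen
#' four-codon blocks that fix R/Y at positions 1 and 3 and a literal middle
#' base, which carries the middle-base partition \{NAN, NGN, NUN, NCN\}
#' exactly onto \{RNR, YNR, RNY, YNY\} respectively. It is an involution:
#' the same action applied to the image returns the original codon (e.g.
#' AGC, in block RGY, maps under (a, ab, a) to UUG and back).
#'
#' @param variant A `cayley_variant` or its name.
#' @return A `piecewise_map`.
#' @export
make_F <- function(variant = cayley_variant()) {
  piecewise_map(list(
    RAR = c("e", "e", "e"),  YGR = c("e", "e", "e"),
    RUY = c("e", "e", "e"),  YCY = c("e", "e", "e"),
    RGR = c("a", "b", "e"),  YAR = c("a", "b", "e"),
    RCY = c("a", "b", "e"),  YUY = c("a", "b", "e"),
    RUR = c("e", "a", "a"),  YCR = c("e", "a", "a"),
    RAY = c("e", "a", "a"),  YGY = c("e", "a", "a"),
    RCR = c("a", "ab", "a"), YUR = c("a", "ab", "a"),
    RGY = c("a", "ab", "a"), YAY = c("a", "ab", "a")
  ), name = "F", variant = variant)
}

# The unique action triple carrying codon x to codon y (the action of K4^3
# on codons is regular, so it exists and is unique).
triple_between <- function(x, y, variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  chx <- strsplit(x, "")[[1]]
  chy <- strsplit(y, "")[[1]]
  vapply(1:3, function(i) {
    for (g in K4_ELEMENTS) {
      if (act_nucleotide(g, chx[i], v) == chy[i]) return(g)
    }
    stop("unreachable")
  }, "")
}

#' Compose two piecewise maps
#'
#' Point-wise composition `m2 after m1`: the returned map sends each codon
#' c to `m2(m1(c))`. The result is re-expressed as rules by grouping codons
#' according to the unique action triple relating each codon to its image
#' (blocks are compressed to patterns when pattern-expressible).
#'
#' @param m1,m2 `piecewise_map` objects on the same variant.
#' @param name Name for the composite; default `"m2 o m1"` style.
#' @return A `piecewise_map`.
#' @export
compose_maps <- function(m1, m2, name = NULL) {
  stopifnot(inherits(m1, "piecewise_map"), inherits(m2, "piecewise_map"))
  if (m1$variant != m2$variant) {
    stop("maps use different Cayley variants", call. = FALSE)
  }
  v <- cayley_variant(m1$variant)
  comp <- stats::setNames(m2$map[m1$map], names(m1$map))
  trips <- vapply(codons(), function(c) {
    paste(triple_between(c, comp[[c]], v), collapse = ",")
  }, "")
  rules <- NULL
  for (t in unique(trips)) {
    block <- names(trips)[trips == t]
    pat <- block_pattern(block)
    pats <- if (is.na(pat)) block else pat
    el <- strsplit(t, ",", fixed = TRUE)[[1]]
    rules <- rbind(rules, data.frame(pattern = pats, a1 = el[1], a2 = el[2],
                                     a3 = el[3], stringsAsFactors = FALSE))
  }
  if (is.null(name)) name <- sprintf("%s o %s", m2$name, m1$name)
  out <- piecewise_map(rules, name = name, variant = v)
  stopifnot(identical(unname(out$map), unname(comp[codons()])))
  out
}

# Pattern string for a codon set if it is a product of per-position symbol
# sets expressible as a base, R, y or N; NA otherwise.
block_pattern <- function(block) {
  ch <- codon_chars(block)
  syms <- character(3)
  for (i in 1:3) {
    s <- sort(unique(ch[, i]))
    sym <- if (length(s) == 1) s
           else if (identical(s, sort(PURINES))) "R"
           else if (identical(s, sort(PYRIMIDINES))) "Y"
           else if (identical(s, sort(NUCLEOTIDES))) "N"
           else return(NA_character_)
    syms[i] <- sym
  }
  pat <- paste(syms, collapse = "")
  if (setequal(match_pattern(pat), block)) pat else NA_character_
}

#' Verify that a piecewise map is a hypercube isometry
#'
#' Checks bijectivity and adjacency preservation of the map's codon
#' function against the hypercube graph of the map's variant.
#'
#' @param m A `piecewise_map`.
#' @param graph Optional `hypercube_graph()`; built from the map's variant
#'   when omitted.
#' @return As [is_hypercube_automorphism()]: a list with `is_automorphism`
#'   and `violations`.
#' @export
verify_isometry <- function(m, graph = NULL) {
  stopifnot(inherits(m, "piecewise_map"))
  if (is.null(graph)) graph <- hypercube_graph(cayley_variant(m$variant))
  is_hypercube_automorphism(m$map, graph)
}

classification_labels <- function(classes) {
  stopifnot(inherits(classes, "codon_classification"))
  classes$labels
}

#' Verify class interchange under a piecewise map
#'
#' For a two-label classification, checks that the map sends every codon of
#' one class to a codon of the other. A violation is a codon whose image
#' carries the same label. Rows involving a stop codon on either side are
#' flagged so the dependence on the stop policy stays visible.
#'
#' @param m A `piecewise_map`.
#' @param classes A two-label `codon_classification` covering all codons.
#' @return A list with `interchanges` (logical) and `violations`, a data
#'   frame with columns `codon`, `label`, `image`, `image_label`,
#'   `involves_stop`.
#' @export
verify_class_interchange <- function(m, classes) {
  labels <- classification_labels(classes)
  if (length(unique(labels)) != 2) {
    stop("`classes` must carry exactly two labels", call. = FALSE)
  }
  if (length(labels) < 64) {
    stop("`classes` must label all 64 codons", call. = FALSE)
  }
  img <- apply_map(m)
  same <- labels == labels[img]
  stops <- stop_codons()
  viol <- data.frame(
    codon = names(labels)[same],
    label = unname(labels[same]),
    image = unname(img[same]),
    image_label = unname(labels[img][same]),
    stringsAsFactors = FALSE
  )
  viol$involves_stop <- viol$codon %in% stops | viol$image %in% stops
  list(interchanges = nrow(viol) == 0, violations = viol)
}

#' Verify class invariance under a piecewise map
#'
#' A violation is a labelled codon whose image carries a different label.
#' Partial classifications are allowed: codons whose image is unlabelled
#' are skipped with a warning.
#'
#' @param m A `piecewise_map`.
#' @param classes A `codon_classification` (total or partial).
#' @return A list with `invariant` (logical) and `violations` (data frame
#'   with `codon`, `label`, `image`, `image_label`).
#' @export
verify_class_invariance <- function(m, classes) {
  labels <- classification_labels(classes)
  img <- apply_map(m, names(labels))
  img_lab <- labels[img]
  skipped <- is.na(img_lab)
  if (any(skipped)) {
    warning(sprintf("%d codon(s) with unlabelled images skipped", sum(skipped)),
            call. = FALSE)
  }
  diff <- !skipped & labels != img_lab
  viol <- data.frame(
    codon = names(labels)[diff],
    label = unname(labels[diff]),
    image = unname(img[diff]),
    image_label = unname(img_lab[diff]),
    stringsAsFactors = FALSE
  )
  list(invariant = nrow(viol) == 0, violations = viol)
}

#' Verify that a map carries one pattern partition onto another
#'
#' Computes the image of every source block and matches it against the
#' target blocks. The mapping is `exact` when every image coincides with
#' one target block and the block correspondence is a bijection.
#'
#' @param m A `piecewise_map`.
#' @param source,target `pattern_partition` objects.
#' @return A list with `exact` (logical) and `block_image_map`, a named
#'   character vector source block -> matching target block (NA where the
#'   image is no target block).
#' @export
verify_partition_mapping <- function(m, source, target) {
  stopifnot(inherits(source, "pattern_partition"),
            inherits(target, "pattern_partition"))
  block_image <- stats::setNames(rep(NA_character_, length(source)),
                                 names(source))
  for (nm in names(source)) {
    img <- unname(apply_map(m, source[[nm]]))
    hit <- names(target)[vapply(target, setequal, TRUE, y = img)]
    if (length(hit) == 1) block_image[nm] <- hit
  }
  exact <- !anyNA(block_image) &&
    !anyDuplicated(block_image) &&
    setequal(block_image, names(target))
  list(exact = exact, block_image_map = block_image)
}

#' Read and write piecewise-map files
#'
#' Two formats are accepted: a TSV with rows `pattern<TAB>a1,a2,a3`
#' (`#` comments allowed) and a JSON object mapping pattern strings to
#' three-element arrays of K4 element names. Validation (totality,
#' disjointness, element names) is as in [piecewise_map()].
#'
#' @param file Path; format chosen by `.json` extension or content.
#' @param name Map name; defaults to the file name.
#' @param variant A `cayley_variant` or its name.
#' @return A `piecewise_map`.
#' @export
read_piecewise_map <- function(file, name = basename(file),
                               variant = cayley_variant()) {
  first <- readLines(file, n = 1)
  is_json <- grepl("\\.json$", file) || grepl("^\\s*\\{", first)
  if (is_json) {
    spec <- jsonlite::read_json(file, simplifyVector = TRUE)
    rules <- lapply(spec, function(x) as.character(x))
  } else {
    lines <- readLines(file)
    keep <- !grepl("^\\s*(#|$)", lines)
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- vapply(parts, length, 1L) < 2
    if (any(bad)) {
      stop(sprintf("malformed line(s) (need pattern<TAB>a1,a2,a3): %s",
                   paste(which(keep)[bad], collapse = ", ")), call. = FALSE)
    }
    rules <- stats::setNames(
      lapply(parts, function(p) trimws(strsplit(p[2], ",", fixed = TRUE)[[1]])),
      vapply(parts, `[`, "", 1)
    )
  }
  lens <- vapply(rules, length, 1L)
  if (any(lens != 3)) {
    stop("every rule needs exactly three K4 elements", call. = FALSE)
  }
  piecewise_map(rules, name = name, variant = variant)
}

#' @rdname read_piecewise_map
#' @param m A `piecewise_map` to write.
#' @param format `"tsv"` or `"json"`.
#' @export
write_piecewise_map <- function(m, file, format = c("tsv", "json")) {
  stopifnot(inherits(m, "piecewise_map"))
  format <- match.arg(format)
  if (format == "json") {
    spec <- stats::setNames(
      lapply(seq_len(nrow(m$rules)),
             function(k) unlist(m$rules[k, c("a1", "a2", "a3")],
                                use.names = FALSE)),
      m$rules$pattern
    )
    jsonlite::write_json(spec, file)
  } else {
    writeLines(c(
      sprintf("# piecewise map: %s", m$name),
      sprintf("%s\t%s,%s,%s", m$rules$pattern, m$rules$a1, m$rules$a2,
              m$rules$a3)
    ), file)
  }
  invisible(file)
}
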