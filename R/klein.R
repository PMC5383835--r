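# Klein four-group and its action on nucleotides and codons.

K4_ELEMENTS <- c("e", "a", "b", "ab")

# Multiplication table of (K4, o). Row = left factor, column = right factor.
K4_TABLE <- matrix(
  c(
    "e",  "a",  "b",  "ab",
    "a",  "e",  "ab", "b",
    "b",  "ab", "e",  "a",
    "ab", "b",  "a",  "e"
  ),
  nrow = 4, byrow = TRUE,
  dimnames = list(K4_ELEMENTS, K4_ELEMENTS)
)

NUCLEOTIDES <- c("A", "C", "G", "U")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "U")

# The three fixed-point-free involutions of {A, C, G, U}:
#   complement  - the complementary transversion (Watson-Crick pairing)
#   transition  - purine <-> purine, pyrimidine <-> pyrimidine
#   transversion2 - the remaining, non-complementary transversion
INVOLUTIONS <- list(
  complement    = c(A = "U", C = "G", G = "C", U = "A"),
  transition    = c(A = "G", C = "U", G = "A", U = "C"),
  transversion2 = c(A = "C", C = "A", G = "U", U = "G")
)

#' Elements of the Klein four-group
#'
#' @return Character vector `c("e", "a", "b", "ab")`.
#' @export
k4_elements <- function() K4_ELEMENTS

check_k4_element <- function(x, arg = "x") {
  if (!is.character(x) || any(!x %in% K4_ELEMENTS)) {
    stop(sprintf(
      "`%s` must be one of %s; got %s", arg,
      paste0('"', K4_ELEMENTS, '"', collapse = ", "),
      paste0('"', x, '"', collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Multiply two elements of the Klein four-group
#'
#' Composition is looked up in the group's multiplication table, in which
#' every element is its own inverse and the group is abelian.
#'
#' @param x,y Element names among `"e"`, `"a"`, `"b"`, `"ab"`. Vectorized;
#'   the usual recycling rules apply.
#' @return Character vector of products.
#' @examples
#' k4_multiply("a", "b")   # "ab"
#' k4_multiply("a", "a")   # "e"
#' @export
k4_multiply <- function(x, y) {
  check_k4_element(x, "x")
  check_k4_element(y, "y")
  K4_TABLE[cbind(x, y)]
}

#' Cayley variants of the group action on nucleotides
#'
#' A Cayley variant assigns the generator roles `a` and `b` to two of the
#' three fixed-point-free involutions of \{A, C, G, U\}; the third involution
#' is forced to be the composite element `ab`. Because the Cayley graph is
#' determined by which involution is relegated to `ab` (a two-generator
#' step), there are exactly three distinct variants.
#'
#' The `"default"` variant takes `a` to be the complementary transversion
#' (A<->U, G<->C) and `b` the transition (A<->G, C<->U), so `ab` is the
#' remaining transversion (A<->C, G<->U). The `"ab-complement"` variant
#' relegates the complementary transversion to the composite element, which
#' reproduces the convention of earlier binary-assignment codon models; in
#' it `a` is the non-complementary transversion and `b` the transition.
#'
#' @param name One of `"default"` (alias `"ab-transversion2"`),
#'   `"ab-complement"`, `"ab-transition"`.
#' @return An object of class `cayley_variant`: a list with the variant
#'   `name` and the three involutions `a`, `b`, `ab` as named character
#'   vectors mapping each nucleotide to its image.
#' @examples
#' v <- cayley_variant()
#' v$a[["A"]]  # "U"
#' @export
cayley_variant <- function(name = "default") {
  stopifnot(is.character(name), length(name) == 1)
  if (name == "ab-transversion2") name <- "default"
  roles <- switch(name,
    "default"       = list(a = "complement",    b = "transition"),
    "ab-complement" = list(a = "transversion2", b = "transition"),
    "ab-transition" = list(a = "complement",    b = "transversion2"),
    stop(sprintf("unknown Cayley variant \"%s\"", name), call. = FALSE)
  )
  a <- INVOLUTIONS[[roles$a]]
  b <- INVOLUTIONS[[roles$b]]
  ab <- b[a]            # composition a then b; named by the input nucleotide
  names(ab) <- names(a)
  structure(
    list(name = name, a = a, b = b, ab = ab),
    class = "cayley_variant"
  )
}

#' @export
print.cayley_variant <- function(x, ...) {
  cat(sprintf("Cayley variant \"%s\"\n", x$name))
  for (g in c("a", "b", "ab")) {
    inv <- x[[g]]
    pairs <- unique(t(apply(cbind(names(inv), inv), 1, sort)))
    cat(sprintf("  %-2s : %s\n", g,
                paste(apply(pairs, 1, paste, collapse = "<->"), collapse = ", ")))
  }
  invisible(x)
}

as_cayley_variant <- function(variant) {
  if (inherits(variant, "cayley_variant")) return(variant)
  cayley_variant(variant)
}

#' Enumerate the admissible Cayley variants
#'
#' All ordered assignments of the three fixed-point-free involutions to the
#' generator pair (a, b) number six, but the resulting Cayley graph depends
#' only on which involution plays the composite role `ab`, so exactly three
#' distinct variants exist.
#'
#' @return A list of the three `cayley_variant` objects.
#' @export
cayley_variants <- function() {
  lapply(c("default", "ab-complement", "ab-transition"), cayley_variant)
}

#' Count placements of the nucleotides on the rectangle's vertices
#'
#' Enumerates the bijections from the four nucleotides to the four labelled
#' vertices of the rectangle whose symmetry group is K4 and returns their
#' number (4! = 24). The placements collapse to three distinct Cayley graphs
#' once the generators are fixed as involutions, matching
#' [cayley_variants()].
#'
#' @return Integer, the number of vertex placements (24).
#' @export
count_vertex_placements <- function() {
  perms <- permutations_of(NUCLEOTIDES)
  nrow(perms)
}

# All permutations of a small vector, one per row.
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest, deparse.level = 0))
  }
  out
}

#' Apply a group element to a nucleotide
#'
#' The action of K4 on \{A, C, G, U\} under a Cayley variant: `e` fixes every
#' nucleotide and each non-identity element applies its involution.
#'
#' @param g Element name (`"e"`, `"a"`, `"b"`, `"ab"`); scalar.
#' @param n Nucleotide symbol(s); vectorized.
#' @param variant A `cayley_variant` or its name.
#' @return Nucleotide symbol(s) of the same length as `n`.
#' @examples
#' act_nucleotide("a", "A")   # "U"
#' act_nucleotide("b", "A")   # "G"
#' @export
act_nucleotide <- function(g, n, variant = cayley_variant()) {
  check_k4_element(g, "g")
  stopifnot(length(g) == 1)
  n <- normalize_nucleotides(n)
  if (g == "e") return(n)
  v <- as_cayley_variant(variant)
  unname(v[[g]][n])
}

normalize_nucleotides <- function(n, arg = "n") {
  if (any(grepl("T", n, fixed = TRUE))) {
    warning("DNA alphabet detected: normalizing T to U", call. = FALSE)
    n <- gsub("T", "U", n, fixed = TRUE)
  }
  bad <- !n %in% NUCLEOTIDES
  if (any(bad)) {
    stop(sprintf("invalid nucleotide(s): %s",
                 paste0('"', unique(n[bad]), '"', collapse = ", ")),
         call. = FALSE)
  }
  n
}

#' All 64 codons
#'
#' @return Character vector of the 64 RNA codons in lexicographic order
#'   (A < C < G < U).
#' @export
codons <- function() {
  grid <- expand.grid(p3 = NUCLEOTIDES, p2 = NUCLEOTIDES, p1 = NUCLEOTIDES,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$p1, grid$p2, grid$p3))
}

codon_chars <- function(c) {
  m <- matrix(unlist(strsplit(c, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
  m
}

normalize_codons <- function(c, arg = "codon") {
  if (!is.character(c) || any(nchar(c) != 3)) {
    stop(sprintf("`%s` must be three-letter codon strings", arg), call. = FALSE)
  }
  ch <- codon_chars(toupper(c))
  ch[] <- normalize_nucleotides(as.vector(ch))
  paste0(ch[, 1], ch[, 2], ch[, 3])
}

#' Apply an action triple to codons
#'
#' An action triple is an ordered triple of K4 elements applied
#' component-wise to codon positions 1-3. Every triple is its own inverse,
#' and the 64 triples act regularly on the 64 codons.
#'
#' @param triple Character vector of length 3 of K4 element names, e.g.
#'   `c("a", "ab", "a")`.
#' @param codon Codon string(s); vectorized.
#' @param variant A `cayley_variant` or its name.
#' @return Codon string(s) of the same length as `codon`.
#' @examples
#' act_codon(c("a", "ab", "a"), "AGC")  # "UUG"
#' @export
act_codon <- function(triple, codon, variant = cayley_variant()) {
  check_k4_element(triple, "triple")
  if (length(triple) != 3) stop("`triple` must have length 3", call. = FALSE)
  codon <- normalize_codons(codon)
  v <- as_cayley_variant(variant)
  ch <- codon_chars(codon)
  for (i in 1:3) {
    if (triple[i] != "e") ch[, i] <- v[[triple[i]]][ch[, i]]
  }
  paste0(ch[, 1], ch[, 2], ch[, 3])
}

#' All 64 action triples
#'
#' @return A 64 x 3 character matrix; each row is one element of K4^3.
#' @export
action_triples <- function() {
  grid <- expand.grid(a3 = K4_ELEMENTS, a2 = K4_ELEMENTS, a1 = K4_ELEMENTS,
                      stringsAsFactors = FALSE)
  m <- as.matrix(grid[, c("a1", "a2", "a3")])
  dimnames(m) <- list(NULL, c("p1", "p2", "p3"))
  m
}

#' Base-wise complementary codon
#'
#' The codon obtained by replacing every base with its Watson-Crick
#' complement, position by position (no reversal).
#'
#' @param codon Codon string(s).
#' @return Codon string(s).
#' @export
codon_complement <- function(codon) {
  codon <- normalize_codons(codon)
  comp <- INVOLUTIONS$complement
  ch <- codon_chars(codon)
  ch[] <- comp[ch]
  paste0(ch[, 1], ch[, 2], ch[, 3])
}
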