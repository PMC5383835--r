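# The codon metric, the 6D hypercube graph and its automorphism group.

#' Distance between two nucleotides
#'
#' The word metric on the Cayley graph of K4 acting on the nucleotides:
#' 0 for identical bases, 1 when one generator (`a` or `b`) converts one
#' base into the other, 2 when the composite element `ab` is required.
#'
#' @param x,y Nucleotide symbols; vectorized.
#' @param variant A `cayley_variant` or its name.
#' @return Integer distances in \{0, 1, 2\}.
#' @export
nucleotide_distance <- function(x, y, variant = cayley_variant()) {
  x <- normalize_nucleotides(x)
  y <- normalize_nucleotides(y)
  v <- as_cayley_variant(variant)
  d <- ifelse(x == y, 0L,
       ifelse(v$a[x] == y | v$b[x] == y, 1L, 2L))
  unname(d)
}

#' Distance between two codons
#'
#' The sum over the three positions of the nucleotide distances; equal to
#' the Hamming distance between the codons' 6-bit coordinates and a true
#' metric on the 64-codon space.
#'
#' @param c1,c2 Codon strings; vectorized.
#' @param variant A `cayley_variant` or its name.
#' @return Integer distances in 0..6.
#' @examples
#' codon_distance("AGC", "UUG")  # 4
#' @export
codon_distance <- function(c1, c2, variant = cayley_variant()) {
  c1 <- normalize_codons(c1, "c1")
  c2 <- normalize_codons(c2, "c2")
  v <- as_cayley_variant(variant)
  ch1 <- codon_chars(c1)
  ch2 <- codon_chars(c2)
  d <- nucleotide_distance(ch1[, 1], ch2[, 1], v) +
       nucleotide_distance(ch1[, 2], ch2[, 2], v) +
       nucleotide_distance(ch1[, 3], ch2[, 3], v)
  d
}

# Per-variant bit indicator sets. bit1 of a codon position is 1 when the
# base lies in the b-orbit of A (so `a` flips it and `b` fixes it); bit2 is
# 1 when the base lies in the a-orbit of A. Under the default variant bit1
# is the purine indicator and bit2 the weak (A/U) indicator.
variant_bit_sets <- function(variant) {
  v <- as_cayley_variant(variant)
  list(
    bit1 = c("A", unname(v$b[["A"]])),
    bit2 = c("A", unname(v$a[["A"]]))
  )
}

#' Binary coordinates of codons
#'
#' Encodes each codon as a 6-bit vector, two bits per position: bits
#' (2i - 1, 2i) encode position i. The encoding is chosen so that a
#' generator-`a` step at a position flips exactly that position's first bit
#' and a generator-`b` step flips exactly its second bit; codon distance is
#' then the Hamming distance between bit vectors.
#'
#' @param codon Codon string(s).
#' @param variant A `cayley_variant` or its name.
#' @return An integer matrix with one row per codon and 6 columns over
#'   \{0, 1\}.
#' @export
codon_to_binary <- function(codon, variant = cayley_variant()) {
  codon <- normalize_codons(codon)
  sets <- variant_bit_sets(variant)
  ch <- codon_chars(codon)
  out <- matrix(0L, nrow = length(codon), ncol = 6)
  for (i in 1:3) {
    out[, 2 * i - 1] <- as.integer(ch[, i] %in% sets$bit1)
    out[, 2 * i]     <- as.integer(ch[, i] %in% sets$bit2)
  }
  rownames(out) <- codon
  out
}

#' @rdname codon_to_binary
#' @param bits An integer matrix (or length-6 vector) of 6-bit rows.
#' @return For `binary_to_codon`, the codon string(s).
#' @export
binary_to_codon <- function(bits, variant = cayley_variant()) {
  if (is.vector(bits)) bits <- matrix(bits, nrow = 1)
  if (ncol(bits) != 6 || !all(bits %in% c(0L, 1L))) {
    stop("`bits` must be rows of six 0/1 values", call. = FALSE)
  }
  sets <- variant_bit_sets(variant)
  # invert the per-position 2-bit encoding
  lookup <- character(4)
  for (n in NUCLEOTIDES) {
    key <- 1 + 2 * (n %in% sets$bit1) + (n %in% sets$bit2)
    lookup[key] <- n
  }
  dec <- function(b1, b2) lookup[1 + 2 * b1 + b2]
  paste0(dec(bits[, 1], bits[, 2]), dec(bits[, 3], bits[, 4]),
         dec(bits[, 5], bits[, 6]))
}

#' The 6D hypercube graph of the genetic code
#'
#' Vertices are the 64 codons; edges join codons at metric distance one,
#' i.e. pairs related by a single generator (`a` or `b`) at a single
#' position. The graph is isomorphic to the binary 6-cube Q6: 64 vertices,
#' all of degree 6, and 192 edges. The edge set depends on the Cayley
#' variant (which involution costs two steps), so the graph records its
#' variant.
#'
#' @param variant A `cayley_variant` or its name.
#' @return An [igraph][igraph::igraph-package] graph with vertex attribute
#'   `bits` (the 6-bit coordinate string) and edge attributes `generator`
#'   (`"a"` or `"b"`) and `position` (1-3); graph attribute `variant`.
#' @export
hypercube_graph <- function(variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  cods <- codons()
  from <- character(0); to <- character(0)
  gen <- character(0); pos <- integer(0)
  for (g in c("a", "b")) {
    for (i in 1:3) {
      triple <- c("e", "e", "e"); triple[i] <- g
      img <- act_codon(triple, cods, v)
      keep <- cods < img   # one direction per unordered pair
      from <- c(from, cods[keep]); to <- c(to, img[keep])
      gen <- c(gen, rep(g, sum(keep))); pos <- c(pos, rep(i, sum(keep)))
    }
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, generator = gen, position = pos,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(
      name = cods,
      bits = apply(codon_to_binary(cods, v), 1, paste, collapse = ""),
      stringsAsFactors = FALSE
    )
  )
  gr <- igraph::set_graph_attr(gr, "variant", v$name)
  gr
}

graph_variant <- function(g) {
  nm <- igraph::graph_attr(g, "variant")
  if (is.null(nm)) "default" else nm
}

#' Test whether a codon map is a hypercube automorphism
#'
#' A codon map qualifies when it is a bijection of the 64 codons and both
#' it and its inverse carry edges to edges.
#'
#' @param map A named character vector: `map[[codon]]` is the image codon.
#'   Must be total over the 64 codons.
#' @param graph A graph from [hypercube_graph()]; built on demand when
#'   omitted.
#' @return A list with `is_automorphism` (logical) and `violations`, a
#'   data frame of codon pairs that are adjacent on one side of the map but
#'   not the other (columns `from`, `to`, `direction`).
#' @export
is_hypercube_automorphism <- function(map, graph = hypercube_graph()) {
  cods <- codons()
  if (is.null(names(map)) || !setequal(names(map), cods)) {
    stop("`map` must be a named vector covering all 64 codons", call. = FALSE)
  }
  map <- map[cods]
  if (anyNA(map) || !all(map %in% cods)) {
    stop("`map` images must be valid codons", call. = FALSE)
  }
  if (anyDuplicated(map)) {
    return(list(is_automorphism = FALSE,
                violations = data.frame(from = character(0), to = character(0),
                                        direction = character(0)),
                bijective = FALSE))
  }
  em <- igraph::as_edgelist(graph)
  edge_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  edges <- edge_key(em[, 1], em[, 2])
  fwd_bad <- !edge_key(map[em[, 1]], map[em[, 2]]) %in% edges
  inv <- stats::setNames(names(map), map)
  bwd_bad <- !edge_key(inv[em[, 1]], inv[em[, 2]]) %in% edges
  viol <- rbind(
    data.frame(from = em[fwd_bad, 1], to = em[fwd_bad, 2],
               direction = rep("forward", sum(fwd_bad)),
               stringsAsFactors = FALSE),
    data.frame(from = em[bwd_bad, 1], to = em[bwd_bad, 2],
               direction = rep("inverse", sum(bwd_bad)),
               stringsAsFactors = FALSE)
  )
  list(is_automorphism = nrow(viol) == 0, violations = viol, bijective = TRUE)
}

#' Enumerate the full automorphism group of the codon hypercube
#'
#' The automorphism group of Q6 is the hyperoctahedral group
#' Z2^6 semidirect S6, of order 2^6 * 6! = 46080: every automorphism is a
#' permutation of the six bit positions followed by a subset of bit flips.
#' Each abstract automorphism is realized as a codon map through the binary
#' encoding of the given variant. The 64 action-triple maps arise as the
#' pure bit-flip subgroup.
#'
#' @param variant A `cayley_variant` or its name.
#' @return An object of class `codon_aut_group`: a list with `perm`, a
#'   46080 x 64 integer matrix whose row k gives, for each codon index, the
#'   index of its image (indices into `codons`), and `codons`, the codon
#'   ordering used.
#' @export
hypercube_automorphisms <- function(variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  cods <- codons()
  B <- codon_to_binary(cods, v)            # 64 x 6
  pow <- 2L^(5:0)
  idx_of_bits <- integer(64)               # bits (as number) -> codon index
  idx_of_bits[as.integer(B %*% pow) + 1L] <- seq_len(64)
  bitperms <- permutations_of(as.character(1:6))
  storage.mode(bitperms) <- "integer"
  masks <- as.matrix(expand.grid(rep(list(0:1), 6)))[, 6:1, drop = FALSE]
  perm <- matrix(0L, nrow = 720L * 64L, ncol = 64L)
  row <- 0L
  for (p in seq_len(720)) {
    BP <- B[, bitperms[p, ], drop = FALSE]
    base <- as.integer(BP %*% pow)
    for (m in seq_len(64)) {
      row <- row + 1L
      flipped <- bitwXor(base, sum(masks[m, ] * pow))
      perm[row, ] <- idx_of_bits[flipped + 1L]
    }
  }
  structure(list(perm = perm, codons = cods, variant = v$name),
            class = "codon_aut_group")
}

#' @export
print.codon_aut_group <- function(x, ...) {
  cat(sprintf("Hypercube automorphism group: %d codon maps (variant \"%s\")\n",
              nrow(x$perm), x$variant))
  invisible(x)
}

#' @export
length.codon_aut_group <- function(x) nrow(x$perm)

#' Extract one automorphism as a codon map
#'
#' @param group A `codon_aut_group` from [hypercube_automorphisms()].
#' @param i Row index.
#' @return A named character vector mapping each codon to its image.
#' @export
aut_as_map <- function(group, i) {
  stopifnot(inherits(group, "codon_aut_group"))
  stats::setNames(group$codons[group$perm[i, ]], group$codons)
}

# Codon maps of all 64 action triples as an index matrix (64 x 64),
# rows ordered as action_triples().
triple_perm_matrix <- function(variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  cods <- codons()
  trips <- action_triples()
  out <- matrix(0L, nrow = 64, ncol = 64)
  for (k in seq_len(64)) {
    out[k, ] <- match(act_codon(trips[k, ], cods, v), cods)
  }
  out
}
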