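# Independent brute-force oracles used to cross-check the implementation.

# Adjacency matrix of the codon space built directly from the metric
# definition (single-generator moves), without going through the package's
# graph machinery.
oracle_adjacency <- function(variant = cayley_variant()) {
  cods <- codons()
  A <- matrix(FALSE, 64, 64, dimnames = list(cods, cods))
  for (g in c("a", "b")) {
    for (i in 1:3) {
      triple <- c("e", "e", "e"); triple[i] <- g
      img <- act_codon(triple, cods, variant)
      A[cbind(cods, img)] <- TRUE
    }
  }
  A
}

# Naive all-pairs automorphism check: bijection plus identical adjacency
# pattern after relabelling.
oracle_is_automorphism <- function(map, variant = cayley_variant()) {
  cods <- codons()
  if (anyDuplicated(map) || !setequal(map, cods)) return(FALSE)
  A <- oracle_adjacency(variant)
  p <- match(map[cods], cods)
  identical(unname(A[p, p]), unname(A))
}

# Graph-walk distance oracle: breadth-first search over single-generator
# moves, independent of the per-position distance formula.
oracle_distance <- function(c1, c2, variant = cayley_variant()) {
  A <- oracle_adjacency(variant)
  cods <- codons()
  dist <- stats::setNames(rep(NA_integer_, 64), cods)
  dist[c1] <- 0L
  frontier <- c1
  while (is.na(dist[c2])) {
    nxt <- unique(unlist(lapply(frontier, function(x) cods[A[x, ]])))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  unname(dist[c2])
}

random_codon_map <- function() {
  stats::setNames(sample(codons()), codons())
}

# Synthetic four-category hydropathy classification (amino-acid level,
# Kyte-Doolittle-like grouping chosen so that third-position transition
# partners share categories); stop codons unlabelled except UGA, which is
# relabelled into Trp's moderately hydrophobic category.
synthetic_hydropathy <- function() {
  cats <- c(
    stats::setNames(rep("very-hydrophobic", 4), c("Ile", "Val", "Leu", "Met")),
    stats::setNames(rep("hydrophobic", 3), c("Phe", "Cys", "Ala")),
    stats::setNames(rep("moderately-hydrophobic", 6),
                    c("Gly", "Thr", "Ser", "Trp", "Tyr", "Pro")),
    stats::setNames(rep("hydrophilic", 7),
                    c("His", "Glu", "Gln", "Asp", "Asn", "Lys", "Arg"))
  )
  code <- standard_code()
  labels <- stats::setNames(unname(cats[code]), names(code))
  labels[["UGA"]] <- "moderately-hydrophobic"
  labels <- labels[!is.na(labels)]    # UAA, UAG stay unlabelled
  structure(list(name = "hydropathy-synthetic", labels = labels,
                 note = "synthetic 4-category hydropathy, UGA as moderately hydrophobic"),
            class = "codon_classification")
}

# Synthetic two-category polarity classification with UGA non-polar and the
# other stops polar.
synthetic_polarity <- function() {
  polar <- c("Ser", "Thr", "Tyr", "His", "Gln", "Asn", "Lys", "Asp", "Glu",
             "Arg", "Gly")
  code <- standard_code()
  labels <- ifelse(code == "STOP", "polar",
                   ifelse(code %in% polar, "polar", "non-polar"))
  labels[names(code) == "UGA"] <- "non-polar"
  structure(list(name = "polarity-synthetic",
                 labels = stats::setNames(labels, names(code)),
                 note = "synthetic polar/non-polar split, UGA non-polar"),
            class = "codon_classification")
}
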