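---
title: "Methods: the six-dimensional symmetry model of the genetic code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the six-dimensional symmetry model of the genetic code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonsym)
```

## The model

Two mutation types generate the symmetries of a nucleotide: transversions
and transitions. Taking `a` to be the complementary transversion (A↔U,
G↔C) and `b` the transition (A↔G, C↔U), with composition of a mutation
with itself equal to the identity, gives the Klein four-group
K4 = {e, a, b, ab} acting on {A, C, G, U} exactly as the symmetry group of
a rectangle acts on its vertices. The action extends component-wise to
codons: K4³ acts on the 64 triplets, and this action is *regular* — the
orbit of any codon under the 64 action triples is the whole codon space,
and every triple is its own inverse.

The word metric of the action (0 = identity, 1 = one generator,
2 = the composite `ab`) summed over the three positions makes codon space
a metric space isometric to the 6-cube: `hypercube_graph()` joins codons
at distance one and has 64 vertices of degree 6 and 192 edges. Its full
automorphism group is the hyperoctahedral group Z2⁶ ⋊ S6 of order 46 080,
which `hypercube_automorphisms()` materializes eagerly as 64-point codon
maps (a 46 080 × 64 index matrix; permutations of 64 points are cheap, so
no lazy group machinery is used).

### Cayley variants

The four nucleotides admit exactly three fixed-point-free involutions, and
a "Cayley variant" assigns two of them to the generator roles (a, b); the
third is forced to be `ab`. The graph depends only on which involution is
relegated to the composite (two-step) role, so of the six ordered
assignments only three distinct variants remain, enumerated by
`cayley_variants()`. The package default is biologically anchored:
`a` = complementary transversion, `b` = transition. The variant
`"ab-complement"` instead makes the complement the composite element; it
reproduces the convention of earlier binary-assignment models of the codon
hypercube, in which a codon and its base-wise complement sit at the
maximum distance 6 (under the default variant that distance is 3: one
single-generator step per position). "Base-wise complement" here means
position-wise complementation without reversal; reversal is a
reading-order convention that the metric does not see.

### Binary coordinates

No canonical 6-bit encoding is forced by the model, so the package fixes
one and asserts it in tests: for each position, bit 1 indicates membership
of the b-orbit of A and bit 2 membership of the a-orbit of A. Under the
default variant these are the purine indicator (A, G → 1) and the
weak-base indicator (A, U → 1). Derived this way the encoding works for
every variant: an `a` step flips exactly bit 1 of its position, a `b` step
exactly bit 2, and codon distance equals Hamming distance on the six bits.

## Biological tables and the stop policy

The standard code table is taken from Biostrings (`GENETIC_CODE`,
`AMINO_ACID_CODE`), with stops UAA, UAG, UGA. (Some figure legends in the
literature on this model list "UUA" among the stops; UUA is Leu in the
standard code, and the package keeps the standard assignments.)

The 20 amino acids split into two 10-member aminoacyl-tRNA synthetase
(aaRS) classes. `aars_classes("structural")` follows the enzymes'
structural classification (Phe in class II, Tyr in class I). Phe and Tyr
are the ambiguous pair, and `"functional"` mode swaps exactly them
(Phe → I, Tyr → II). The package treats the swap as an empirical question
and answers it by brute force: under the functional assignment — and only
under it — the isometries T1 and T2 below interchange the two classes with
zero violations, while the structural assignment leaves a deterministic
8-codon violation set (the Phe/Ser and Tyr/Cys wobble families), which the
tests regression-lock. Stop codons are attached to class I in both modes
(documented stop-codon captures are predominantly by class I amino acids);
this single policy is what makes the interchange exact, and interchange
reports flag stop-involving pairs so the dependence stays visible.

## The piecewise isometries

`make_T1()` / `make_T2()` are defined block-wise on the partition
{RNY, YNR, RNR, YNY}:

| block     | T1        | T2         |
|-----------|-----------|------------|
| RNY ↔ YNR | (a, b, a) | (a, b, ab) |
| RNR ↔ RNR | (e, b, e) | (e, b, b)  |
| YNY ↔ YNY | (e, b, e) | (e, b, b)  |

Because the triples are self-inverse and each rule's image block carries
the same triple, both maps are involutions; both are verified (not
assumed) to be hypercube automorphisms over all 192 edges. Their
composition collapses to the uniform triple (e, e, b) — a transition in
the wobble position — which `compose_maps()` recovers by re-expressing the
point-wise composite as rules: each codon determines a unique relating
triple (regularity), codons are grouped by triple, and each group is
compressed to an R/Y/N pattern when it is pattern-expressible.

`make_F()` is defined on the sixteen 4-codon blocks that fix R/Y at
positions 1 and 3 and a literal middle base; it converts the Rodin–Ohno
middle-base sub-codes {NAN, NGN, NUN, NCN} exactly onto
{RNR, YNR, RNY, YNY}, in that order (`verify_partition_mapping()` checks
block-image bijectivity exhaustively). The worked conversion AGC → UUG
and back is the canonical example.

Rule application never needs a tie-break: `piecewise_map()` validates at
construction that the domain patterns are pairwise disjoint and cover all
64 codons, so exactly one rule matches any codon, and malformed map files
are rejected with the offending codons named.

## Quotient chains

For a subgroup G of K4 the quotient N/G is the orbit partition of the
nucleotides (N/T = {R, Y} for the transition subgroup T = {e, b}; N/E four
singletons; N/K4 one class), and subgroup triples act component-wise on
codons. `delarue_chain("binary")` applies K4TK4, K4eK4, TeK4, eeK4, eeT,
eee in order, doubling the block count at each step
(1, 2, 4, 8, 16, 32, 64); `"quaternary"` applies K4eK4, eeK4, eee,
resolving one codon position per step (1, 4, 16, 64). Every step provably
refines its parent, and blocks are named by R/Y/N/base patterns whenever
pattern-expressible (every block arising in these chains is), with the
lexicographically smallest member as fallback. The genealogy this
algebraizes was originally narrated as *five* binary choices; the algebraic
rendering needs six products because the wobble assignment is counted as a
step of its own, and the package implements the six-product version.
Which stops sit in which block at each step is reported as annotation
only (`print(chain, annotate = TRUE)`, `delarue_chain_json()`), not
imposed as a constraint.

## The symmetry scanner

For a classification (any codon → label map) and a universe of
automorphisms — the 64 action triples or all 46 080 hypercube
automorphisms — `scan_symmetries()` classifies each map as
*label-preserving* (every codon maps within its label block) or
*block-permuting* (every label block maps setwise onto some label block;
partial overlaps disqualify, since only whole-category interchanges are of
interest). Block-permuting maps induce permutations of the label set, and
the induced permutations always form a group. Unlabelled codons must map
among themselves by default (`strict = TRUE`); `strict = FALSE` ignores
them instead, which is appropriate when stops are simply missing from a
user file rather than forming a category of their own.

For the default polar-requirement categories — the four middle-base
16-codon blocks, which are 4D subcubes — the scan *computes* (rather than
asserts) that the induced label group has order 8 and is the dihedral
group of the square, and that the setwise stabilizer of one category
restricts to 384 distinct permutations of its 16 codons, the order of the
4D hyperoctahedral group S2 ≀ S4. The published four-colour category
assignment itself is not recoverable from text sources, which is why the
middle-base blocks are the package default and user TSV files override
them; the same holds for the four hydropathy categories, so those claims
are exercised as property tests on files. The shipped
`inst/extdata/hydropathy_synthetic.tsv` and `polarity_synthetic.tsv` are
explicitly synthetic stand-ins built at the amino-acid level from a
Kyte–Doolittle-style grouping; with UGA placed in Trp's moderately
hydrophobic category the wobble transition (e, e, b) becomes an invariant
action, and with UGA non-polar and the other stops polar, (e, e, a) and
(e, e, ab) join it — the structure the model predicts, demonstrated on
synthetic data rather than on the unpublished originals.

`null_distribution()` quantifies how exceptional an observed invariance
is: labels are shuffled across the labelled codons (the label multiset is
preserved, so arrangement rather than composition is tested), the
invariant-action count is recomputed per replicate, and a one-sided
permutation p-value with the +1 continuity correction is reported. The
run is fully determined by its seed.

## Problem sizes and numerical choices

Everything in the model is finite and exact — there are no tolerances,
optimizations or floating-point comparisons anywhere in the core; the only
stochastic component is the label-shuffling null, which is seeded. The
test suite verifies group and action axioms exhaustively (4³ element
triples, all variants), metric properties and binary-coordinate
equivalence over all 64 × 64 codon pairs, automorphism soundness for the
full 46 080-map enumeration against a brute-force adjacency oracle, and
agreement of the scanner with a naive per-map check on the 64-triple
universe; random-map and random-classification property tests use fixed
seeds with a few dozen replicates each, and null-model examples use 10-30
replicates, sizes at which the whole suite runs in well under a minute.

## Limitations

* Only the standard nuclear code is modelled; mitochondrial and other
  variant codes, and anticodon-side conventions, are out of scope.
* The aaRS class tables encode the consensus assignments; organisms with
  non-canonical synthetases (e.g. class I LysRS in some archaea) are not
  represented.
* The scanner counts symmetries; it does not score error-minimization
  efficiency against numerical polar-requirement values.
* The quotient chains model the partition genealogy only; why a given
  differentiation step prefers minor- or major-groove recognition is not
  part of the algebra.
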