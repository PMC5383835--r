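# codonsym

Group-theoretic analysis of the standard genetic code (SGC) as a
six-dimensional hypercube.

The 64 codons carry a natural symmetry structure: the Klein four-group
K4 = {e, a, b, ab}, with `a` read as the complementary transversion
(A↔U, G↔C) and `b` as the transition (A↔G, C↔U), acts on each codon
position, so K4³ acts component-wise on codon space. The word metric of
this action (0 for identity, 1 for a single generator, 2 for the composite
`ab`) turns the codon table into the 6-cube Q6: 64 vertices, 192 edges,
automorphism group Z2⁶ ⋊ S6 of order 46 080. `codonsym` implements:

* the K4 action under all three admissible Cayley variants, the codon
  metric, binary coordinates and the hypercube graph with automorphism
  membership testing and full enumeration;
* the built-in biological tables: the standard code, the two 10-member
  aminoacyl-tRNA synthetase (aaRS) classes (structural and functional
  modes), and the RNY / middle-base / 16-block pattern partitions;
* the piecewise isometries **T1** and **T2** that interchange the codons of
  aaRS class I and class II, their composition **T3** = (e, e, b) — a
  wobble-position transition — and the isometry **F** that converts the
  Rodin–Ohno sub-codes {NAN, NGN, NUN, NCN} into {RNR, YNR, RNY, YNY};
* Delarue's differentiation genealogy as chains of refining quotient
  partitions NNN/G1G2G3 (six binary or three quaternary steps);
* a symmetry scanner that classifies automorphisms as label-preserving or
  block-permuting for any codon classification (aaRS class, polar
  requirement, hydropathy, user TSV files), computes the induced
  label-permutation group, and scores the observed symmetry against a
  label-shuffling null model.

## Worked example

```r
library(codonsym)

# The codon AGC sits in the Rodin-Ohno block RGY; the action (a, ab, a)
# carries it into the RNY-based model, and applying it again returns it:
act_codon(c("a", "ab", "a"), "AGC")
#> [1] "UUG"
act_codon(c("a", "ab", "a"), "UUG")
#> [1] "AGC"

# F performs this conversion on all 64 codons and maps the middle-base
# partition exactly onto the first/third-position R/Y partition:
verify_partition_mapping(make_F(), pattern_blocks("middle-base"),
                         pattern_blocks("first-third-RY"))$block_image_map
#>   NAN   NGN   NUN   NCN
#> "RNR" "YNR" "RNY" "YNY"

# T1 interchanges the two aaRS classes perfectly under the functional
# class assignment (Phe -> I, Tyr -> II, stops -> I):
verify_class_interchange(make_T1(), codon_classification("aars-functional"))$interchanges
#> [1] TRUE

# The four default polar-requirement categories (16-codon 4D subcubes):
scan_symmetries(codon_classification("pr-default"),
                "full-hypercube-automorphisms")
#> Symmetry scan of "pr-default" over full-hypercube-automorphisms (46080 maps)
#>   label-preserving maps : 384
#>   block-permuting maps  : 3072
#>   induced label group   : order 8
#>   block stabilizers     : NAN=384, NCN=384, NGN=384, NUN=384
```

The induced label group of order 8 is the dihedral group of the square
(whole categories interchange like the symmetries of a square), and each
category's setwise stabilizer restricts to the 4D hyperoctahedral group
S2 ≀ S4 of order 384 on its own 16 codons.

A thin command-line front end is installed as `exec/codonsym`:

```sh
codonsym transform --map F --codon AGC       # AGC -> UUG
codonsym delarue --mode binary --annotate
codonsym scan --classification my_labels.tsv --universe full --json report.json
```

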