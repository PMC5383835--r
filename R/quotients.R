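# Subgroups of K4, orbit partitions of nucleotides and codons under
# subgroup triples, and the Delarue differentiation genealogy rendered as a
# chain of refining quotient partitions.

SUBGROUP_ELEMENTS <- list(
  E  = "e",
  T  = c("e", "b"),
  A  = c("e", "a"),
  AB = c("e", "ab"),
  K4 = c("e", "a", "b", "ab")
)

#' The five subgroups of the Klein four-group
#'
#' K4 has exactly five subgroups: the trivial group E = \{e\}, the three
#' order-2 subgroups generated by each involution -- T = \{e, b\} (the
#' transition subgroup), A = \{e, a\}, AB = \{e, ab\} -- and K4 itself.
#'
#' @return A named list of element vectors.
#' @export
k4_subgroups <- function() SUBGROUP_ELEMENTS

as_subgroup <- function(s) {
  if (is.character(s) && length(s) == 1 && s %in% names(SUBGROUP_ELEMENTS)) {
    return(SUBGROUP_ELEMENTS[[s]])
  }
  if (is.character(s) && all(s %in% K4_ELEMENTS)) {
    for (nm in names(SUBGROUP_ELEMENTS)) {
      if (setequal(s, SUBGROUP_ELEMENTS[[nm]])) return(SUBGROUP_ELEMENTS[[nm]])
    }
  }
  stop(sprintf("not a subgroup of K4: %s", paste(s, collapse = ",")),
       call. = FALSE)
}

#' Parse a positional subgroup-triple string
#'
#' The compact notation names the subgroup acting at each codon position,
#' e.g. `"K4TK4"` (full group at positions 1 and 3, transitions at 2),
#' `"eeK4"`, `"eee"`. Tokens are `K4`, `AB`, `A`, `T`, `E`; a lower-case
#' `e` denotes the trivial subgroup.
#'
#' @param spec A string such as `"K4TK4"`, or a character vector of three
#'   subgroup names.
#' @return Character vector of three canonical subgroup names, class
#'   `subgroup_triple`.
#' @export
subgroup_triple <- function(spec) {
  if (length(spec) == 3) {
    names <- vapply(spec, function(s) {
      s <- if (s == "e") "E" else s
      if (!s %in% names(SUBGROUP_ELEMENTS)) {
        stop(sprintf("unknown subgroup \"%s\"", s), call. = FALSE)
      }
      s
    }, "")
  } else if (length(spec) == 1) {
    rest <- spec
    names <- character(0)
    while (nchar(rest) > 0) {
      tok <- regmatches(rest, regexpr("^(K4|AB|A|T|E|e)", rest))
      if (length(tok) == 0) {
        stop(sprintf("cannot parse subgroup triple \"%s\"", spec),
             call. = FALSE)
      }
      names <- c(names, if (tok == "e") "E" else tok)
      rest <- substring(rest, nchar(tok) + 1)
    }
    if (length(names) != 3) {
      stop(sprintf("\"%s\" does not name three subgroups", spec),
           call. = FALSE)
    }
  } else {
    stop("`spec` must be one string or three subgroup names", call. = FALSE)
  }
  structure(unname(names), class = "subgroup_triple")
}

#' Orbits of the nucleotides under a subgroup
#'
#' The quotient set N/S: the partition of \{A, C, G, U\} into orbits of the
#' subgroup's action. The transition subgroup T yields the purine and
#' pyrimidine classes \{R, Y\}; the trivial subgroup yields four
#' singletons; K4 yields one orbit.
#'
#' @param s A subgroup name (`"E"`, `"T"`, `"A"`, `"AB"`, `"K4"`) or
#'   element vector.
#' @param variant A `cayley_variant` or its name.
#' @return A list of nucleotide vectors (the orbits), ordered by first
#'   member.
#' @export
nucleotide_orbits <- function(s, variant = cayley_variant()) {
  elems <- as_subgroup(s)
  v <- as_cayley_variant(variant)
  seen <- character(0)
  orbits <- list()
  for (n in NUCLEOTIDES) {
    if (n %in% seen) next
    orb <- sort(unique(vapply(elems, act_nucleotide, "", n = n, variant = v)))
    orbits[[length(orbits) + 1]] <- orb
    seen <- c(seen, orb)
  }
  orbits
}

# Orbit of a set of codons under a subgroup triple: close the set under all
# triples of subgroup elements (component-wise action).
codon_orbits <- function(codon_set, st, variant = cayley_variant()) {
  v <- as_cayley_variant(variant)
  subs <- lapply(st, as_subgroup)
  triples <- expand.grid(g1 = subs[[1]], g2 = subs[[2]], g3 = subs[[3]],
                         stringsAsFactors = FALSE)
  remaining <- codon_set
  orbits <- list()
  while (length(remaining) > 0) {
    c0 <- remaining[1]
    orb <- unique(vapply(seq_len(nrow(triples)), function(k) {
      act_codon(unlist(triples[k, ]), c0, v)
    }, ""))
    orb <- sort(intersect(orb, codon_set))
    orbits[[length(orbits) + 1]] <- orb
    remaining <- setdiff(remaining, orb)
  }
  orbits
}

block_name <- function(block) {
  pat <- block_pattern(block)
  if (is.na(pat)) sort(block)[1] else pat
}

new_quotient_partition <- function(blocks, triple = NULL, parent = NULL,
                                   variant = "default") {
  names(blocks) <- vapply(blocks, block_name, "")
  structure(list(blocks = blocks, triple = triple, parent = parent,
                 variant = variant),
            class = "quotient_partition")
}

#' The root codon partition
#'
#' @return A `quotient_partition` with the single block NNN (all 64
#'   codons).
#' @export
quotient_root <- function() {
  new_quotient_partition(list(codons()))
}

#' Refine a codon partition by a subgroup triple
#'
#' Every block of the parent partition is split into the orbits of the
#' subgroup triple's component-wise action restricted to that block, so the
#' result always refines its parent. Blocks are named by their R/Y/N/base
#' pattern when pattern-expressible, otherwise by their smallest member.
#'
#' @param parent A `quotient_partition` (start from [quotient_root()]).
#' @param st A subgroup triple (string such as `"K4TK4"` or
#'   [subgroup_triple()] result).
#' @param variant A `cayley_variant` or its name.
#' @return A `quotient_partition` with the parent recorded.
#' @export
refine_partition <- function(parent, st, variant = cayley_variant()) {
  stopifnot(inherits(parent, "quotient_partition"))
  if (!inherits(st, "subgroup_triple")) st <- subgroup_triple(st)
  v <- as_cayley_variant(variant)
  blocks <- list()
  for (b in parent$blocks) {
    blocks <- c(blocks, codon_orbits(b, st, v))
  }
  new_quotient_partition(blocks, triple = st, parent = parent,
                         variant = v$name)
}

#' @export
print.quotient_partition <- function(x, annotate = FALSE, ...) {
  lab <- if (is.null(x$triple)) "root" else paste(x$triple, collapse = "-")
  cat(sprintf("Quotient partition (%s): %d block(s)\n", lab, length(x$blocks)))
  code <- if (annotate) standard_code() else NULL
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    extra <- ""
    if (annotate) {
      aa <- sort(unique(code[b]))
      extra <- sprintf("  [%s]", paste(aa, collapse = " "))
    }
    cat(sprintf("  %-4s (%2d)%s\n", nm, length(b), extra))
  }
  invisible(x)
}

#' The Delarue differentiation genealogy as quotient chains
#'
#' Renders the successive codon-ambiguity reductions of Delarue's genealogy
#' as a chain of quotient partitions starting from the undifferentiated
#' root NNN. In `"binary"` mode the six subgroup-triple products K4TK4,
#' K4eK4, TeK4, eeK4, eeT, eee are applied in order, doubling the block
#' count at each step (1, 2, 4, 8, 16, 32, 64) -- six binary decisions
#' including the wobble assignment. In `"quaternary"` mode the three
#' products K4eK4, eeK4, eee resolve one codon position per step
#' (1, 4, 16, 64).
#'
#' @param mode `"binary"` or `"quaternary"`.
#' @param variant A `cayley_variant` or its name.
#' @return An object of class `delarue_chain`: a list of
#'   `quotient_partition`s beginning with the root, with the applied
#'   triples as attribute `steps`.
#' @export
delarue_chain <- function(mode = c("binary", "quaternary"),
                          variant = cayley_variant()) {
  mode <- match.arg(mode)
  steps <- switch(mode,
    binary     = c("K4TK4", "K4eK4", "TeK4", "eeK4", "eeT", "eee"),
    quaternary = c("K4eK4", "eeK4", "eee")
  )
  chain <- list(quotient_root())
  for (s in steps) {
    chain[[length(chain) + 1]] <-
      refine_partition(chain[[length(chain)]], s, variant)
  }
  structure(chain, steps = steps, mode = mode, class = "delarue_chain")
}

#' @export
print.delarue_chain <- function(x, annotate = FALSE, ...) {
  cat(sprintf("Delarue %s chain: %s blocks\n", attr(x, "mode"),
              paste(vapply(x, function(p) length(p$blocks), 1L),
                    collapse = " -> ")))
  stops <- stop_codons()
  for (k in seq_along(x)) {
    step <- if (k == 1) "root" else attr(x, "steps")[k - 1]
    cat(sprintf("step %d (%s):\n", k - 1, step))
    for (nm in names(x[[k]]$blocks)) {
      b <- x[[k]]$blocks[[nm]]
      note <- ""
      if (annotate) {
        aa <- sort(unique(standard_code()[b]))
        st <- intersect(b, stops)
        note <- sprintf("  [%s]%s", paste(aa, collapse = " "),
                        if (length(st) > 0)
                          sprintf(" stops: %s", paste(st, collapse = ","))
                        else "")
      }
      cat(sprintf("  %s%s (%d)%s\n", strrep("  ", k - 1), nm, length(b), note))
    }
  }
  invisible(x)
}

#' Serialize a Delarue chain to JSON
#'
#' @param chain A `delarue_chain`.
#' @param file Optional path; when `NULL` the JSON string is returned.
#' @param annotate Attach amino acids and stop codons per block.
#' @return The JSON string (invisibly when written to `file`).
#' @export
delarue_chain_json <- function(chain, file = NULL, annotate = TRUE) {
  stopifnot(inherits(chain, "delarue_chain"))
  code <- standard_code()
  stops <- stop_codons()
  out <- lapply(seq_along(chain), function(k) {
    p <- chain[[k]]
    list(
      step = k - 1,
      quotient = if (k == 1) "root" else attr(chain, "steps")[k - 1],
      blocks = lapply(names(p$blocks), function(nm) {
        b <- p$blocks[[nm]]
        blk <- list(name = nm, codons = b)
        if (annotate) {
          blk$amino_acids <- sort(unique(unname(code[b])))
          blk$stops <- intersect(b, stops)
        }
        blk
      })
    )
  })
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
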