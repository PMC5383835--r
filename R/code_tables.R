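# Built-in biological tables: the standard genetic code, the
# aminoacyl-tRNA synthetase class partition, pattern partitions of the
# codon table, and classification file I/O.

STOP_LABEL <- "STOP"

# Structural aaRS class membership: each class activates 10 amino acids.
AARS_CLASS_I <- c("Arg", "Cys", "Gln", "Glu", "Ile", "Leu", "Met", "Trp",
                  "Tyr", "Val")
AARS_CLASS_II <- c("Ala", "Asn", "Asp", "Gly", "His", "Lys", "Phe", "Pro",
                   "Ser", "Thr")

#' The standard genetic code
#'
#' @return A named character vector over the 64 RNA codons giving the
#'   three-letter amino-acid code, or `"STOP"` for the three termination
#'   codons UAA, UAG and UGA.
#' @examples
#' standard_code()[["AUG"]]  # "Met"
#' @export
standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  rna <- gsub("T", "U", names(gc), fixed = TRUE)
  aa <- ifelse(gc == "*", STOP_LABEL,
               unname(Biostrings::AMINO_ACID_CODE[gc]))
  stats::setNames(aa, rna)[codons()]
}

stop_codons <- function() {
  code <- standard_code()
  names(code)[code == STOP_LABEL]
}

#' Aminoacyl-tRNA synthetase class assignment of the amino acids
#'
#' The 20 amino acids split into two 10-member classes according to which
#' synthetase superfamily activates them. In `"structural"` mode the split
#' follows the enzymes' structural classification (Phe in class II, Tyr in
#' class I). `"functional"` mode swaps exactly this ambiguous pair
#' (Phe -> I, Tyr -> II), the assignment under which the piecewise
#' isometries T1 and T2 interchange the two classes perfectly. In both
#' modes stop codons, when a codon-level classification is derived, are
#' attached to class I (most documented stop-codon captures are by class I
#' amino acids); see [codon_classification()].
#'
#' @param mode `"structural"` or `"functional"`.
#' @return An object of class `aars_class_map`: a list with `classes`
#'   (named character vector amino acid -> `"I"`/`"II"`), `mode`, and
#'   `stop_policy` (`"class-I"`).
#' @export
aars_classes <- function(mode = c("structural", "functional")) {
  mode <- match.arg(mode)
  cls <- c(
    stats::setNames(rep("I", 10), AARS_CLASS_I),
    stats::setNames(rep("II", 10), AARS_CLASS_II)
  )
  if (mode == "functional") {
    cls[["Phe"]] <- "I"
    cls[["Tyr"]] <- "II"
  }
  structure(list(classes = cls, mode = mode, stop_policy = "class-I"),
            class = "aars_class_map")
}

#' @export
print.aars_class_map <- function(x, ...) {
  cat(sprintf("aaRS class map (%s mode; stops -> class I)\n", x$mode))
  for (k in c("I", "II")) {
    cat(sprintf("  class %-2s: %s\n", k,
                paste(sort(names(x$classes)[x$classes == k]), collapse = " ")))
  }
  invisible(x)
}

# Expand an R/Y/N/base pattern such as "RNY" to the codons matching it.
match_pattern <- function(pattern) {
  pattern <- toupper(gsub("T", "U", pattern, fixed = TRUE))
  if (nchar(pattern) != 3 ||
      !all(strsplit(pattern, "")[[1]] %in% c(NUCLEOTIDES, "R", "Y", "N"))) {
    stop(sprintf("malformed codon pattern \"%s\"", pattern), call. = FALSE)
  }
  sets <- list(R = PURINES, Y = PYRIMIDINES, N = NUCLEOTIDES)
  ch <- strsplit(pattern, "")[[1]]
  pos <- lapply(ch, function(s) if (s %in% names(sets)) sets[[s]] else s)
  apply(expand.grid(pos[[1]], pos[[2]], pos[[3]], stringsAsFactors = FALSE),
        1, paste, collapse = "")
}

#' Named pattern partitions of the codon table
#'
#' Each scheme partitions the 64 codons into blocks defined by per-position
#' R (purine), Y (pyrimidine), N (any) or literal-base patterns:
#'
#' * `"first-third-RY"`: \{RNY, YNR, RNR, YNY\}, the four 16-codon blocks by
#'   purine/pyrimidine character at positions 1 and 3 (RNY is the primeval
#'   code; RNY with YNR covers 32 codons).
#' * `"middle-base"`: \{NAN, NGN, NUN, NCN\}, the Rodin-Ohno sub-codes, four
#'   16-codon blocks that are 4D subcubes of the hypercube.
#' * `"table5-blocks"`: the 16 four-codon blocks fixing R/Y at positions 1
#'   and 3 and a literal middle base (RAR, YGY, ...), the common refinement
#'   of the two schemes above.
#'
#' @param scheme A scheme name, or a character vector of patterns for a
#'   custom scheme.
#' @return An object of class `pattern_partition`: a named list of codon
#'   blocks with attribute `scheme`.
#' @export
pattern_blocks <- function(scheme = "first-third-RY") {
  if (length(scheme) == 1 && scheme %in%
      c("first-third-RY", "middle-base", "table5-blocks")) {
    patterns <- switch(scheme,
      "first-third-RY" = c("RNY", "YNR", "RNR", "YNY"),
      "middle-base"    = c("NAN", "NGN", "NUN", "NCN"),
      "table5-blocks"  = as.vector(outer(
        c("R", "Y"), as.vector(outer(NUCLEOTIDES, c("R", "Y"), paste0)),
        paste0))
    )
    name <- scheme
  } else {
    patterns <- scheme
    name <- "custom"
  }
  blocks <- stats::setNames(lapply(patterns, match_pattern), patterns)
  all <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all)) {
    stop(sprintf("patterns overlap on: %s",
                 paste(unique(all[duplicated(all)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!setequal(all, codons())) {
    stop(sprintf("patterns do not cover: %s",
                 paste(setdiff(codons(), all), collapse = ", ")),
         call. = FALSE)
  }
  structure(blocks, scheme = name, class = "pattern_partition")
}

#' @export
print.pattern_partition <- function(x, ...) {
  cat(sprintf("Pattern partition \"%s\": %d blocks\n",
              attr(x, "scheme"), length(x)))
  for (nm in names(x)) {
    cat(sprintf("  %-4s (%2d): %s\n", nm, length(x[[nm]]),
                paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Codon-level classifications
#'
#' A classification maps codons to free-form labels; it is the object that
#' symmetry scans and invariance checks operate on. Built-in kinds:
#'
#' * `"aars-structural"` / `"aars-functional"`: each codon is labelled by
#'   the aaRS class of its amino acid (see [aars_classes()]); stop codons
#'   receive class `"I"` under the package's stop policy.
#' * `"pr-default"`: the four 16-codon middle-base blocks, the package's
#'   default rendering of the four polar-requirement categories (they are
#'   the natural four-way split into 4D subcubes); the stop codons are
#'   flagged in the `stop_codons` attribute. Published category colourings
#'   are supplied instead through `"user-file"`.
#' * `"user-file"`: read from a two-column TSV via [read_classification()].
#'
#' @param kind One of `"aars-structural"`, `"aars-functional"`,
#'   `"pr-default"`, `"user-file"`.
#' @param source Path to the TSV file when `kind = "user-file"`.
#' @return An object of class `codon_classification`: a list with `name`,
#'   `labels` (named character vector codon -> label; unlabelled codons are
#'   absent) and `note`.
#' @export
codon_classification <- function(kind = c("aars-structural", "aars-functional",
                                          "pr-default", "user-file"),
                                 source = NULL) {
  kind <- match.arg(kind)
  if (kind == "user-file") {
    if (is.null(source)) stop("`source` file required for kind \"user-file\"",
                              call. = FALSE)
    return(read_classification(source))
  }
  code <- standard_code()
  if (kind %in% c("aars-structural", "aars-functional")) {
    mode <- sub("^aars-", "", kind)
    cm <- aars_classes(mode)
    labels <- ifelse(code == STOP_LABEL, "I", unname(cm$classes[code]))
    out <- new_classification(stats::setNames(labels, names(code)), kind,
                              note = sprintf("aaRS classes, %s mode; stops as class I", mode))
  } else {
    mb <- pattern_blocks("middle-base")
    labels <- stats::setNames(rep(names(mb), lengths(mb)),
                              unlist(mb, use.names = FALSE))[codons()]
    out <- new_classification(labels, "pr-default",
                              note = "four middle-base 4D subcubes as polar-requirement categories")
    attr(out, "stop_codons") <- stop_codons()
  }
  out
}

new_classification <- function(labels, name, note = "") {
  stopifnot(is.character(labels), !is.null(names(labels)))
  labels <- labels[!is.na(labels)]
  if (any(labels == "")) stop("classification labels must be non-empty",
                              call. = FALSE)
  bad <- !names(labels) %in% codons()
  if (any(bad)) {
    stop(sprintf("invalid codon(s) in classification: %s",
                 paste(names(labels)[bad], collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, labels = labels, note = note),
            class = "codon_classification")
}

#' @export
print.codon_classification <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Codon classification \"%s\": %d/64 codons labelled\n",
              x$name, length(x$labels)))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  if (nzchar(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' Read and write classification TSV files
#'
#' The format is two tab-separated columns, `codon<TAB>label`, with `#`
#' comment lines; DNA input (T) is normalized to U with a warning. Files
#' with duplicate codons, invalid codon strings or empty labels are
#' rejected with a message listing the offending lines.
#'
#' @param file Path to a TSV file.
#' @param name Classification name; defaults to the file name.
#' @return A `codon_classification`.
#' @export
read_classification <- function(file, name = basename(file)) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("classification file is empty", call. = FALSE)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2
  if (any(bad)) {
    stop(sprintf("malformed line(s) (need codon<TAB>label): %s",
                 paste(rows[bad], collapse = ", ")), call. = FALSE)
  }
  cod <- trimws(vapply(parts, `[`, "", 1))
  lab <- trimws(vapply(parts, `[`, "", 2))
  problems <- character(0)
  cod_norm <- character(length(cod))
  for (i in seq_along(cod)) {
    ok <- tryCatch({
      cod_norm[i] <- suppressWarnings(normalize_codons(cod[i]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) problems <- c(problems,
                           sprintf("line %d: invalid codon \"%s\"", rows[i], cod[i]))
  }
  if (any(grepl("T", cod, fixed = TRUE))) {
    warning("DNA alphabet detected: normalizing T to U", call. = FALSE)
  }
  empty <- !nzchar(lab)
  if (any(empty)) problems <- c(problems,
                                sprintf("line %d: empty label", rows[empty]))
  dup <- duplicated(cod_norm) & nzchar(cod_norm)
  if (any(dup)) problems <- c(problems,
                              sprintf("line %d: duplicate codon \"%s\"",
                                      rows[dup], cod_norm[dup]))
  if (length(problems) > 0) {
    stop(paste(c("invalid classification file:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  new_classification(stats::setNames(lab, cod_norm), name,
                     note = sprintf("read from %s", file))
}

#' @rdname read_classification
#' @param classification A `codon_classification` to write.
#' @export
write_classification <- function(classification, file) {
  stopifnot(inherits(classification, "codon_classification"))
  lines <- c(
    sprintf("# classification: %s", classification$name),
    paste(names(classification$labels), classification$labels, sep = "\t")
  )
  writeLines(lines, file)
  invisible(file)
}

#' Size of the space of possible genetic codes
#'
#' With 64 codons and 21 meanings (20 amino acids plus a termination mark),
#' there are 21^64, about 4 x 10^84, conceivable codes; scaling by the
#' reported one-in-a-million rate of random codes more efficient than the
#' standard one leaves about 4 x 10^78 codes as efficient as the standard
#' code.
#'
#' @return A list with `total` (21^64) and `as_efficient` (`total / 1e6`),
#'   both as doubles.
#' @export
code_space_size <- function() {
  total <- 21^64
  list(total = total, as_efficient = total / 1e6)
}
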