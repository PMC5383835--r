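# Graph export and fixture generation.

#' Export the codon hypercube to GraphML or DOT
#'
#' Writes the hypercube graph with codon-named vertices, generator/position
#' edge attributes, and optional vertex annotations: amino acid, aaRS
#' class, a classification label, and the 6-bit coordinate string.
#'
#' @param graph A graph from [hypercube_graph()].
#' @param file Output path.
#' @param format `"graphml"` or `"dot"`.
#' @param annotate_code Attach amino-acid names from [standard_code()].
#' @param class_mode `NULL`, `"structural"` or `"functional"`: attach the
#'   codon-level aaRS class.
#' @param classification Optional `codon_classification` attached as vertex
#'   attribute `label`.
#' @return The file path, invisibly.
#' @export
export_graph <- function(graph, file, format = c("graphml", "dot"),
                         annotate_code = TRUE, class_mode = NULL,
                         classification = NULL) {
  format <- match.arg(format)
  if (annotate_code) {
    code <- standard_code()
    graph <- igraph::set_vertex_attr(graph, "amino_acid",
                                     value = unname(code[igraph::V(graph)$name]))
  }
  if (!is.null(class_mode)) {
    cls <- codon_classification(paste0("aars-", class_mode))
    graph <- igraph::set_vertex_attr(graph, "aars_class",
                                     value = unname(cls$labels[igraph::V(graph)$name]))
  }
  if (!is.null(classification)) {
    lab <- aligned_labels(classification)
    graph <- igraph::set_vertex_attr(graph, "label",
                                     value = unname(lab[igraph::V(graph)$name]))
  }
  igraph::write_graph(graph, file, format = format)
  invisible(file)
}

#' Generate test fixtures
#'
#' Writes deterministic fixture files for negative-control and error-path
#' testing: `n` random k-label classifications, `n` random valid piecewise
#' maps on the \{RNY, YNR, RNR, YNY\} pattern scheme, and three deliberately
#' broken files (`broken-overlap.tsv`, `broken-noncover.tsv`,
#' `broken-codon.tsv`). Outputs are byte-identical for a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n Number of random classifications and maps (>= 1).
#' @param k Number of labels per random classification.
#' @return Character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, n = 3, k = 4) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)
  for (i in seq_len(n)) {
    labels <- paste0("cat", sample.int(k, 64, replace = TRUE))
    cls <- new_classification(stats::setNames(labels, codons()),
                              sprintf("random-%d", i))
    p <- file.path(dir, sprintf("classification-%d.tsv", i))
    write_classification(cls, p)
    paths <- c(paths, p)
  }
  patterns <- c("RNY", "YNR", "RNR", "YNY")
  for (i in seq_len(n)) {
    rules <- stats::setNames(
      lapply(patterns, function(p) sample(K4_ELEMENTS, 3, replace = TRUE)),
      patterns
    )
    m <- piecewise_map(rules, name = sprintf("random-map-%d", i))
    p <- file.path(dir, sprintf("map-%d.tsv", i))
    write_piecewise_map(m, p)
    paths <- c(paths, p)
  }
  broken <- list(
    "broken-overlap.tsv"  = c("RNY\ta,b,a", "RNN\te,e,e", "YNN\te,e,e"),
    "broken-noncover.tsv" = c("RNY\ta,b,a"),
    "broken-codon.tsv"    = c("AGX\tcat1", "AUG\tcat2")
  )
  for (nm in names(broken)) {
    p <- file.path(dir, nm)
    writeLines(broken[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
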