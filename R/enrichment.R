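#' Annotation set: gene-to-GO-term map over a screened universe
#'
#' @param annotations Named list: gene -> character vector of terms. Genes
#'   with no annotation may be omitted (they still count in denominators).
#' @param universe Character vector of all screened genes; every annotated
#'   gene must belong to it.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(annotations, universe) {
  stopifnot(is.list(annotations), is.character(universe))
  extra <- setdiff(names(annotations), universe)
  if (length(extra)) {
    stop("annotated genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(annotations = annotations, universe = unique(universe)),
            class = "annotation_set")
}

term_count <- function(genes, term, annotations) {
  sum(vapply(genes, function(g) term %in% (annotations[[g]] %||% character(0)),
             TRUE))
}

#' GO-term enrichment ratio for one phenotypic class
#'
#' The frequency of a term among the class genes divided by its frequency in
#' the entire screened set: `(k_class / n_class) / (K_universe / N_universe)`.
#' A ratio of 0 means the term does not appear in the class; ratios above 1
#' mean the term is over-represented in the class relative to the screen.
#'
#' @param term GO-term label.
#' @param class_genes Genes in the phenotypic class (subset of the universe).
#' @param annotations An [annotation_set()].
#' @return The enrichment ratio (>= 0).
#' @export
enrichment_ratio <- function(term, class_genes, annotations) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (length(class_genes) == 0) stop("empty phenotypic class")
  outside <- setdiff(class_genes, annotations$universe)
  if (length(outside)) {
    stop("class genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_univ <- length(annotations$universe)
  k_univ <- term_count(annotations$universe, term, annotations$annotations)
  if (k_univ == 0) {
    stop("term '", term, "' absent from the screened set: ratio undefined")
  }
  k_class <- term_count(class_genes, term, annotations$annotations)
  (k_class / length(class_genes)) / (k_univ / n_univ)
}

#' Term-by-class enrichment-ratio matrix
#'
#' @param terms Character vector of GO-term labels.
#' @param classes Named list: class label -> gene vector.
#' @param annotations An [annotation_set()].
#' @return Numeric matrix (terms x classes) of enrichment ratios. Terms
#'   absent from the universe yield `NA` for the whole row with a warning.
#' @export
enrichment_table <- function(terms, classes, annotations) {
  stopifnot(inherits(annotations, "annotation_set"), is.list(classes))
  m <- matrix(NA_real_, nrow = length(terms), ncol = length(classes),
              dimnames = list(terms, names(classes)))
  for (tm in terms) {
    present <- term_count(annotations$universe, tm,
                          annotations$annotations) > 0
    if (!present) {
      warning("term '", tm, "' absent from the screened set; row is NA")
      next
    }
    for (cl in names(classes)) {
      m[tm, cl] <- enrichment_ratio(tm, classes[[cl]], annotations)
    }
  }
  m
}

#' Severity colors used in network figures
#' @keywords internal
severity_colors <- c(Severe = "red", Intermediate = "orange", Weak = "blue",
                     None = "grey")

#' Assemble a severity-annotated gene-interaction network
#'
#' Builds an undirected graph over the classified genes; edges carry an
#' interaction kind (`genetic` or `physical`), duplicates are collapsed by
#' (endpoints, kind), self-loops (a gene interacting with itself) are kept,
#' and edges touching unknown genes are dropped with a warning.
#'
#' @param genes Data frame with columns `gene`, `severity`, and optionally
#'   `group` (functional group).
#' @param edges Data frame with columns `from`, `to`, `kind`.
#' @return An [igraph::graph] with vertex attributes `severity`, `color`,
#'   `group` and edge attribute `kind`.
#' @export
build_network <- function(genes, edges) {
  stopifnot(is.data.frame(genes), all(c("gene", "severity") %in% names(genes)),
            is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  if (is.null(edges$kind)) edges$kind <- "genetic"
  known <- edges$from %in% genes$gene & edges$to %in% genes$gene
  if (any(!known)) {
    warning(sum(!known), " edge(s) with unknown endpoints dropped")
    edges <- edges[known, , drop = FALSE]
  }
  # de-duplicate by unordered endpoints + kind
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- edges[!duplicated(paste(a, b, edges$kind, sep = "\r")), ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "kind")],
    directed = FALSE,
    vertices = data.frame(
      name = genes$gene,
      severity = genes$severity,
      color = unname(severity_colors[genes$severity]),
      group = genes$group %||% rep(NA_character_, nrow(genes))
    )
  )
  g
}

#' Serialize an interaction network
#'
#' @param graph An igraph object from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` (attribute-preserving, round-trippable) or
#'   `"tsv"` (plain `from<TAB>to<TAB>kind` edge list).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a serialized interaction network back
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"tsv"`.
#' @return An igraph object.
#' @export
import_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    el <- utils::read.delim(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(el, directed = FALSE)
  }
}
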