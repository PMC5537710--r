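#' Edge-type to signed-weight map
#'
#' Activation, phosphorylation and expression edges propagate with weight
#' +1; inhibition with -1. Binding/association and indirect edges are
#' treated as live +1 connections by default, switchable to 0 (inert) for
#' variants of the propagation that ignore them.
#'
#' @param binding_weight weight assigned to binding/association and
#'   indirect edges (+1 default, 0 to silence them).
#' @return named numeric vector mapping edge type to weight.
#' @export
edge_type_weights <- function(binding_weight = 1) {
  c(activation = 1, phosphorylation = 1, expression = 1,
    inhibition = -1,
    binding = binding_weight, `binding/association` = binding_weight,
    association = binding_weight, indirect = binding_weight)
}

#' Construct a pathway graph
#'
#' A pathway is a gene set plus signed, typed, directed edges. Edge
#' weights are determined by the type map; parallel edges of the same
#' type between the same ordered pair are collapsed.
#'
#' @param name pathway label.
#' @param genes character vector of member genes (node set).
#' @param edges data frame with columns `source`, `target`, `type` and
#'   optionally `pathway` (provenance). May have zero rows.
#' @param binding_weight see [edge_type_weights()].
#' @return object of class `pathway_graph`: list with `name`, `genes`,
#'   `edges` (with `weight` and `provenance` columns added).
#' @export
pathway_graph <- function(name, genes, edges = NULL, binding_weight = 1) {
  genes <- unique(as.character(genes))
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        type = character(), stringsAsFactors = FALSE)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$type <- tolower(as.character(edges$type))
  bad <- setdiff(c(edges$source, edges$target), genes)
  if (length(bad))
    stop("edge endpoints not in gene set: ", paste(bad, collapse = ", "))
  wm <- edge_type_weights(binding_weight)
  unknown <- setdiff(unique(edges$type), names(wm))
  if (length(unknown))
    stop("unknown edge type(s): ", paste(unknown, collapse = ", "))
  if (is.null(edges$provenance))
    edges$provenance <- rep(name, nrow(edges))
  key <- paste(edges$source, edges$target, edges$type, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    prov <- tapply(edges$provenance, key, function(p)
      paste(unique(p), collapse = ";"))
    edges <- edges[keep, , drop = FALSE]
    edges$provenance <- unname(prov[paste(edges$source, edges$target,
                                          edges$type, sep = "\r")])
  }
  edges$weight <- unname(wm[edges$type])
  rownames(edges) <- NULL
  structure(list(name = name, genes = genes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("Pathway graph '%s': %d genes, %d directed edges\n",
              x$name, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read pathway membership (GMT) and typed edge lists
#'
#' `read_gmt` parses the GMT dialect: one pathway per line,
#' tab-separated `name`, `description`, then member genes.
#' `read_pathway_edges` reads a TSV with header
#' `pathway, source, target, type`.
#' `read_pathways` combines both into a list of [pathway_graph()]s.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @return `read_pathway_edges`: data frame of typed edges.
#' @export
read_pathway_edges <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway", "source", "target", "type")
  if (!all(need %in% names(x)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname read_gmt
#' @param gmt_path GMT membership file.
#' @param edges_path typed edge-list TSV.
#' @param binding_weight see [edge_type_weights()].
#' @return `read_pathways`: named list of `pathway_graph` objects.
#' @export
read_pathways <- function(gmt_path, edges_path, binding_weight = 1) {
  members <- read_gmt(gmt_path)
  edges <- read_pathway_edges(edges_path)
  out <- lapply(names(members), function(nm) {
    e <- edges[edges$pathway == nm,
               c("source", "target", "type"), drop = FALSE]
    pathway_graph(nm, members[[nm]], e, binding_weight = binding_weight)
  })
  names(out) <- names(members)
  out
}

#' Fuse pathways into one network
#'
#' Node and edge union across pathways. Duplicate edges (same source,
#' target and type) are collapsed into one, keeping the provenance list
#' of contributing pathways. Conflicting types for the same ordered gene
#' pair are kept as distinct edges (a message notes them).
#'
#' @param graphs list of `pathway_graph` objects.
#' @param name name of the merged graph.
#' @return a merged `pathway_graph`.
#' @export
fuse_pathways <- function(graphs, name = "fused") {
  stopifnot(length(graphs) >= 1L)
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  genes <- unique(unlist(lapply(graphs, `[[`, "genes")))
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  g <- pathway_graph(name, genes, edges)
  pairkey <- paste(g$edges$source, g$edges$target, sep = "\r")
  n_conflict <- sum(duplicated(pairkey))
  if (n_conflict > 0)
    message(n_conflict,
            " gene pair(s) carry edges of more than one type; all kept")
  g
}

#' Restrict a pathway to genes measured on the array
#'
#' Nodes absent from the expression universe are dropped before
#' perturbation propagation; out-degrees are implicitly recomputed since
#' incident edges are removed.
#'
#' @param graph `pathway_graph`.
#' @param array_genes character vector of measured gene ids.
#' @return filtered `pathway_graph`.
#' @export
restrict_to_array <- function(graph, array_genes) {
  keep <- intersect(graph$genes, array_genes)
  e <- graph$edges[graph$edges$source %in% keep &
                   graph$edges$target %in% keep, , drop = FALSE]
  pathway_graph(graph$name, keep, e[, c("source", "target", "type",
                                        "provenance")])
}

# igraph view of a pathway graph (directed, possibly multi-edge)
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")],
    directed = TRUE,
    vertices = data.frame(name = graph$genes))
}
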