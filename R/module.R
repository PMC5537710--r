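#' Extract the DEG-connecting module from a fused pathway network
#'
#' For every ordered pair of differentially expressed genes (a, b) with a
#' directed path from a to b, all minimum-length directed paths are
#' enumerated; the module is the union of their nodes and edges. DEGs
#' that are connected to no other DEG (in either direction) are excluded.
#' Path length is the unweighted hop count; edge types do not affect it.
#'
#' @param merged fused `pathway_graph` (see [fuse_pathways()]).
#' @param degs character vector of differentially expressed gene ids.
#' @return object of class `module_graph`: a `pathway_graph` whose edges
#'   all lie on at least one shortest DEG-to-DEG path, plus a logical
#'   `is_deg` flag per node. Empty (with a warning) when no DEG pair is
#'   connected.
#' @examples
#' g <- pathway_graph("p", c("A", "X", "B"),
#'        data.frame(source = c("A", "X"), target = c("X", "B"),
#'                   type = "activation"))
#' extract_module(g, degs = c("A", "B"))
#' @export
extract_module <- function(merged, degs) {
  degs <- intersect(unique(degs), merged$genes)
  if (length(degs) == 0L)
    stop("no differentially expressed genes present in the network")
  ig <- as_igraph(merged)
  node_set <- character()
  pair_key <- character()
  if (length(degs) >= 2L) {
    dist <- igraph::distances(ig, v = degs, to = degs, mode = "out")
    for (a in degs) for (b in degs) {
      if (a == b || !is.finite(dist[a, b])) next
      sp <- igraph::all_shortest_paths(ig, from = a, to = b,
                                       mode = "out")$vpaths
      for (p in sp) {
        nm <- names(p)
        node_set <- c(node_set, nm)
        pair_key <- c(pair_key,
                      paste(nm[-length(nm)], nm[-1], sep = "\r"))
      }
    }
  }
  pair_key <- unique(pair_key)
  if (length(pair_key) == 0L) {
    warning("no directed path connects any DEG pair; module is empty")
    out <- pathway_graph("module", character())
    out$is_deg <- logical()
    class(out) <- c("module_graph", class(out))
    return(out)
  }
  keep_edge <- paste(merged$edges$source, merged$edges$target,
                     sep = "\r") %in% pair_key
  nodes <- unique(node_set)
  out <- pathway_graph("module", nodes,
                       merged$edges[keep_edge,
                                    c("source", "target", "type",
                                      "provenance"), drop = FALSE])
  out$is_deg <- stats::setNames(out$genes %in% degs, out$genes)
  class(out) <- c("module_graph", class(out))
  out
}

#' @export
print.module_graph <- function(x, ...) {
  cat(sprintf(
    "DEG module: %d nodes (%d DEGs, %d connectors), %d directed edges\n",
    length(x$genes), sum(x$is_deg), sum(!x$is_deg), nrow(x$edges)))
  if (module_is_cyclic(x)) cat("  note: module contains directed cycles\n")
  invisible(x)
}

# TRUE when the module's directed graph has a cycle
module_is_cyclic <- function(module) {
  if (nrow(module$edges) == 0L) return(FALSE)
  !igraph::is_dag(as_igraph(module))
}

#' Export a module graph as an edge-list TSV and DOT file
#'
#' @param module `module_graph`.
#' @param tsv_path,dot_path output paths (either may be `NULL` to skip).
#' @export
write_module <- function(module, tsv_path = NULL, dot_path = NULL) {
  if (!is.null(tsv_path)) {
    e <- module$edges
    e$source_is_deg <- module$is_deg[e$source]
    e$target_is_deg <- module$is_deg[e$target]
    utils::write.table(e, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(dot_path)) {
    lines <- c("digraph module {",
               sprintf("  \"%s\" [style=filled, fillcolor=%s];",
                       module$genes,
                       ifelse(module$is_deg[module$genes], "green",
                              "yellow")),
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       module$edges$source, module$edges$target,
                       module$edges$type),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(module)
}
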