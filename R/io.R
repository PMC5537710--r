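#' Read and write expression matrices and sample sheets
#'
#' The matrix dialect is TSV: first column gene id, header row of sample
#' ids. The sample sheet is a two-column TSV `sample`, `group`.
#'
#' @param path file path.
#' @return `read_expression`: numeric matrix with gene row names.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- x[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(x[, -1, drop = FALSE])
  if (anyNA(m)) stop("missing values in expression matrix")
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @return `read_groups`: named character vector (sample -> group).
#' @export
read_groups <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(x)))
    stop("sample sheet must have columns sample, group")
  stats::setNames(x$group, x$sample)
}

#' @rdname read_expression
#' @param x matrix to write (row names = gene/probe ids).
#' @param id_col header name of the id column.
#' @export
write_matrix_tsv <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @param groups named character vector (sample -> group).
#' @export
write_groups_tsv <- function(groups, path) {
  utils::write.table(
    data.frame(sample = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pathway membership and edges
#'
#' @param pathways named list of `pathway_graph`s.
#' @param gmt_path,edges_path output paths.
#' @export
write_pathways <- function(pathways, gmt_path, edges_path) {
  lines <- vapply(pathways, function(p)
    paste(c(p$name, "na", p$genes), collapse = "\t"), character(1))
  writeLines(lines, gmt_path)
  edges <- do.call(rbind, lapply(pathways, function(p) {
    if (nrow(p$edges) == 0L) return(NULL)
    data.frame(pathway = p$name, p$edges[, c("source", "target", "type")],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(gmt_path)
}

#' Read a beta-value matrix with its probe map and sample sheet
#'
#' @param beta_path TSV matrix (first column `probe`).
#' @param groups_path two-column sample sheet TSV.
#' @param probe_map_path TSV `probe`, `gene`.
#' @return a [beta_matrix()].
#' @export
read_beta <- function(beta_path, groups_path, probe_map_path = NULL) {
  v <- read_expression(beta_path)
  groups <- read_groups(groups_path)
  groups <- groups[colnames(v)]
  map <- if (!is.null(probe_map_path))
    utils::read.delim(probe_map_path, stringsAsFactors = FALSE) else NULL
  beta_matrix(v, groups, probe_map = map)
}
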