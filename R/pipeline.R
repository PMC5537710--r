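#' Validate pipeline input files
#'
#' Schema checks per format: the expression matrix (unique gene ids, no
#' missing values, numeric), the sample sheet (two groups covering the
#' matrix columns), pathway files (GMT lines, edge endpoints within
#' membership) and beta matrices (values within [0, 1]). Returns a
#' machine-readable issue list rather than stopping at the first
#' problem; an unreadable file is fatal.
#'
#' @param paths named list with any of `matrix`, `groups`, `gmt`,
#'   `edges`, `beta`.
#' @return data frame with columns `file`, `issue` (zero rows when all
#'   checks pass).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, issue = issue, stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      stop("unreadable file: ", paths[[nm]])
  }
  if (!is.null(paths$matrix)) {
    x <- utils::read.delim(paths$matrix, check.names = FALSE)
    ids <- x[[1]]
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      note(paths$matrix, paste("duplicated gene id:",
                               paste(dup, collapse = ", ")))
    m <- suppressWarnings(as.matrix(x[, -1, drop = FALSE]))
    if (anyNA(m)) note(paths$matrix, "missing or non-numeric values")
  }
  if (!is.null(paths$groups)) {
    g <- utils::read.delim(paths$groups, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(g)))
      note(paths$groups, "missing sample/group columns")
  }
  if (!is.null(paths$gmt) && !is.null(paths$edges)) {
    ok <- tryCatch({
      read_pathways(paths$gmt, paths$edges)
      TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) note(paths$gmt, ok)
  }
  if (!is.null(paths$beta)) {
    b <- utils::read.delim(paths$beta, check.names = FALSE)
    v <- as.matrix(b[, -1, drop = FALSE])
    bad <- which(v < 0 | v > 1, arr.ind = TRUE)
    if (nrow(bad))
      note(paths$beta,
           sprintf("%d beta value(s) outside [0, 1] (e.g. %.3g)",
                   nrow(bad), v[bad[1, 1], bad[1, 2]]))
  }
  if (length(issues) == 0L)
    return(data.frame(file = character(), issue = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, issues)
}

#' Run the expression arm of the pipeline end to end
#'
#' Orchestrates SAM differential expression, pathway impact analysis and
#' the module-level structural-equation comparison: DEGs are called at
#' the target FDR; pathways with `pGFdr` below the significance gate are
#' fused; the module spanned by directed shortest paths between DEGs is
#' extracted and its path model compared between conditions. When no
#' pathway passes the gate the module stage is skipped with an explicit
#' record (this mirrors treatments whose downstream analysis finds
#' nothing). Per-stage TSV/JSON outputs and a manifest (seed, input
#' checksums, versions) are written to `out_dir`.
#'
#' @param matrix_path,groups_path expression TSV and sample sheet.
#' @param gmt_path,edges_path pathway membership and typed edge list.
#' @param out_dir output directory (created if needed).
#' @param fdr SAM target FDR and the pGFdr significance gate.
#' @param delta optional fixed SAM delta (otherwise chosen for `fdr`).
#' @param n_perm SAM permutations.
#' @param n_boot pPERT bootstraps.
#' @param seed integer seed for every stochastic stage.
#' @param control_group label of the reference condition (defaults to
#'   the first group level).
#' @return invisibly, a list with `sam`, `spia`, `sem` (NULL when
#'   skipped), `files`.
#' @export
run_all <- function(matrix_path, groups_path, gmt_path, edges_path,
                    out_dir, fdr = 0.05, delta = NULL, n_perm = 200L,
                    n_boot = 2000L, seed = 1L, control_group = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  x <- read_expression(matrix_path)
  groups <- read_groups(groups_path)[colnames(x)]
  if (!is.null(control_group))
    groups <- factor(groups, levels = c(control_group,
                                        setdiff(unique(groups),
                                                control_group)))
  pathways <- read_pathways(gmt_path, edges_path)

  log_stage <- function(stage, t0)
    message(sprintf("[pertsyn] stage=%s elapsed=%.2fs seed=%d", stage,
                    as.numeric(Sys.time()) - t0, seed))

  t0 <- as.numeric(Sys.time())
  sam_fit <- sam(x, groups, target_fdr = fdr, delta = delta,
                 n_perm = n_perm, seed = seed)
  utils::write.table(sam_table(sam_fit), file.path(out_dir, "sam.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(s0 = sam_fit$s0, delta = sam_fit$delta, fdr = sam_fit$fdr,
         n_deg = sam_fit$n_called, n_perm = sam_fit$n_perm),
    file.path(out_dir, "sam_summary.json"), auto_unbox = TRUE,
    digits = NA)
  log_stage("sam", t0)

  t0 <- as.numeric(Sys.time())
  degs <- sam_degs(sam_fit)
  delta_e <- sam_fit$fold_change[degs]
  spia_res <- spia(pathways, delta_e, array_genes = rownames(x),
                   n_boot = n_boot, seed = seed)
  utils::write.table(as.data.frame(spia_res),
                     file.path(out_dir, "spia.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("spia", t0)

  sig <- spia_res$pathway[spia_res$p_g_fdr < fdr]
  sem_res <- NULL
  if (length(sig) == 0L || length(degs) == 0L) {
    jsonlite::write_json(
      list(status = "no significant pathways",
           gate = fdr, n_significant = 0),
      file.path(out_dir, "module_sem.json"), auto_unbox = TRUE,
      digits = NA)
  } else {
    t0 <- as.numeric(Sys.time())
    fused <- fuse_pathways(pathways[sig])
    fused <- restrict_to_array(fused, rownames(x))
    module <- extract_module(fused, degs)
    if (length(module$genes) == 0L) {
      jsonlite::write_json(
        list(status = "empty module (no connected DEG pair)"),
        file.path(out_dir, "module_sem.json"), auto_unbox = TRUE,
        digits = NA)
    } else {
      lv <- levels(as.factor(groups))
      sem_res <- sem_multigroup(module,
                                x[, groups == lv[1], drop = FALSE],
                                x[, groups == lv[2], drop = FALSE])
      utils::write.table(edge_differences(sem_res),
                         file.path(out_dir, "module_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_module(module, dot_path = file.path(out_dir, "module.dot"))
      jsonlite::write_json(
        list(status = "ok", lrt = sem_res$lrt, df = sem_res$df,
             p_value = sem_res$p_value,
             loglik_free = sem_res$loglik_free,
             loglik_constrained = sem_res$loglik_constrained,
             cyclic = sem_res$cyclic),
        file.path(out_dir, "module_sem.json"), auto_unbox = TRUE,
        digits = NA)
    }
    log_stage("module_sem", t0)
  }

  inputs <- c(matrix_path, groups_path, gmt_path, edges_path)
  manifest <- list(
    package = "pertsyn",
    version = as.character(utils::packageVersion("pertsyn")),
    r_version = R.version.string,
    seed = seed, fdr = fdr, n_perm = n_perm, n_boot = n_boot,
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     basename(inputs))),
    significant_pathways = as.list(sig)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sam = sam_fit, spia = spia_res, sem = sem_res,
                 significant_pathways = sig,
                 files = list.files(out_dir, full.names = TRUE)))
}
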