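#' Over-representation probability pNDE
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' number of differentially expressed genes in a pathway, given the
#' pathway's size on the array, the total number of DEGs and the size of
#' the measured gene universe.
#'
#' @param n_de_in_pathway observed DEGs in the pathway.
#' @param pathway_size genes of the pathway present on the array.
#' @param n_de_total total DEGs on the array.
#' @param universe_size number of measured genes.
#' @return `P(X >= n_de_in_pathway)` under hypergeometric sampling.
#' @export
p_nde <- function(n_de_in_pathway, pathway_size, n_de_total,
                  universe_size) {
  if (n_de_in_pathway < 0 ||
      n_de_in_pathway > min(pathway_size, n_de_total) ||
      pathway_size > universe_size || n_de_total > universe_size)
    stop("inconsistent counts for hypergeometric tail")
  if (n_de_in_pathway == 0) return(1)
  stats::phyper(n_de_in_pathway - 1, pathway_size,
                universe_size - pathway_size, n_de_total,
                lower.tail = FALSE)
}

#' Signed perturbation propagation over a pathway
#'
#' Solves the linear propagation system: each gene's perturbation factor
#' is its own expression change plus the normalised signed contribution
#' of its upstream regulators,
#' `PF(g) = dE(g) + sum_u beta_ug * PF(u) / Nds(u)`,
#' where `Nds(u)` is the out-degree of `u`. In matrix form
#' `(I - B) PF = dE` with `B[g, u] = beta_ug / Nds(u)`. The net
#' accumulation is `Acc(g) = PF(g) - dE(g)` and the pathway total
#' `tA = sum(Acc)`. A singular system is damped (`B <- 0.99 B`) and
#' re-solved, with a message.
#'
#' @param graph `pathway_graph` (already restricted to array genes).
#' @param delta_e named per-gene log2 fold change; genes absent from the
#'   vector count as 0 (non-DEGs).
#' @return list with `pf`, `acc` (named per gene) and scalar `ta`.
#' @export
accumulate_perturbation <- function(graph, delta_e) {
  genes <- graph$genes
  if (length(genes) == 0L) return(list(pf = numeric(), acc = numeric(),
                                       ta = 0))
  de <- stats::setNames(numeric(length(genes)), genes)
  common <- intersect(names(delta_e), genes)
  de[common] <- delta_e[common]
  pf <- drop(propagation_inverse(graph) %*% de)
  pf <- stats::setNames(as.numeric(pf), genes)
  acc <- pf - de
  list(pf = pf, acc = acc, ta = sum(acc))
}

# (I - B)^-1, damped when the system is singular or near-singular so
# that the observed tA and its bootstrap null use the same operator
propagation_inverse <- function(graph) {
  B <- propagation_matrix(graph)
  A <- diag(nrow(B)) - B
  if (nrow(B) > 0 && rcond(A) < 1e-10) {
    message("singular propagation system in '", graph$name,
            "'; damping B by 0.99 and re-solving")
    A <- diag(nrow(B)) - 0.99 * B
  }
  solve(A)
}

# B[target, source] = weight / outdegree(source)
propagation_matrix <- function(graph) {
  genes <- graph$genes
  B <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  e <- graph$edges
  if (nrow(e) == 0L) return(B)
  outdeg <- table(factor(e$source, levels = genes))
  for (i in seq_len(nrow(e))) {
    B[e$target[i], e$source[i]] <-
      B[e$target[i], e$source[i]] +
      e$weight[i] / as.numeric(outdeg[e$source[i]])
  }
  B
}

#' Bootstrap perturbation probability pPERT
#'
#' Probability of observing a total accumulated perturbation at least as
#' extreme as the one measured, under random placement of the observed
#' expression changes: the non-zero `delta_e` values are repeatedly
#' assigned to random genes of the pathway, `tA` is recomputed, and the
#' p-value is the fraction of median-centred bootstrap `|tA|` values at
#' or beyond the centred observed one, floored at `1/n_boot`.
#'
#' @inheritParams accumulate_perturbation
#' @param n_boot number of bootstrap reassignments (>= 200).
#' @param seed integer seed (mandatory; the bootstrap is the only source
#'   of randomness in the pathway test).
#' @return list with `p_pert`, `ta_obs`, `ta_boot`.
#' @export
p_pert <- function(graph, delta_e, n_boot = 2000L, seed) {
  if (missing(seed)) stop("seed is required for the pPERT bootstrap")
  if (n_boot < 200L) stop("n_boot must be >= 200")
  de_obs <- delta_e[names(delta_e) %in% graph$genes & delta_e != 0]
  if (length(de_obs) == 0L)
    return(list(p_pert = 1, ta_obs = 0, ta_boot = numeric()))
  ta_obs <- accumulate_perturbation(graph, de_obs)$ta
  vals <- as.numeric(de_obs)
  genes <- graph$genes
  Ainv <- propagation_inverse(graph)
  colsum_acc <- colSums(Ainv) - 1  # acc contribution of a unit change per gene
  ta_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pos <- sample.int(length(genes), length(vals))
      sum(colsum_acc[pos] * vals)
    }, numeric(1))
  })
  med <- stats::median(ta_boot)
  # tolerance keeps floating-point ties (equal |tA| up to round-off) in
  # the exceedance count
  tol <- 1e-9 * (1 + abs(ta_obs))
  p <- mean(abs(ta_boot - med) >= abs(ta_obs - med) - tol)
  list(p_pert = max(p, 1 / n_boot), ta_obs = ta_obs, ta_boot = ta_boot)
}

#' Combine pNDE and pPERT into a global pathway probability
#'
#' Fisher-product combination: with `c = pNDE * pPERT`,
#' `pG = c - c * ln(c)`, the probability that a product of two
#' independent uniforms is at most `c`. Zero inputs are clamped to the
#' smallest positive double.
#'
#' @param pnde,ppert probabilities in (0, 1].
#' @return global probability pG in (0, 1].
#' @export
combine_global <- function(pnde, ppert) {
  if (any(c(pnde, ppert) < 0) || any(c(pnde, ppert) > 1))
    stop("pnde and ppert must lie in [0, 1]")
  if (any(c(pnde, ppert) == 0)) {
    message("zero input probability clamped to machine minimum")
    pnde <- max(pnde, .Machine$double.xmin)
    ppert <- max(ppert, .Machine$double.xmin)
  }
  cc <- pnde * ppert
  ifelse(cc >= 1, 1, cc - cc * log(cc))
}

#' Signaling pathway impact analysis
#'
#' For each pathway: restricts the graph to measured genes, computes the
#' hypergeometric over-representation probability (pNDE), propagates the
#' observed expression changes over the signed topology to obtain the net
#' accumulated perturbation tA and its bootstrap probability (pPERT),
#' combines the two into a global probability pG, and adjusts across
#' pathways (Benjamini-Hochberg by default) into pGFdr.
#'
#' @param pathways list of `pathway_graph` objects.
#' @param delta_e named log2 fold changes of the DEGs (names = gene ids);
#'   all other measured genes count as unchanged.
#' @param array_genes character vector: the measured gene universe.
#' @param n_boot bootstrap size for pPERT.
#' @param seed integer seed.
#' @param adjust `"BH"` (default) or `"bonferroni"` for pGFdr.
#' @return object of class `spia_result`: data frame with one row per
#'   pathway (`pathway`, `n_genes_on_array`, `n_de`, `ta`, `p_nde`,
#'   `p_pert`, `p_g`, `p_g_fdr`), sorted by `p_g`.
#' @examples
#' p <- pathway_graph("toy", c("A", "B", "C"),
#'        data.frame(source = c("A", "B"), target = c("B", "C"),
#'                   type = "activation"))
#' spia(list(p), c(A = 2), array_genes = c("A", "B", "C", "D"),
#'      n_boot = 200, seed = 1)
#' @export
spia <- function(pathways, delta_e, array_genes, n_boot = 2000L, seed,
                 adjust = c("BH", "bonferroni")) {
  if (missing(seed)) stop("seed is required")
  adjust <- match.arg(adjust)
  degs <- names(delta_e)[delta_e != 0]
  degs <- intersect(degs, array_genes)
  universe <- length(array_genes)
  rows <- lapply(seq_along(pathways), function(i) {
    g <- restrict_to_array(pathways[[i]], array_genes)
    n_path <- length(g$genes)
    n_de <- length(intersect(degs, g$genes))
    pnde <- if (n_path == 0) 1 else
      p_nde(n_de, n_path, length(degs), universe)
    pp <- p_pert(g, delta_e, n_boot = n_boot,
                 seed = seed + i - 1L)
    data.frame(pathway = g$name, n_genes_on_array = n_path,
               n_de = n_de, ta = pp$ta_obs, p_nde = pnde,
               p_pert = pp$p_pert,
               p_g = combine_global(pnde, pp$p_pert),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_g_fdr <- stats::p.adjust(out$p_g, method = adjust)
  out <- out[order(out$p_g), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n_boot") <- n_boot
  class(out) <- c("spia_result", "data.frame")
  out
}

#' @export
print.spia_result <- function(x, digits = 4, ...) {
  cat("Signaling pathway impact analysis (", nrow(x), " pathways, ",
      attr(x, "n_boot"), " bootstraps)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
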