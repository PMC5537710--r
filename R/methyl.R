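#' Build a methylation beta-value matrix
#'
#' Beta-values are methylation fractions in [0, 1] (0 fully
#' unmethylated, 1 fully methylated), probes x samples, with a sample to
#' treatment-arm map and a probe to gene map. The canonical arm order is
#' CTR, EV, AZA, EV+AZA.
#'
#' @param values numeric matrix probes x samples, all in [0, 1].
#' @param groups character/factor of length `ncol(values)`.
#' @param probe_map data frame `probe`, `gene` covering the row names.
#' @param group_levels arm order used in summaries.
#' @return object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, groups,
                        probe_map = NULL,
                        group_levels = c("CTR", "EV", "AZA", "EV+AZA")) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1))
    stop("beta-values must lie in [0, 1]")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("cg", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values))) stop("probe ids must be unique")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("one group label per sample required")
  lv <- intersect(group_levels, unique(groups))
  if (length(lv) == 0L) lv <- unique(groups)
  if (is.null(probe_map))
    probe_map <- data.frame(probe = rownames(values),
                            gene = rownames(values),
                            stringsAsFactors = FALSE)
  structure(list(values = values,
                 groups = factor(groups, levels = lv),
                 probe_map = probe_map),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("Beta-value matrix: %d probes x %d samples, arms: %s\n",
              nrow(x$values), ncol(x$values),
              paste(levels(x$groups), collapse = ", ")))
  invisible(x)
}

# pooled observations (all probes of the subset x samples) per arm
pool_beta <- function(beta, probes = NULL) {
  v <- beta$values
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(v))
    if (length(miss))
      stop("unknown probes: ", paste(miss, collapse = ", "))
    v <- v[probes, , drop = FALSE]
  }
  obs <- as.vector(v)
  grp <- factor(rep(as.character(beta$groups), each = nrow(v)),
                levels = levels(beta$groups))
  empty <- levels(grp)[tabulate(grp, nbins = nlevels(grp)) == 0]
  if (length(empty))
    stop("group(s) with zero observations: ",
         paste(empty, collapse = ", "))
  list(obs = obs, grp = grp)
}

#' Kruskal-Wallis test on pooled beta-values
#'
#' Rank-based comparison of methylation across treatment arms. The
#' observations are the pooled beta-values of the probe subset (all
#' probes of the subset, all samples of the arm), matching a joint test
#' over a gene panel's probes; per-probe testing is available via
#' `per_probe = TRUE`.
#'
#' @param beta a [beta_matrix()].
#' @param probes optional probe subset (default: all probes).
#' @param per_probe run one test per probe instead of pooling.
#' @return pooled mode: list with `statistic` (tie-corrected H), `df`,
#'   `p_value`, `n`. Per-probe mode: a data frame of the same per probe.
#' @export
kruskal_wallis_beta <- function(beta, probes = NULL, per_probe = FALSE) {
  if (per_probe) {
    pr <- if (is.null(probes)) rownames(beta$values) else probes
    rows <- lapply(pr, function(p) {
      kt <- stats::kruskal.test(beta$values[p, ], beta$groups)
      data.frame(probe = p, statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value)
    })
    return(do.call(rbind, rows))
  }
  d <- pool_beta(beta, probes)
  kt <- stats::kruskal.test(d$obs, d$grp)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(d$obs))
}

#' Dunn post hoc test on pooled beta-values
#'
#' Pairwise rank comparisons following a Kruskal-Wallis test: for arms i
#' and j, `z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' where ranks are pooled over all arms and
#' `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties. Two-sided normal
#' p-values are adjusted across pairs (Benjamini-Hochberg by default;
#' Bonferroni available).
#'
#' @inheritParams kruskal_wallis_beta
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return data frame with `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(beta, probes = NULL,
                         adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  d <- pool_beta(beta, probes)
  r <- rank(d$obs)
  N <- length(r)
  ties <- table(d$obs)
  tie_corr <- sum(ties ^ 3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, d$grp, mean)
  ns <- tapply(r, d$grp, length)
  lv <- levels(d$grp)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[p[1]] + 1 / ns[p[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = unname(z), p_value = unname(p),
             p_adjusted = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Per-gene, per-arm beta-value summaries
#'
#' Box-plot style summaries (median and quartiles) of methylation per
#' gene and treatment arm, over all of the gene's probes and the arm's
#' samples. Genes without probes are listed in a `skipped` attribute.
#'
#' @param beta a [beta_matrix()].
#' @param genes genes to summarise (default: all mapped genes).
#' @return data frame `gene`, `group`, `n`, `q1`, `median`, `q3`, in the
#'   canonical arm order, with attribute `skipped`.
#' @export
gene_beta_summary <- function(beta, genes = NULL) {
  map <- beta$probe_map
  if (is.null(genes)) genes <- unique(map$gene)
  skipped <- genes[!genes %in% map$gene]
  genes <- setdiff(genes, skipped)
  rows <- list()
  for (g in genes) {
    probes <- intersect(map$probe[map$gene == g], rownames(beta$values))
    v <- beta$values[probes, , drop = FALSE]
    for (lv in levels(beta$groups)) {
      obs <- as.vector(v[, beta$groups == lv, drop = FALSE])
      q <- stats::quantile(obs, c(0.25, 0.5, 0.75))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, group = lv, n = length(obs),
                   q1 = q[[1]], median = q[[2]], q3 = q[[3]],
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
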