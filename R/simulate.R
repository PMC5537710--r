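#' Default module topology for simulations
#'
#' A 31-gene directed acyclic network patterned on the apoptotic
#' NGFR-RAC1-MAPK10-TP53-BAX/BCL2 axis and its neighbouring
#' PI3K-Akt / focal-adhesion / ECM-receptor genes, with typed signed
#' edges. It is the default planted module of the expression simulator,
#' chosen to match the scale of the module a real combination-treatment
#' analysis produces.
#'
#' @return a `pathway_graph` with 31 genes.
#' @export
ngfr_module_topology <- function() {
  e <- function(s, t, ty) data.frame(source = s, target = t, type = ty,
                                     stringsAsFactors = FALSE)
  edges <- rbind(
    e("NGF",     "NGFR",    "binding"),
    e("NGFR",    "RAC1",    "activation"),
    e("NGFR",    "CDC42",   "activation"),
    e("NGFR",    "ARHGDIB", "binding/association"),
    e("RAC1",    "MAPK10",  "indirect"),
    e("RAC1",    "PAK1",    "activation"),
    e("CDC42",   "PAK1",    "activation"),
    e("PAK1",    "MAP2K1",  "phosphorylation"),
    e("MAPK10",  "JUN",     "phosphorylation"),
    e("MAPK10",  "TP53",    "activation"),
    e("MDM2",    "TP53",    "inhibition"),
    e("TP53",    "BAX",     "expression"),
    e("BCL2",    "BAX",     "inhibition"),
    e("SHC1",    "GRB2",    "binding"),
    e("GRB2",    "SOS1",    "binding"),
    e("SOS1",    "HRAS",    "activation"),
    e("HRAS",    "PIK3CA",  "activation"),
    e("PIK3CA",  "AKT1",    "activation"),
    e("AKT1",    "MDM2",    "phosphorylation"),
    e("AKT1",    "MTOR",    "activation"),
    e("MTOR",    "RPS6KB1", "phosphorylation"),
    e("EPHA2",   "IRS1",    "activation"),
    e("IRS1",    "PIK3CA",  "activation"),
    e("FN1",     "ITGA1",   "binding"),
    e("COL4A1",  "ITGB1",   "binding"),
    e("ITGA1",   "PTK2",    "binding"),
    e("ITGB1",   "PTK2",    "binding"),
    e("PTK2",    "PIP5K1C", "phosphorylation"),
    e("PIP5K1C", "VCL",     "indirect"),
    e("VCL",     "ACTN1",   "binding/association"),
    e("PTK2",    "RAC1",    "activation")
  )
  genes <- unique(c(edges$source, edges$target))
  pathway_graph("ngfr_module", genes, edges)
}

#' Simulate single-agent dose-response viability
#'
#' Viability follows the median-effect model,
#' `v(D) = 1 / (1 + (D / Dm)^m)`, perturbed by multiplicative lognormal
#' noise and clipped to [0, 1].
#'
#' @param drug label.
#' @param m sigmoidicity slope (> 0).
#' @param Dm median-effect dose in nM (> 0).
#' @param doses dose grid in nM.
#' @param n_rep replicates per dose.
#' @param noise_sd lognormal sigma of the multiplicative noise (0 =
#'   noise-free).
#' @param seed integer seed.
#' @param ratio dose-share weights recorded in the table.
#' @return a [viability_table()].
#' @export
sim_dose_response <- function(drug, m, Dm, doses = 10 ^ seq(-1, 2, 0.5),
                              n_rep = 4L, noise_sd = 0.05, seed = 1L,
                              ratio = c(1, 0)) {
  if (m <= 0 || Dm <= 0) stop("m and Dm must be positive")
  v0 <- 1 / (1 + (doses / Dm) ^ m)
  v <- withr::with_seed(seed, {
    matrix(rep(v0, n_rep) *
             exp(stats::rnorm(length(doses) * n_rep, 0, noise_sd)),
           nrow = length(doses))
  })
  viability_table(drug, doses, pmin(pmax(v, 0), 1), ratio = ratio)
}

#' Simulate a fixed-ratio combination with a planted interaction
#'
#' Inverts the combination-index definition: for each target effect
#' level `fa`, the total combination dose is the one for which the
#' two-term index equals the planted `CI(fa)`,
#' `Dtot = CI / (ratio_1 / Dx_1(fa) + ratio_2 / Dx_2(fa))`,
#' where `Dx_i` come from the given single-agent parameters. The
#' resulting (dose, 1 - fa) pairs, plus noise, form the table. A planted
#' CI of 1 is exact Loewe additivity; below 1 synergy; above 1
#' antagonism.
#'
#' @param singles list of two lists with elements `m`, `Dm` (single-agent
#'   parameters, same order as `ratio`).
#' @param ratio length-2 dose-share weights summing to 1.
#' @param target_ci planted combination index: a scalar or a function of
#'   `fa`.
#' @param fa_grid effect levels generated.
#' @inheritParams sim_dose_response
#' @return a [viability_table()] on the total-dose axis.
#' @export
sim_combination <- function(singles, ratio = c(0.5, 0.5), target_ci = 1,
                            fa_grid = seq(0.1, 0.9, by = 0.1),
                            n_rep = 4L, noise_sd = 0.05, seed = 1L,
                            drug = "combo") {
  stopifnot(length(singles) == 2L)
  ci_fun <- if (is.function(target_ci)) target_ci else
    function(fa) rep(target_ci, length(fa))
  ci <- ci_fun(fa_grid)
  if (any(ci <= 0)) stop("target CI must be positive")
  dx <- vapply(singles, function(s)
    s$Dm * (fa_grid / (1 - fa_grid)) ^ (1 / s$m), numeric(length(fa_grid)))
  d_tot <- ci / (ratio[1] / dx[, 1] + ratio[2] / dx[, 2])
  v0 <- 1 - fa_grid
  v <- withr::with_seed(seed, {
    matrix(rep(v0, n_rep) *
             exp(stats::rnorm(length(v0) * n_rep, 0, noise_sd)),
           nrow = length(v0))
  })
  viability_table(drug, d_tot, pmin(pmax(v, 0), 1), ratio = ratio)
}

#' Simulate module-gene expression from linear structural equations
#'
#' Generates samples over the module's genes in topological order:
#' `child = sum(coefficient x parent) + N(0, noise_sd)`, exogenous nodes
#' pure noise. Coefficients are per ordered parent-child pair, in the
#' order of `unique(module$edges[, c("source","target")])`; their signs
#' are free (an inhibition edge would normally carry a negative one).
#'
#' @param module acyclic `pathway_graph` / `module_graph`.
#' @param coefficients numeric vector, one per unique ordered edge pair
#'   (recycled if length 1).
#' @param n number of samples.
#' @param noise_sd Gaussian error standard deviation.
#' @param seed integer seed.
#' @param shift named vector of per-gene mean shifts added to the node's
#'   equation (propagates downstream), e.g. planted DEG effects.
#' @return genes x n numeric matrix.
#' @export
sim_module_data <- function(module, coefficients, n, noise_sd = 1,
                            seed = 1L, shift = NULL) {
  if (module_is_cyclic(module))
    stop("generation topology must be acyclic")
  pairs <- unique(module$edges[, c("source", "target")])
  coefficients <- rep_len(coefficients, nrow(pairs))
  ord <- names(igraph::topo_sort(as_igraph(module)))
  x <- matrix(0, length(module$genes), n,
              dimnames = list(module$genes, NULL))
  withr::with_seed(seed, {
    for (g in ord) {
      parents <- pairs$source[pairs$target == g]
      b <- coefficients[pairs$target == g]
      mu <- if (length(parents))
        drop(crossprod(x[parents, , drop = FALSE], b)) else 0
      sh <- if (!is.null(shift) && g %in% names(shift)) shift[[g]] else 0
      x[g, ] <- mu + sh + stats::rnorm(n, 0, noise_sd)
    }
  })
  x
}

#' Simulate a two-condition expression study with planted truth
#'
#' Emulates a two-colour-free microarray comparison of a treatment arm
#' against untreated control: background genes are i.i.d. Gaussian on the
#' log2 scale; a planted module is generated from linear structural
#' equations with group-specific path coefficients; differential
#' expression is planted as mean shifts in the treatment arm, both on a
#' random background subset and on the module's source nodes (so the
#' module's DEGs propagate a coherent perturbation, as the pathway
#' analysis expects).
#'
#' @param n_genes total background genes (module genes are added on top).
#' @param n_per_group samples per condition.
#' @param n_deg_background background genes receiving a mean shift.
#' @param effect_size mean shift (log2 units) of planted DEGs.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param module planted module topology (`NULL` for none;
#'   default [ngfr_module_topology()]).
#' @param base_coef absolute path coefficient shared by unperturbed
#'   edges; each edge's sign follows its type weight.
#' @param perturb_edges data frame `source`, `target` of edges whose
#'   coefficient differs between conditions (`NULL` for none).
#' @param perturb_size amount added to the treatment coefficient of each
#'   perturbed edge.
#' @param module_deg module genes planted as DEGs (default: exogenous
#'   module nodes).
#' @param seed integer seed.
#' @return list with `matrix` (genes x 2*n samples, control first),
#'   `groups`, `deg_truth`, `module`, `coef_control`, `coef_treat`,
#'   `perturbed_edges`, `seed`.
#' @export
sim_expression <- function(n_genes = 20000L, n_per_group = 3L,
                           n_deg_background = 40L, effect_size = 2,
                           noise_sd = 1, module = ngfr_module_topology(),
                           base_coef = 0.6, perturb_edges = NULL,
                           perturb_size = 1.5, module_deg = NULL,
                           seed = 1L) {
  n <- n_per_group
  bg_ids <- sprintf("BG%05d", seq_len(n_genes))
  out <- withr::with_seed(seed, {
    bg_deg <- sample(bg_ids, min(n_deg_background, n_genes))
    x_ctrl <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)
    x_trt <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n)
    rownames(x_ctrl) <- rownames(x_trt) <- bg_ids
    x_trt[bg_deg, ] <- x_trt[bg_deg, ] + effect_size
    list(bg_deg = bg_deg, x_ctrl = x_ctrl, x_trt = x_trt)
  })
  deg_truth <- out$bg_deg
  coef_control <- coef_treat <- NULL
  perturbed <- NULL
  if (!is.null(module)) {
    pairs <- unique(module$edges[, c("source", "target")])
    wm <- edge_type_weights()
    sign_of <- vapply(seq_len(nrow(pairs)), function(i) {
      ty <- module$edges$type[module$edges$source == pairs$source[i] &
                              module$edges$target == pairs$target[i]][1]
      unname(wm[ty])
    }, numeric(1))
    coef_control <- base_coef * sign_of
    coef_treat <- coef_control
    if (!is.null(perturb_edges)) {
      idx <- match(paste(perturb_edges$source, perturb_edges$target),
                   paste(pairs$source, pairs$target))
      if (anyNA(idx)) stop("perturb_edges not found in module")
      coef_treat[idx] <- coef_treat[idx] + perturb_size
      perturbed <- pairs[idx, , drop = FALSE]
    }
    if (is.null(module_deg)) {
      indeg <- table(factor(pairs$target, levels = module$genes))
      module_deg <- module$genes[indeg == 0]
    }
    shift <- stats::setNames(rep(effect_size, length(module_deg)),
                             module_deg)
    m_ctrl <- sim_module_data(module, coef_control, n,
                              noise_sd = noise_sd, seed = seed + 1L)
    m_trt <- sim_module_data(module, coef_treat, n, noise_sd = noise_sd,
                             seed = seed + 2L, shift = shift)
    out$x_ctrl <- rbind(out$x_ctrl, m_ctrl)
    out$x_trt <- rbind(out$x_trt, m_trt)
    deg_truth <- c(deg_truth, module_deg)
  }
  x <- cbind(out$x_ctrl, out$x_trt)
  colnames(x) <- c(paste0("CTR_", seq_len(n)), paste0("TRT_", seq_len(n)))
  list(matrix = x,
       groups = rep(c("CTR", "TRT"), each = n),
       deg_truth = deg_truth,
       module = module,
       coef_control = coef_control, coef_treat = coef_treat,
       perturbed_edges = perturbed,
       seed = seed)
}

#' Simulate pathway definitions hosting a planted module
#'
#' Builds one host pathway that contains the planted module (its genes
#' and edges, padded with extra background genes and random typed edges)
#' plus decoy pathways of random signed edges over background genes, so
#' that pathway impact analysis and module fusion can be exercised end
#' to end with known truth.
#'
#' @param module the planted module (`pathway_graph`).
#' @param all_genes measured gene universe the decoys draw from.
#' @param n_decoys number of decoy pathways.
#' @param size_range min/max genes per decoy (host is padded to at least
#'   `min`).
#' @param edge_factor edges per gene in decoys.
#' @param seed integer seed.
#' @return named list of `pathway_graph`s; the host is named `"host"`.
#' @export
sim_pathways <- function(module, all_genes, n_decoys = 7L,
                         size_range = c(25L, 60L), edge_factor = 1.5,
                         seed = 1L) {
  if (size_range[1] < length(module$genes))
    size_range[1] <- length(module$genes)
  types <- c("activation", "inhibition", "binding", "indirect",
             "phosphorylation")
  bg <- setdiff(all_genes, module$genes)
  # salt the seed so a shared base seed does not replay the expression
  # simulator's RNG stream (which would align decoys with planted DEGs)
  withr::with_seed(seed + 104729L, {
    pad <- sample(bg, max(0, size_range[1] - length(module$genes)))
    host_genes <- c(module$genes, pad)
    extra <- random_typed_edges(host_genes,
                                round(edge_factor * length(pad)), types)
    host <- pathway_graph("host", host_genes,
                          rbind(module$edges[, c("source", "target",
                                                 "type")], extra))
    decoys <- lapply(seq_len(n_decoys), function(i) {
      sz <- sample(size_range[1]:size_range[2], 1)
      g <- sample(bg, min(sz, length(bg)))
      pathway_graph(paste0("decoy", i), g,
                    random_typed_edges(g, round(edge_factor * sz), types))
    })
    out <- c(list(host = host), decoys)
    names(out) <- vapply(out, `[[`, character(1), "name")
    out
  })
}

random_typed_edges <- function(genes, n_edges, types) {
  if (n_edges <= 0 || length(genes) < 2)
    return(data.frame(source = character(), target = character(),
                      type = character(), stringsAsFactors = FALSE))
  s <- sample(genes, n_edges, replace = TRUE)
  t <- sample(genes, n_edges, replace = TRUE)
  keep <- s != t
  unique(data.frame(source = s[keep], target = t[keep],
                    type = sample(types, sum(keep), replace = TRUE),
                    stringsAsFactors = FALSE))
}

#' Simulate a four-arm methylation beta-value matrix
#'
#' Beta-distributed methylation fractions per probe with arm-specific
#' means: AZA-containing arms (AZA, EV+AZA) receive a planted
#' demethylation shift, emulating the hypomethylating action of the
#' demethylating agent, while everolimus alone leaves methylation
#' unchanged.
#'
#' @param genes gene panel (probes are spread over it).
#' @param n_probes total probes across the panel.
#' @param n_per_arm samples per treatment arm.
#' @param base_mean methylation mean of CTR and EV arms, in (0, 1).
#' @param aza_shift change in mean for AZA-containing arms (negative =
#'   demethylation).
#' @param concentration beta-distribution precision (larger = tighter).
#' @param seed integer seed.
#' @return a [beta_matrix()] with arms CTR, EV, AZA, EV+AZA.
#' @export
sim_beta <- function(genes = c("NGFR", "MAPK10", "TP53", "BAX", "BCL2"),
                     n_probes = 125L, n_per_arm = 2L, base_mean = 0.6,
                     aza_shift = -0.2, concentration = 30, seed = 1L) {
  arms <- c("CTR", "EV", "AZA", "EV+AZA")
  means <- c(CTR = base_mean, EV = base_mean,
             AZA = base_mean + aza_shift,
             `EV+AZA` = base_mean + aza_shift)
  if (any(means <= 0 | means >= 1))
    stop("arm means must lie strictly inside (0, 1)")
  gene_of <- rep(genes, length.out = n_probes)
  probe_mu <- withr::with_seed(seed, {
    # probe-level baseline wobble around the arm mean
    stats::runif(n_probes, -0.05, 0.05)
  })
  groups <- rep(arms, each = n_per_arm)
  v <- withr::with_seed(seed + 1L, {
    vapply(groups, function(arm) {
      mu <- pmin(pmax(means[[arm]] + probe_mu, 0.02), 0.98)
      stats::rbeta(n_probes, mu * concentration,
                   (1 - mu) * concentration)
    }, numeric(n_probes))
  })
  rownames(v) <- sprintf("cg%05d", seq_len(n_probes))
  colnames(v) <- paste0(groups, "_", sequence(rep(n_per_arm, 4)))
  beta_matrix(v, groups,
              probe_map = data.frame(probe = rownames(v), gene = gene_of,
                                     stringsAsFactors = FALSE))
}
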