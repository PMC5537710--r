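test_that("pNDE equals exhaustive enumeration on small universes", {
  expect_equal(p_nde(0, 5, 3, 20), 1)
  expect_equal(p_nde(5, 5, 5, 10), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(p_nde(1, 2, 2, 4), 5 / 6, tolerance = 1e-12)
  for (universe in c(6, 9, 12)) {
    for (pathway in c(2, 4)) {
      for (de_total in c(2, 4)) {
        for (obs in 0:min(pathway, de_total)) {
          expect_equal(
            p_nde(obs, pathway, de_total, universe),
            oracle_pnde_enum(obs, pathway, de_total, universe),
            tolerance = 1e-12,
            info = sprintf("u=%d p=%d k=%d x=%d", universe, pathway,
                           de_total, obs))
        }
      }
    }
  }
  expect_error(p_nde(6, 5, 5, 10), "inconsistent")
})

test_that("perturbation accumulation solves the propagation system", {
  chain <- pathway_graph("c", c("A", "B"),
    data.frame(source = "A", target = "B", type = "activation"))
  res <- accumulate_perturbation(chain, c(A = 1))
  expect_equal(unname(res$pf), c(1, 1))
  expect_equal(unname(res$acc), c(0, 1))
  expect_equal(res$ta, 1)
  inhib <- pathway_graph("c", c("A", "B"),
    data.frame(source = "A", target = "B", type = "inhibition"))
  expect_equal(accumulate_perturbation(inhib, c(A = 1))$ta, -1)
  # no perturbation in, none out
  expect_equal(accumulate_perturbation(chain, c(A = 0))$ta, 0)
  # linearity in the expression change
  g <- random_dag(10, 0.3, seed = 5)
  de <- c(n1 = 1.2, n3 = -0.7)
  expect_equal(accumulate_perturbation(g, 2 * de)$ta,
               2 * accumulate_perturbation(g, de)$ta, tolerance = 1e-10)
})

test_that("linear-system solution equals relaxed fixed-point iteration", {
  checked <- 0
  for (s in 1:200) {
    g <- if (s %% 2 == 0) random_dag(12, 0.25, seed = s)
         else random_pathway(10, 18, seed = s)
    B <- pertsyn:::propagation_matrix(g)
    if (max(abs(eigen(B, only.values = TRUE)$values)) >= 0.99) next
    de <- withr::with_seed(s, {
      v <- numeric(length(g$genes))
      v[sample.int(length(v), 3)] <- rnorm(3)
      stats::setNames(v, g$genes)
    })
    pf <- accumulate_perturbation(g, de)$pf
    pf_iter <- oracle_fixed_point(B, de[g$genes])
    expect_equal(unname(pf), unname(pf_iter), tolerance = 1e-8)
    checked <- checked + 1
    if (checked >= 100) break
  }
  expect_gte(checked, 100)
})

test_that("singular propagation systems are damped and re-solved", {
  loop <- pathway_graph("loop", c("A", "B"),
    data.frame(source = c("A", "B"), target = c("B", "A"),
               type = "activation"))
  expect_message(res <- accumulate_perturbation(loop, c(A = 1)),
                 "damping")
  expect_true(all(is.finite(res$pf)))
})

test_that("pPERT conventions: no DEGs, symmetric graphs, determinism", {
  g <- pathway_graph("c", c("A", "B"),
    data.frame(source = "A", target = "B", type = "activation"))
  expect_equal(p_pert(g, c(Z = 2), n_boot = 200, seed = 1)$p_pert, 1)
  # edgeless graph: every assignment gives tA = 0, so p = 1
  flat <- pathway_graph("flat", c("A", "B", "C"))
  expect_equal(p_pert(flat, c(A = 1.5), n_boot = 200, seed = 1)$p_pert, 1)
  # exchange-symmetric toy: all placements give identical tA
  sym <- suppressMessages(
    pathway_graph("sym", c("A", "B", "C"),
      data.frame(source = c("A", "A", "B", "B", "C", "C"),
                 target = c("B", "C", "A", "C", "A", "B"),
                 type = "activation")))
  expect_equal(suppressMessages(
    p_pert(sym, c(A = 2), n_boot = 200, seed = 3)$p_pert), 1)
  # fixed seed reproducibility
  gg <- random_dag(15, 0.2, seed = 9)
  de <- c(n2 = 1, n5 = -2, n9 = 0.5)
  p1 <- p_pert(gg, de, n_boot = 500, seed = 7)$p_pert
  p2 <- p_pert(gg, de, n_boot = 500, seed = 7)$p_pert
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 500)
  expect_error(p_pert(gg, de, n_boot = 50, seed = 1), "200")
})

test_that("global probability combines evidence as the Fisher product tail", {
  expect_equal(combine_global(1, 1), 1)
  expect_equal(combine_global(0.1, 0.1), 0.01 - 0.01 * log(0.01),
               tolerance = 1e-12)
  expect_message(p0 <- combine_global(0, 0.5), "clamped")
  expect_gt(p0, 0)
  # pG >= product, and BH preserves the ranking
  expect_gte(combine_global(0.2, 0.3), 0.06)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("spia ranks an enriched, coherently perturbed pathway first", {
  sim <- sim_expression(n_genes = 400, n_per_group = 50,
                        n_deg_background = 10, effect_size = 2,
                        seed = 21)
  paths <- sim_pathways(sim$module, rownames(sim$matrix), n_decoys = 4,
                        seed = 21)
  fit <- sam(sim$matrix, sim$groups, n_perm = 50, seed = 21)
  res <- spia(paths, fit$fold_change[sam_degs(fit)],
              array_genes = rownames(sim$matrix), n_boot = 300, seed = 21)
  expect_s3_class(res, "spia_result")
  expect_equal(res$pathway[1], "host")
  expect_true(all(res$p_g_fdr >= res$p_g - 1e-15))
  expect_true(all(diff(res$p_g_fdr) >= -1e-15))  # BH keeps pG order
  # determinism under the same seed
  res2 <- spia(paths, fit$fold_change[sam_degs(fit)],
               array_genes = rownames(sim$matrix), n_boot = 300,
               seed = 21)
  expect_identical(res$p_pert, res2$p_pert)
})
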