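test_that("dose-response generator round-trips through the fit", {
  vt <- sim_dose_response("a", m = 2, Dm = 25,
                          doses = 10 ^ seq(0, 3, by = 0.5),
                          noise_sd = 0, n_rep = 2, seed = 1)
  f <- fit_median_effect(vt)
  expect_equal(f$m, 2, tolerance = 1e-9)
  expect_equal(f$Dm, 25, tolerance = 1e-8)
  # viability at D = Dm is one half, noise-free
  vdm <- sim_dose_response("a", m = 2, Dm = 25, doses = 25,
                           noise_sd = 0, n_rep = 1, seed = 1)
  expect_equal(vdm$viability, 0.5)
  # same seed, same table; different seed differs
  t1 <- sim_dose_response("a", 1, 10, seed = 7)
  t2 <- sim_dose_response("a", 1, 10, seed = 7)
  expect_identical(t1$viability, t2$viability)
  expect_false(identical(
    t1$viability, sim_dose_response("a", 1, 10, seed = 8)$viability))
  expect_error(sim_dose_response("a", m = -1, Dm = 10), "positive")
})

test_that("noisy dose-response tables recover parameters on average", {
  # dose grid brackets Dm so that fa spans ~0.15-0.85, the informative
  # region of the median-effect plot where the log-odds transform is
  # well conditioned
  ests <- vapply(1:500, function(s) {
    vt <- sim_dose_response("a", m = 1.5, Dm = 50,
                            doses = 10 ^ seq(1.2, 2.2, by = 0.25),
                            noise_sd = 0.05, n_rep = 4, seed = s)
    f <- fit_median_effect(vt)
    c(f$m, f$Dm)
  }, numeric(2))
  expect_gt(mean(ests[1, ]), 1.45); expect_lt(mean(ests[1, ]), 1.55)
  expect_gt(mean(ests[2, ]), 47.5); expect_lt(mean(ests[2, ]), 52.5)
})

test_that("planted combination indices are recovered and classified", {
  singles <- list(list(m = 1, Dm = 6.3), list(m = 1.4, Dm = 46.7))
  sf <- lapply(singles, function(s) {
    fit_median_effect(sim_dose_response("x", s$m, s$Dm,
                                        doses = 10 ^ seq(-1, 3, 0.5),
                                        noise_sd = 0, seed = 1))
  })
  for (ci0 in c(0.2, 1, 2)) {
    combo <- sim_combination(singles, target_ci = ci0, noise_sd = 0,
                             seed = 2)
    cf <- fit_median_effect(combo)
    rep_ <- combination_index(cf, sf, fa = 0.5)
    expect_equal(rep_$ci, ci0, tolerance = 0.03 * max(1, ci0))
  }
  combo_syn <- sim_combination(singles, target_ci = 0.2, noise_sd = 0,
                               seed = 3)
  expect_identical(
    combination_index(fit_median_effect(combo_syn), sf, fa = 0.5)$label,
    "strong synergism")
  combo_ant <- sim_combination(singles, target_ci = 2, noise_sd = 0,
                               seed = 4)
  expect_identical(
    combination_index(fit_median_effect(combo_ant), sf, fa = 0.5)$label,
    "antagonism")
})

test_that("a planted constant CI survives noise across the curve", {
  singles <- list(list(m = 1.2, Dm = 10), list(m = 1.8, Dm = 80))
  sf <- lapply(singles, function(s) {
    fit_median_effect(sim_dose_response("x", s$m, s$Dm,
                                        doses = 10 ^ seq(-1, 3, 0.25),
                                        noise_sd = 0, seed = 1))
  })
  combo <- sim_combination(singles, target_ci = 0.5,
                           fa_grid = seq(0.05, 0.95, by = 0.05),
                           noise_sd = 0.02, n_rep = 4, seed = 5)
  curve <- fa_ci_curve(fit_median_effect(combo), sf,
                       fa_grid = seq(0.2, 0.8, by = 0.1))
  expect_true(all(abs(curve$ci - 0.5) <= 0.05))
})

test_that("expression simulator plants DEGs, module structure and truth tables", {
  sim <- sim_expression(n_genes = 150, n_per_group = 4,
                        n_deg_background = 10, effect_size = 2,
                        seed = 31)
  expect_equal(dim(sim$matrix), c(150 + 31, 8))
  expect_equal(sim$groups, rep(c("CTR", "TRT"), each = 4))
  expect_true(all(sim$deg_truth %in% rownames(sim$matrix)))
  # same seed bit-identical, background DEGs shifted upward
  sim2 <- sim_expression(n_genes = 150, n_per_group = 4,
                         n_deg_background = 10, effect_size = 2,
                         seed = 31)
  expect_identical(sim$matrix, sim2$matrix)
  bg_degs <- grep("^BG", sim$deg_truth, value = TRUE)
  shift <- rowMeans(sim$matrix[bg_degs, 5:8, drop = FALSE]) -
    rowMeans(sim$matrix[bg_degs, 1:4, drop = FALSE])
  expect_gt(mean(shift), 1)
  # perturbed edges are recorded
  sp <- sim_expression(n_genes = 50, n_per_group = 3, module_deg = "NGF",
                       perturb_edges = data.frame(source = "NGFR",
                                                  target = "RAC1"),
                       seed = 5)
  expect_equal(sp$perturbed_edges$source, "NGFR")
  expect_error(sim_expression(n_genes = 20, n_per_group = 3, seed = 1,
                              perturb_edges = data.frame(source = "xx",
                                                         target = "yy")),
               "not found")
})

test_that("null expression data yield almost no DEG calls and calibrated LRT", {
  sim <- sim_expression(n_genes = 500, n_per_group = 4,
                        n_deg_background = 0, effect_size = 0,
                        module = NULL, seed = 77)
  fit <- sam(sim$matrix, sim$groups, n_perm = 70, seed = 77)
  expect_lte(fit$n_called, 10)
  mod <- ngfr_module_topology()
  m1 <- sim_module_data(mod, 0.5, n = 30, seed = 1)
  m2 <- sim_module_data(mod, 0.5, n = 30, seed = 2)
  fit2 <- sem_multigroup(mod, m1, m2)
  expect_gt(fit2$p_value, 0.001)
})

test_that("pathway generator hosts the module and writes valid dialects", {
  sim <- sim_expression(n_genes = 200, n_per_group = 3, seed = 13)
  paths <- sim_pathways(sim$module, rownames(sim$matrix), n_decoys = 3,
                        seed = 13)
  expect_named(paths, c("host", paste0("decoy", 1:3)))
  expect_true(all(sim$module$genes %in% paths$host$genes))
  key <- function(e) paste(e$source, e$target, e$type)
  expect_true(all(key(sim$module$edges) %in% key(paths$host$edges)))
  # file round trip through the GMT + edge-list dialect
  gmt <- tempfile(fileext = ".gmt"); ed <- tempfile(fileext = ".tsv")
  write_pathways(paths, gmt, ed)
  back <- read_pathways(gmt, ed)
  expect_named(back, names(paths))
  expect_setequal(back$host$genes, paths$host$genes)
  expect_setequal(key(back$host$edges), key(paths$host$edges))
  # extract_module on the host with the true DEGs covers the module genes
  deg_in_module <- intersect(sim$deg_truth, sim$module$genes)
  mod <- extract_module(paths$host, sim$deg_truth)
  expect_true(all(deg_in_module %in% mod$genes) ||
                length(mod$genes) == 0)
})

test_that("beta generator respects support, arms and determinism", {
  sb <- sim_beta(n_probes = 200, n_per_arm = 3, seed = 17)
  expect_true(all(sb$values >= 0 & sb$values <= 1))
  expect_equal(levels(sb$groups), c("CTR", "EV", "AZA", "EV+AZA"))
  expect_equal(dim(sb$values), c(200, 12))
  sb2 <- sim_beta(n_probes = 200, n_per_arm = 3, seed = 17)
  expect_identical(sb$values, sb2$values)
  expect_error(sim_beta(base_mean = 0.9, aza_shift = 0.2), "inside")
})
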