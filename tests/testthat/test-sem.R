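simple_module <- function() {
  extract_module(pathway_graph("p", c("A", "B"),
    data.frame(source = "A", target = "B", type = "activation")),
    degs = c("A", "B"))
}

chain_module <- function() {
  extract_module(pathway_graph("p", c("A", "B", "C"),
    data.frame(source = c("A", "B"), target = c("B", "C"),
               type = "activation")), degs = c("A", "C"))
}

test_that("path coefficients recover the generating model", {
  mod <- simple_module()
  x <- sim_module_data(mod, 0.8, n = 200, seed = 1)
  # raw-scale fit recovers the raw coefficient
  raw <- fit_path_model(mod, x, standardize = FALSE)
  expect_gt(raw$coefficients$estimate, 0.7)
  expect_lt(raw$coefficients$estimate, 0.9)
  # standardised fit recovers the implied standardised coefficient
  std <- fit_path_model(mod, x, standardize = TRUE)
  truth_std <- oracle_standardized_coef(mod, 0.8)
  expect_equal(std$coefficients$estimate, truth_std, tolerance = 0.12)
  # a planted zero coefficient stays near zero
  x0 <- sim_module_data(mod, 0, n = 200, seed = 2)
  expect_lt(abs(fit_path_model(mod, x0)$coefficients$estimate), 0.15)
})

test_that("saturated single-edge fit reproduces the ML sample covariance", {
  mod <- simple_module()
  x <- sim_module_data(mod, 0.8, n = 100, seed = 3)
  fit <- fit_path_model(mod, x, standardize = FALSE)
  b <- fit$coefficients$estimate
  xc <- x - rowMeans(x)
  S <- tcrossprod(xc) / ncol(x)  # ML covariance
  # implied: Var(A) = S_AA, Cov = b Var(A), Var(B) = b^2 Var(A) + s2e
  expect_equal(b * S["A", "A"], S["A", "B"], tolerance = 1e-6)
  s2e <- S["B", "B"] - b ^ 2 * S["A", "A"]
  implied_bb <- b ^ 2 * S["A", "A"] + s2e
  expect_equal(implied_bb, S["B", "B"], tolerance = 1e-6)
})

test_that("free-model coefficient RMSE stays small on a 31-gene module", {
  mod <- ngfr_module_topology()
  pairs <- unique(mod$edges[, c("source", "target")])
  wm <- edge_type_weights()
  signs <- vapply(seq_len(nrow(pairs)), function(i) {
    ty <- mod$edges$type[mod$edges$source == pairs$source[i] &
                         mod$edges$target == pairs$target[i]][1]
    unname(wm[ty])
  }, numeric(1))
  b <- 0.6 * signs
  x <- sim_module_data(mod, b, n = 200, seed = 4)
  fit <- fit_path_model(mod, x, standardize = TRUE)
  truth <- oracle_standardized_coef(mod, b)
  rmse <- sqrt(mean((fit$coefficients$estimate - truth) ^ 2))
  expect_lte(rmse, 0.15)
})

test_that("likelihoods nest and are invariant to sample order", {
  mod <- chain_module()
  for (s in 1:10) {
    x1 <- sim_module_data(mod, c(0.5, -0.4), n = 40, seed = s)
    x2 <- sim_module_data(mod, c(0.9, 0.1), n = 40, seed = 100 + s)
    fit <- sem_multigroup(mod, x1, x2)
    expect_gte(fit$loglik_free, fit$loglik_constrained - 1e-8)
    expect_gte(fit$lrt, 0)
  }
  x1 <- sim_module_data(mod, c(0.5, -0.4), n = 40, seed = 1)
  x2 <- sim_module_data(mod, c(0.9, 0.1), n = 40, seed = 101)
  f_a <- sem_multigroup(mod, x1, x2)
  perm <- withr::with_seed(9, sample(ncol(x1)))
  f_b <- sem_multigroup(mod, x1[, perm], x2)
  expect_equal(f_a$lrt, f_b$lrt, tolerance = 1e-10)
  expect_equal(f_a$fit_control$coefficients$estimate,
               f_b$fit_control$coefficients$estimate, tolerance = 1e-12)
})

test_that("identical groups give LRT near zero and unit p-values", {
  mod <- chain_module()
  x <- sim_module_data(mod, c(0.7, 0.5), n = 60, seed = 12)
  fit <- sem_multigroup(mod, x, x)
  expect_lt(fit$lrt, 1e-6)
  expect_gt(fit$p_value, 0.999)
  ed <- edge_differences(fit)
  expect_equal(ed$estimate_diff, rep(0, nrow(ed)), tolerance = 1e-10)
  expect_true(all(ed$p_diff > 0.999))
})

test_that("estimates are invariant to rescaling both groups' data", {
  mod <- chain_module()
  x1 <- sim_module_data(mod, c(0.5, 0.8), n = 50, seed = 21)
  x2 <- sim_module_data(mod, c(0.5, 0.8), n = 50, seed = 22)
  f1 <- sem_multigroup(mod, x1, x2)
  f2 <- sem_multigroup(mod, 2 * x1, 2 * x2)
  expect_equal(edge_differences(f1)$estimate_control,
               edge_differences(f2)$estimate_control, tolerance = 1e-10)
  expect_equal(f1$lrt, f2$lrt, tolerance = 1e-8)
})

test_that("a planted sign flip is localised by the edge-difference test", {
  mod <- simple_module()
  set.seed(31)
  hits <- replicate(30, {
    seeds <- sample.int(1e6, 2)
    xc <- sim_module_data(mod, -0.9, n = 150, seed = seeds[1])
    xt <- sim_module_data(mod, 0.5, n = 150, seed = seeds[2])
    ed <- edge_differences(sem_multigroup(mod, xc, xt))
    c(diff = ed$estimate_diff, sig = ed$p_diff < 0.05)
  })
  expect_gte(mean(hits["sig", ]), 0.9)
  expect_gt(mean(hits["diff", ]), 1.0)
  expect_lt(mean(hits["diff", ]), 1.8)
})

test_that("only_significant filters the difference table", {
  mod <- chain_module()
  xc <- sim_module_data(mod, c(-0.9, 0.5), n = 150, seed = 41)
  xt <- sim_module_data(mod, c(0.5, 0.5), n = 150, seed = 42)
  fit <- sem_multigroup(mod, xc, xt)
  full <- edge_differences(fit)
  expect_named(full, c("source", "target", "type", "estimate_control",
                       "p_control", "estimate_treat", "p_treat",
                       "estimate_diff", "p_diff", "p_diff_bh"))
  only <- edge_differences(fit, only_significant = TRUE)
  expect_true(all(only$p_diff < 0.05))
  expect_true(paste("A", "B") %in% paste(only$source, only$target))
})

test_that("ridge fallback engages when parents outnumber samples", {
  g <- pathway_graph("wide", c(paste0("P", 1:6), "C"),
    data.frame(source = paste0("P", 1:6), target = "C",
               type = "activation"))
  mod <- extract_module(g, degs = c(paste0("P", 1:6), "C"))
  x <- matrix(rnorm(7 * 4), 7, 4, dimnames = list(mod$genes, NULL))
  fit <- fit_path_model(mod, x)
  expect_true(fit$ridge)
  expect_true(all(is.na(fit$coefficients$se)))
})
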