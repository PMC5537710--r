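#' Per-gene relative difference statistic
#'
#' The SAM statistic for a two-class unpaired comparison:
#' `d_i = (mean_treat - mean_ctrl) / (s_i + s0)`, where `s_i` is the
#' pooled standard error of the difference,
#' `s_i = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`.
#' The fudge factor `s0` stabilises `d` for genes with tiny variance.
#'
#' @param x numeric matrix, genes x samples, log2 scale.
#' @param groups factor/character of length `ncol(x)` with exactly two
#'   levels; the first level is the reference (control).
#' @param s0 non-negative fudge factor.
#' @return list with `d` (named per gene), `s` (pooled SE), `numer`
#'   (mean difference, treat minus control, i.e. the log2 fold change).
#' @export
sam_relative_difference <- function(x, groups, s0 = 0) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  i1 <- which(groups == levels(groups)[1L])  # control / reference
  i2 <- which(groups == levels(groups)[2L])  # treatment
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1) ^ 2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2) ^ 2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  denom <- s + s0
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero variance and s0 = 0; d set to 0")
    denom[zero] <- 1
  }
  d <- (m2 - m1) / denom
  d[zero & (m2 - m1) != 0] <- sign((m2 - m1)[zero & (m2 - m1) != 0]) * Inf
  list(d = d, s = s, numer = m2 - m1)
}

#' Estimate the SAM fudge factor s0
#'
#' Chooses `s0` among percentiles of the pooled standard errors `s_i`
#' (including 0) so that the spread of `d_i` is as uniform as possible
#' across the range of `s_i`: for each candidate, genes are binned into
#' windows by `s_i` quantile, the median absolute deviation of `d` is
#' computed per window, and the candidate minimising the coefficient of
#' variation of those MADs is selected.
#'
#' @inheritParams sam_relative_difference
#' @param probs candidate percentile grid of `s_i`.
#' @param n_windows number of `s_i`-quantile windows.
#' @return the selected `s0` (scalar, >= 0).
#' @export
sam_estimate_s0 <- function(x, groups, probs = seq(0, 1, by = 0.05),
                            n_windows = 10L) {
  base <- sam_relative_difference(x, groups, s0 = 0)
  s <- base$s
  if (length(s) < 100L)
    warning("fewer than 100 genes; s0 estimate may be unstable")
  if (stats::sd(s) == 0) {
    warning("constant s_i across genes; s0 = 0")
    return(0)
  }
  cand <- unique(c(0, unname(stats::quantile(s, probs))))
  # quantile windows over s
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_windows + 1L)))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- base$numer / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads)]
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  cand[which.min(cv)]
}

#' Permutation null for the SAM statistic
#'
#' Recomputes the relative difference under permuted group labels and
#' returns, per permutation, the sorted `d` vector together with the
#' expected order statistics `dbar_(i)` (the mean across permutations of
#' the i-th smallest `d`). When the number of distinct label assignments
#' `choose(n, n1)` does not exceed `n_perm`, all assignments are
#' enumerated exactly once (the identity assignment included); otherwise
#' `n_perm` assignments are sampled with the given seed.
#'
#' @inheritParams sam_relative_difference
#' @param n_perm requested number of permutations.
#' @param seed integer seed controlling sampled permutations.
#' @return list with `d_sorted` (n_genes x n_perm matrix of sorted null
#'   d), `dbar` (expected order statistics), `exhaustive` flag, and
#'   `n_perm` actually used.
#' @export
sam_permutation_null <- function(x, groups, n_perm = 200L, seed = 1L,
                                 s0 = 0) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  n <- ncol(x)
  n1 <- sum(groups == levels(groups)[1L])
  n_total <- choose(n, n1)
  exhaustive <- n_total <= n_perm
  if (exhaustive) {
    idx <- utils::combn(n, n1, simplify = FALSE)
  } else {
    idx <- withr::with_seed(seed, {
      replicate(n_perm, sort(sample.int(n, n1)), simplify = FALSE)
    })
  }
  lv <- levels(groups)
  d_sorted <- vapply(idx, function(i1) {
    g <- factor(ifelse(seq_len(n) %in% i1, lv[1L], lv[2L]), levels = lv)
    sort(sam_relative_difference(x, g, s0 = s0)$d)
  }, numeric(nrow(x)))
  list(d_sorted = d_sorted, dbar = rowMeans(d_sorted),
       exhaustive = exhaustive, n_perm = length(idx))
}

# Asymmetric SAM cutpoints: scan the quantile-quantile plot of observed
# vs expected order statistics; past the first crossing of the delta band
# every more extreme gene is called.
sam_cutpoints <- function(d_sorted_obs, dbar, delta) {
  if (delta == 0)  # zero band: every gene is past the crossing
    return(list(cut_up = -Inf, cut_lo = -Inf))
  diffs <- d_sorted_obs - dbar
  # scan each side outward from the centre of the null qq-line
  i_up <- which(diffs >= delta & dbar >= 0)
  i_lo <- which(diffs <= -delta & dbar <= 0)
  list(
    cut_up = if (length(i_up)) d_sorted_obs[min(i_up)] else Inf,
    cut_lo = if (length(i_lo)) d_sorted_obs[max(i_lo)] else -Inf
  )
}

# pi0: proportion of truly null genes, estimated from the fraction of
# observed d falling inside the null interquartile band.
sam_pi0 <- function(d, null) {
  q <- stats::quantile(as.vector(null$d_sorted), c(0.25, 0.75))
  min(1, 2 * mean(d >= q[1] & d <= q[2]))
}

#' Call differentially expressed genes at a given delta
#'
#' Standard asymmetric SAM calling: genes whose sorted statistic departs
#' from the permutation-expected order statistic by at least `delta` set
#' the upper/lower cutpoints; every gene beyond a cutpoint is called. The
#' FDR estimate is `pi0 * median_perm(#null beyond cuts) / #called`.
#'
#' @param d named per-gene statistic vector (from
#'   [sam_relative_difference()]).
#' @param null permutation null from [sam_permutation_null()].
#' @param delta non-negative calling threshold.
#' @param fold_change optional named per-gene log2 fold change carried
#'   into the result.
#' @return object of class `sam_result`: list with `called` (logical per
#'   gene), `sign`, `fdr`, `delta`, `cut_up`, `cut_lo`, `n_called`, `pi0`.
#' @export
sam_call_degs <- function(d, null, delta, fold_change = NULL) {
  if (delta < 0) stop("delta must be >= 0")
  ord <- order(d)
  cuts <- sam_cutpoints(d[ord], null$dbar, delta)
  called <- d >= cuts$cut_up | d <= cuts$cut_lo
  n_called <- sum(called)
  null_counts <- colSums(null$d_sorted >= cuts$cut_up |
                         null$d_sorted <= cuts$cut_lo)
  pi0 <- sam_pi0(d, null)
  fdr <- if (n_called == 0) 0 else
    min(1, pi0 * stats::median(null_counts) / n_called)
  out <- list(called = called, sign = sign(d),
              d = d, fold_change = fold_change,
              fdr = fdr, delta = delta, pi0 = pi0,
              cut_up = cuts$cut_up, cut_lo = cuts$cut_lo,
              n_called = n_called, no_calls = n_called == 0)
  class(out) <- "sam_result"
  out
}

#' Choose the smallest delta reaching a target FDR
#'
#' Evaluates the FDR estimate on a grid of 200 delta values between 0 and
#' the largest observed departure from the expected order statistics, and
#' returns the smallest delta whose (monotonised, non-increasing) FDR
#' estimate is at or below the target.
#'
#' @inheritParams sam_call_degs
#' @param target_fdr target false discovery rate in (0, 1].
#' @param grid_size number of grid values.
#' @return list with `delta`, the grid, and the (monotone) FDR estimates.
#' @export
sam_choose_delta <- function(d, null, target_fdr = 0.05,
                             grid_size = 200L) {
  if (target_fdr <= 0 || target_fdr > 1)
    stop("target_fdr must be in (0, 1]")
  dmax <- max(abs(sort(d) - null$dbar))
  grid <- seq(0, dmax, length.out = grid_size)
  fdr <- vapply(grid, function(delta)
    sam_call_degs(d, null, delta)$fdr, numeric(1))
  # enforce non-increasing FDR in delta before thresholding (suffix max:
  # a delta qualifies only if every larger delta also meets the target)
  fdr_mono <- rev(cummax(rev(fdr)))
  ok <- which(fdr_mono <= target_fdr)
  if (length(ok) == 0L) {
    warning("no delta reaches target FDR; returning largest grid value")
    delta <- grid[grid_size]
  } else {
    delta <- grid[min(ok)]
  }
  list(delta = delta, grid = grid, fdr = fdr_mono)
}

#' SAM analysis of a two-class expression matrix
#'
#' Full significance-analysis-of-microarrays run: fudge factor
#' estimation, permutation null, delta selection for a target FDR (or a
#' fixed delta), and DEG calling.
#'
#' @inheritParams sam_relative_difference
#' @param target_fdr target FDR used to select delta when `delta` is
#'   `NULL`.
#' @param delta optional fixed calling threshold.
#' @param n_perm number of permutations (exhaustive enumeration is used
#'   when it needs fewer).
#' @param seed integer seed.
#' @param s0 optional fixed fudge factor; estimated when `NULL`.
#' @return `sam_fit` object: the `sam_result` augmented with `s0`,
#'   `n_perm`, `seed`, `genes`, `fold_change`.
#' @examples
#' sim <- sim_expression(n_genes = 60, n_deg = 10, n_per_group = 4,
#'                       effect_size = 3, seed = 7)
#' fit <- sam(sim$matrix, sim$groups, n_perm = 50, seed = 7)
#' print(fit)
#' @export
sam <- function(x, groups, target_fdr = 0.05, delta = NULL,
                n_perm = 200L, seed = 1L, s0 = NULL) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x))) stop("gene ids must be unique")
  if (anyNA(x)) stop("missing values in expression matrix")
  if (is.null(s0)) s0 <- sam_estimate_s0(x, groups)
  obs <- sam_relative_difference(x, groups, s0 = s0)
  null <- sam_permutation_null(x, groups, n_perm = n_perm, seed = seed,
                               s0 = s0)
  if (is.null(delta)) {
    sel <- sam_choose_delta(obs$d, null, target_fdr = target_fdr)
    delta <- sel$delta
  }
  res <- sam_call_degs(obs$d, null, delta, fold_change = obs$numer)
  res$s0 <- s0
  res$n_perm <- null$n_perm
  res$exhaustive <- null$exhaustive
  res$seed <- seed
  res$genes <- rownames(x)
  class(res) <- c("sam_fit", "sam_result")
  res
}

#' @export
print.sam_fit <- function(x, ...) {
  cat("SAM two-class analysis\n")
  cat(sprintf("  s0 = %.4g, delta = %.4g, permutations = %d%s\n",
              x$s0, x$delta, x$n_perm,
              if (isTRUE(x$exhaustive)) " (exhaustive)" else ""))
  cat(sprintf("  %d genes called (estimated FDR %.4f, pi0 %.3f)\n",
              x$n_called, x$fdr, x$pi0))
  invisible(x)
}

#' Genes called by a SAM fit
#'
#' @param fit a `sam_fit`.
#' @return character vector of called gene ids.
#' @export
sam_degs <- function(fit) {
  stopifnot(inherits(fit, "sam_result"))
  names(which(fit$called))
}

#' Per-gene SAM table
#'
#' @param fit a `sam_fit`.
#' @return data frame with gene, d, fold change (log2), called flag, sign.
#' @export
sam_table <- function(fit) {
  data.frame(gene = names(fit$d), d = unname(fit$d),
             fold_change = if (is.null(fit$fold_change)) NA_real_
                           else unname(fit$fold_change),
             called = unname(fit$called), sign = unname(fit$sign),
             stringsAsFactors = FALSE)
}
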