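#' Build a viability table for median-effect analysis
#'
#' Packages dose-response measurements (relative viability after MTT-style
#' normalisation to the untreated control) for a single agent or a
#' fixed-ratio two-drug mixture. The fraction affected is
#' `fa = 1 - viability`; viabilities are clipped to the open unit interval
#' before the median-effect transform so that `log10(fa/fu)` stays finite.
#'
#' @param drug label of the agent or mixture.
#' @param dose numeric vector of total doses in nM, strictly positive.
#' @param viability numeric vector (same length as `dose`) or matrix with
#'   one row per dose and one column per replicate, values in `[0, 1]`.
#' @param ratio length-2 non-negative weights summing to 1; the share of
#'   the total dose contributed by each drug. A single agent is `c(1, 0)`.
#' @param clip half-width of the exclusion zone at 0 and 1 used when
#'   clipping viabilities.
#' @return An object of class `viability_table`: a data frame with columns
#'   `dose`, `viability`, `fa` (replicates unrolled into rows) and
#'   attributes `drug` and `ratio`.
#' @examples
#' vt <- viability_table("EV", c(1, 3, 10, 30, 100),
#'                       1 / (1 + (c(1, 3, 10, 30, 100) / 10)))
#' fit_median_effect(vt)
#' @export
viability_table <- function(drug, dose, viability, ratio = c(1, 0),
                            clip = 1e-4) {
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("doses must be finite and strictly positive")
  viability <- as.matrix(viability)
  if (nrow(viability) == 1L && ncol(viability) == length(dose))
    viability <- t(viability)
  if (nrow(viability) != length(dose))
    stop("viability must have one row (or element) per dose")
  if (any(!is.finite(viability)))
    stop("viability values must be finite")
  ratio <- as.numeric(ratio)
  if (length(ratio) != 2L || any(ratio < 0) ||
      abs(sum(ratio) - 1) > 1e-8)
    stop("ratio must be two non-negative weights summing to 1")
  v <- pmin(pmax(as.vector(viability), clip), 1 - clip)
  out <- data.frame(
    dose = rep(dose, times = ncol(viability)),
    viability = v,
    fa = 1 - v
  )
  attr(out, "drug") <- as.character(drug)
  attr(out, "ratio") <- ratio
  class(out) <- c("viability_table", "data.frame")
  out
}

#' Read a viability CSV
#'
#' Expects columns `drug`, `dose_nM`, then one or more replicate columns
#' (`viability_rep1`, ...). Combination files may carry `ratio_a`,
#' `ratio_b` columns (constant within the file).
#'
#' @param path CSV file path.
#' @return a `viability_table`.
#' @export
read_viability <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE)
  need <- c("drug", "dose_nM")
  if (!all(need %in% names(x)))
    stop("missing required columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  reps <- grep("^viability", names(x), value = TRUE)
  if (length(reps) == 0L) stop("no viability_rep* columns found")
  ratio <- if (all(c("ratio_a", "ratio_b") %in% names(x)))
    c(x$ratio_a[1], x$ratio_b[1]) else c(1, 0)
  viability_table(x$drug[1], x$dose_nM,
                  as.matrix(x[, reps, drop = FALSE]), ratio = ratio)
}

#' Fit the median-effect model
#'
#' Ordinary least squares on the median-effect plot: for each measurement,
#' `log10(fa / fu)` is regressed on `log10(D)`. The slope is the
#' sigmoidicity `m` and the median-effect dose satisfies
#' `log10(Dm) = -intercept / m`, so that half the cells are affected at
#' `D = Dm`. The linear correlation `r` of the plot is reported as a
#' fit-quality flag; a warning is raised when `r^2 < 0.9`, mirroring the
#' conventional quality screen for this analysis.
#'
#' @param table a [viability_table()].
#' @return An object of class `medfx` with components `m`, `Dm`, `r`,
#'   `n_points`, `drug`, `ratio`.
#' @export
fit_median_effect <- function(table) {
  stopifnot(inherits(table, "viability_table"))
  fa <- table$fa
  usable <- fa > 0 & fa < 1
  if (length(unique(table$dose[usable])) < 3L)
    stop("median-effect fit needs >= 3 distinct usable dose levels")
  if (stats::sd(fa[usable]) == 0)
    stop("all fa values identical; median-effect plot has zero variance")
  x <- log10(table$dose[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0)
    warning("non-positive median-effect slope; dose-response is not monotone")
  b <- unname(stats::coef(fit)[1])
  out <- list(
    m = m,
    Dm = 10 ^ (-b / m),
    r = stats::cor(x, y),
    n_points = sum(usable),
    drug = attr(table, "drug"),
    ratio = attr(table, "ratio")
  )
  class(out) <- "medfx"
  if (is.finite(out$r) && out$r ^ 2 < 0.9)
    warning(sprintf("median-effect plot r^2 = %.3f < 0.9 for '%s'",
                    out$r ^ 2, out$drug))
  out
}

#' @export
print.medfx <- function(x, ...) {
  cat("Median-effect fit:", x$drug, "\n")
  cat(sprintf("  m  = %.4f (slope)\n  Dm = %.4g nM (ED50)\n  r  = %.4f (%d points)\n",
              x$m, x$Dm, x$r, x$n_points))
  invisible(x)
}

#' @export
coef.medfx <- function(object, ...) c(m = object$m, Dm = object$Dm)

#' Dose required for a given effect level
#'
#' Inverts the median-effect equation `fa/fu = (D/Dm)^m`:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`. `dose_for_effect(fit, 0.5)` equals
#' the fitted `Dm` (the ED50/IC50).
#'
#' @param fit a `medfx` object.
#' @param fa effect level(s), fraction affected, in (0, 1).
#' @return dose(s) in nM.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "medfx"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)")
  fit$Dm * (fa / (1 - fa)) ^ (1 / fit$m)
}

#' Predicted fraction affected at given doses
#'
#' Forward evaluation of the fitted median-effect model,
#' `fa = 1 / (1 + (Dm/D)^m)`.
#'
#' @param object a `medfx` object.
#' @param dose doses in nM.
#' @param ... unused.
#' @export
predict.medfx <- function(object, dose, ...) {
  if (any(dose <= 0)) stop("doses must be positive")
  1 / (1 + (object$Dm / dose) ^ object$m)
}
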