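#' Classify a combination index value
#'
#' Maps a combination index (CI) to the conventional interpretation bands:
#' CI below 1 indicates synergy, 1 additivity, and above 1 antagonism,
#' with a strong-synergism band at very low CI.
#'
#' @param ci positive combination index value(s).
#' @return character vector of labels among `"strong synergism"`,
#'   `"synergism"`, `"additivity"`, `"antagonism"`.
#' @examples
#' classify_ci(c(0.1, 0.7, 1.0, 2.3))
#' @export
classify_ci <- function(ci) {
  if (any(ci <= 0)) stop("CI must be positive")
  cut(ci,
      breaks = c(0, 0.3, 0.9, 1.1, Inf),
      labels = c("strong synergism", "synergism", "additivity",
                 "antagonism"),
      right = TRUE) |> as.character()
}

#' Combination index, dose reduction index and potentiation factor
#'
#' Two-term (mutually exclusive) Chou-Talalay combination index at effect
#' level `fa`:
#' \deqn{CI = \sum_i (D)_i / (Dx)_i}
#' where `(D)_i = ratio_i * Dtot` is drug i's share of the total
#' combination dose producing effect `fa` (from the fixed-ratio
#' combination fit) and `(Dx)_i` is the dose of drug i alone producing the
#' same effect. The dose reduction index is `DRI_i = (Dx)_i / (D)_i`, so
#' `CI = sum(1 / DRI)` holds as an algebraic identity. The potentiation
#' factor is the ratio of the single-agent ED50 to that drug's dose within
#' the combination at ED50.
#'
#' @param combo_fit `medfx` fit of the fixed-ratio combination (total-dose
#'   axis).
#' @param single_fits list of two `medfx` fits, one per drug, in the same
#'   order as `ratio`.
#' @param ratio length-2 dose-share weights of the combination (taken from
#'   `combo_fit$ratio` when `NULL`).
#' @param fa effect level in (0, 1) at which to evaluate the index.
#' @return An object of class `synergy_report`: a one-row data frame with
#'   `fa`, `ci`, `dri_1`, `dri_2`, `pf_1`, `pf_2`, `label`. A zero ratio
#'   weight leaves that drug's DRI/PF as `NA` (logged via message).
#' @export
combination_index <- function(combo_fit, single_fits, ratio = NULL,
                              fa = 0.5) {
  stopifnot(inherits(combo_fit, "medfx"), length(single_fits) == 2L)
  if (is.null(ratio)) ratio <- combo_fit$ratio
  if (length(fa) != 1L || fa <= 0 || fa >= 1)
    stop("fa must be a single value in (0, 1)")
  d_tot <- dose_for_effect(combo_fit, fa)
  d_in_combo <- ratio * d_tot
  dx <- vapply(single_fits, dose_for_effect, numeric(1), fa = fa)
  dri <- ifelse(ratio > 0, dx / d_in_combo, NA_real_)
  if (any(ratio == 0))
    message("zero ratio weight: DRI/PF undefined for drug ",
            which(ratio == 0))
  ci <- sum(d_in_combo[ratio > 0] / dx[ratio > 0])
  ed50_single <- vapply(single_fits, function(f) f$Dm, numeric(1))
  pf <- ifelse(ratio > 0, ed50_single / (ratio * combo_fit$Dm), NA_real_)
  out <- data.frame(fa = fa, ci = ci,
                    dri_1 = dri[1], dri_2 = dri[2],
                    pf_1 = pf[1], pf_2 = pf[2],
                    label = classify_ci(ci),
                    stringsAsFactors = FALSE)
  class(out) <- c("synergy_report", "data.frame")
  out
}

#' Fa-CI curve
#'
#' Evaluates [combination_index()] on a grid of effect levels, the data
#' behind a CI versus fraction-affected plot.
#'
#' @inheritParams combination_index
#' @param fa_grid effect levels, all in (0, 1).
#' @return `synergy_report` data frame with one row per grid point,
#'   ordered as given.
#' @export
fa_ci_curve <- function(combo_fit, single_fits, ratio = NULL,
                        fa_grid = seq(0.05, 0.95, by = 0.05)) {
  if (any(fa_grid <= 0 | fa_grid >= 1)) stop("fa_grid must lie in (0, 1)")
  rows <- lapply(fa_grid, function(f)
    combination_index(combo_fit, single_fits, ratio, fa = f))
  out <- do.call(rbind, rows)
  class(out) <- c("synergy_report", "data.frame")
  out
}

#' @export
print.synergy_report <- function(x, digits = 3, ...) {
  cat("Synergy report (", nrow(x), " effect level",
      if (nrow(x) > 1) "s", "):\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Plot a Fa-CI curve
#'
#' @param x a `synergy_report` with multiple effect levels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.synergy_report <- function(x, ...) {
  graphics::plot(x$fa, x$ci, type = "b", xlab = "fraction affected (fa)",
                 ylab = "combination index (CI)", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write a synergy report as TSV
#'
#' @param x `synergy_report`.
#' @param path output file.
#' @export
write_synergy_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
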