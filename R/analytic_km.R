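#' Closed-form epistasis factor for K_M in the simple mechanism
#'
#' When mutation i scales k_minus1 by alpha_i, k2 by beta_i and k1 by
#' gamma_i, the K_M epistasis factor of the additive double mutant is
#'
#' eps = (alpha1 alpha2 k_minus1 + beta1 beta2 k2) (k_minus1 + k2) /
#'       ((alpha1 k_minus1 + beta1 k2) (alpha2 k_minus1 + beta2 k2))
#'
#' The gamma (k1) folds cancel, so only the effects on k_minus1 and k2
#' matter. eps = 1 exactly when (alpha1 - beta1)(alpha2 - beta2) = 0, i.e.
#' whenever either mutation affects k_minus1 and k2 identically.
#'
#' @param alpha1,beta1 Fold effects of mutation 1 on k_minus1 and k2.
#' @param alpha2,beta2 Fold effects of mutation 2.
#' @param k_minus1,k2 Wild-type rate constants (1/s).
#' @return The epistasis factor (vectorised).
#' @export
km_epsilon <- function(alpha1, beta1, alpha2, beta2, k_minus1, k2) {
  .check_positive(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                  beta2 = beta2, k_minus1 = k_minus1, k2 = k2)
  (alpha1 * alpha2 * k_minus1 + beta1 * beta2 * k2) * (k_minus1 + k2) /
    ((alpha1 * k_minus1 + beta1 * k2) * (alpha2 * k_minus1 + beta2 * k2))
}

#' Sign of K_M epistasis from fold effects alone
#'
#' For any positive k_minus1 and k2, the sign of eps - 1 equals the sign
#' of (alpha1 - beta1)(alpha2 - beta2): positive epistasis requires both
#' mutations to shift their k_minus1 effect relative to their k2 effect
#' in the same direction.
#'
#' @param alpha1,beta1,alpha2,beta2 Positive fold effects (vectorised).
#' @return -1, 0 or +1.
#' @export
epsilon_sign <- function(alpha1, beta1, alpha2, beta2) {
  .check_positive(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                  beta2 = beta2)
  sign((alpha1 - beta1) * (alpha2 - beta2))
}

#' Default logarithmic fold grid
#'
#' @param n Number of points per axis (default 41).
#' @param range Two positive folds (default 0.01 to 100).
#' @return Log-spaced vector of folds.
#' @export
default_ratio_grid <- function(n = 41L, range = c(0.01, 100)) {
  .check_positive(range = range)
  10^seq(log10(range[1L]), log10(range[2L]), length.out = n)
}

#' Scan the K_M epistasis surface over fold-effect ratios
#'
#' Evaluates [km_epsilon()] on the Cartesian grid of per-mutation
#' alpha/beta ratios. By default beta1 = beta2 = `beta` is held fixed and
#' alpha_i = ratio_i * beta is varied, so each grid point corresponds to a
#' single epsilon value; pass a vector `beta` to scan beta too (the grid
#' is then the cross of ratios and betas for each mutation).
#'
#' @param ratios Positive fold ratios alpha_i/beta_i for both axes.
#' @param k_minus1,k2 Wild-type rate constants (defaults: the simple
#'   wild-type values 62.1 and 11.5 1/s).
#' @param beta Fixed (or scanned) beta fold(s), default 1.
#' @return A `data.table` with columns `ratio1`, `ratio2`, `alpha1`,
#'   `beta1`, `alpha2`, `beta2`, `k_minus1`, `k2`, `epsilon`.
#' @export
grid_scan <- function(ratios = default_ratio_grid(), k_minus1 = 62.1,
                      k2 = 11.5, beta = 1) {
  if (!length(ratios)) stop("`ratios` must be non-empty", call. = FALSE)
  .check_positive(ratios = ratios, k_minus1 = k_minus1, k2 = k2, beta = beta)
  g <- data.table::CJ(ratio1 = ratios, beta1 = beta,
                      ratio2 = ratios, beta2 = beta)
  g[, `:=`(alpha1 = ratio1 * beta1, alpha2 = ratio2 * beta2,
           k_minus1 = k_minus1, k2 = k2)]
  g[, epsilon := km_epsilon(alpha1, beta1, alpha2, beta2, k_minus1, k2)]
  data.table::setcolorder(g, c("ratio1", "ratio2", "alpha1", "beta1",
                               "alpha2", "beta2", "k_minus1", "k2",
                               "epsilon"))
  g[]
}

#' K_M epistasis surfaces across wild-type k_minus1 values
#'
#' Re-runs [grid_scan()] with k_minus1 set to each multiple of the base
#' k2, probing how the strength and placement of positive epistasis
#' responds to the k_minus1/k2 balance of the wild-type enzyme. The
#' maximum epsilon over the bounded grid grows as k_minus1 departs from
#' k2 in either direction.
#'
#' @param multipliers Positive multiples of `base_k2` to use as k_minus1.
#' @param base_k2 Wild-type k2 (default 11.5 1/s).
#' @param ratios Fold-ratio grid for each scan.
#' @param beta Fixed beta fold(s), as in [grid_scan()].
#' @return An object of class `kminus1_sweep`: `$summary` `data.table`
#'   (`multiplier`, `k_minus1`, `max_epsilon`, `min_epsilon`) and
#'   `$grids`, the per-multiplier scan tables.
#' @export
kminus1_sweep <- function(multipliers, base_k2 = 11.5,
                          ratios = default_ratio_grid(), beta = 1) {
  .check_positive(multipliers = multipliers, base_k2 = base_k2)
  grids <- lapply(multipliers, function(m) {
    grid_scan(ratios, k_minus1 = m * base_k2, k2 = base_k2, beta = beta)
  })
  summary <- data.table::data.table(
    multiplier = multipliers,
    k_minus1 = multipliers * base_k2,
    max_epsilon = vapply(grids, function(g) max(g$epsilon), numeric(1L)),
    min_epsilon = vapply(grids, function(g) min(g$epsilon), numeric(1L)))
  structure(list(summary = summary, grids = grids, base_k2 = base_k2),
            class = "kminus1_sweep")
}

#' @export
print.kminus1_sweep <- function(x, ...) {
  cat("<kminus1_sweep> k2 = ", x$base_k2, " 1/s\n", sep = "")
  print(x$summary)
  invisible(x)
}
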