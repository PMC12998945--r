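#' Assemble an experimental double-mutant cycle
#'
#' Bundles microscopic rate constants for the wild type, both single
#' mutants and the double mutant, plus optional measured kinetic
#' parameters and flags for rate constants reported only as bounds
#' ("greater than" thresholds). This is the input of the specific /
#' non-specific epistasis correction workflow, which requires every
#' microscopic rate constant entering k_cat and K_M for all four
#' variants.
#'
#' @param wt,mutA,mutB,double `rate_constants` objects (or named
#'   lists/vectors coercible by [rate_constants()]), all of the same
#'   mechanism kind. For acyl-enzyme style mechanisms where no reverse
#'   chemical rate is reported, omit `k_minus2` (treated as zero).
#' @param measured Optional named list (names among `wt`, `mutA`, `mutB`,
#'   `double`) of named vectors with any of `k_cat` (1/s), `K_M` (molar),
#'   `efficiency` (1/(M s)); used only for fold-error screening, never in
#'   any epistasis factor.
#' @param bound_flags Optional named list (same names) of character
#'   vectors naming rate constants reported as bounds rather than point
#'   estimates; they are used at face value with a recorded warning.
#' @return An object of class `experimental_variant_set`.
#' @export
experimental_variant_set <- function(wt, mutA, mutB, double,
                                     measured = NULL, bound_flags = NULL) {
  variants <- list(wt = wt, mutA = mutA, mutB = mutB, double = double)
  variants <- lapply(variants, function(v) {
    if (inherits(v, "rate_constants")) v else rate_constants(v)
  })
  mechs <- vapply(variants, function(v) v$mechanism, character(1L))
  if (length(unique(mechs)) != 1L) {
    stop("all variants must use the same mechanism kind", call. = FALSE)
  }
  if (!is.null(measured)) {
    bad <- setdiff(names(measured), names(variants))
    if (length(bad)) {
      stop("unknown variant(s) in `measured`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(bound_flags)) {
    for (v in names(bound_flags)) {
      bad <- setdiff(bound_flags[[v]], names(variants[[v]]$k))
      if (length(bad)) {
        stop("bound flag names unknown rate constant(s) for ", v, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(
    list(variants = variants, mechanism = mechs[[1L]],
         measured = measured, bound_flags = bound_flags),
    class = "experimental_variant_set"
  )
}

#' Symmetric fold error between measured and computed values
#'
#' max(measured/computed, computed/measured), always >= 1. Values above
#' 1.5 indicate that computing a kinetic parameter from microscopic rate
#' constants already deviates substantially from the direct measurement
#' (the 1.5-fold screen).
#'
#' @param measured,computed Positive values (vectorised).
#' @return Fold errors >= 1.
#' @export
fold_error <- function(measured, computed) {
  .check_positive(measured = measured, computed = computed)
  pmax(measured / computed, computed / measured)
}

#' Null-model (multiplicative) double-mutant rate constants
#'
#' Per rate constant, k_expected = k_wt * (k_A/k_wt) * (k_B/k_wt). Under
#' strictly additive free-energy effects the observed double equals this
#' expectation exactly; any deviation is specific epistasis.
#'
#' @param wt,mutA,mutB `rate_constants` of the same mechanism kind.
#' @return A `rate_constants` object of expected double-mutant rates.
#' @export
expected_double_rates <- function(wt, mutA, mutB) {
  stopifnot(inherits(wt, "rate_constants"), inherits(mutA, "rate_constants"),
            inherits(mutB, "rate_constants"))
  if (wt$mechanism != mutA$mechanism || wt$mechanism != mutB$mechanism) {
    stop("mechanism kinds do not match", call. = FALSE)
  }
  k <- wt$k * (mutA$k / wt$k) * (mutB$k / wt$k)
  # 0 * (0/0) from an all-zero k_minus2 column is NaN; keep it zero.
  k[wt$k == 0 & mutA$k == 0 & mutB$k == 0] <- 0
  rate_constants(k, wt$mechanism)
}

#' Specific epistasis per microscopic rate constant
#'
#' Observed over expected (multiplicative-null) double-mutant rate
#' constants. A fold of 1 means the rate combined additively on the free
#' energy scale; deviations are specific epistasis, attributable to a
#' physical interaction between the mutations.
#'
#' @param observed,expected `rate_constants` of the same mechanism kind.
#' @return Named numeric vector of folds, one per rate constant (NA where
#'   both rates are zero).
#' @export
specific_epistasis <- function(observed, expected) {
  stopifnot(inherits(observed, "rate_constants"),
            inherits(expected, "rate_constants"))
  if (observed$mechanism != expected$mechanism) {
    stop("mechanism kinds do not match", call. = FALSE)
  }
  folds <- observed$k / expected$k
  folds[observed$k == 0 & expected$k == 0] <- NA_real_
  folds
}

#' Separate specific from non-specific epistasis in a double-mutant cycle
#'
#' Computes kinetic parameters from the microscopic rate constants of all
#' four variants (measured kinetic parameters, when supplied, are used
#' only to report fold errors). Three double-mutant predictions are then
#' compared per kinetic parameter:
#' \describe{
#'   \item{null}{wild type times both singles' computed fold-changes —
#'     the standard multiplicative null.}
#'   \item{corrected null}{parameters recomputed from multiplicatively
#'     combined microscopic rate constants ([expected_double_rates()]) —
#'     what the double would show with zero specific epistasis. Its ratio
#'     to the null is the non-specific epistasis inherent in the kinetic
#'     ensemble.}
#'   \item{observed}{parameters from the double's measured rate
#'     constants.}
#' }
#' The apparent specific epistasis (observed/null) factorises exactly
#' into non-specific (corrected-null/null) times corrected specific
#' (observed/corrected-null), so correcting for the ensemble's intrinsic
#' non-linearity can strengthen or flip the inferred interaction.
#'
#' @param data An `experimental_variant_set`.
#' @return An object of class `correction_report`: per-variant computed
#'   `$parameters`, `$expected_rates`, `$specific_epistasis` per rate
#'   constant, and per kinetic parameter `$null`, `$corrected_null`,
#'   `$nonspecific_epsilon`, `$apparent_epsilon`,
#'   `$corrected_epsilon`; `$fold_errors` where measurements were
#'   supplied; `$warnings` for bound-flagged rates.
#' @export
correction_report <- function(data) {
  stopifnot(inherits(data, "experimental_variant_set"))
  v <- data$variants
  plain <- function(x) {
    x <- unclass(x)
    attr(x, "mechanism") <- NULL
    x
  }
  pars <- lapply(v, function(vi) plain(kinetic_parameters(vi)))
  pw <- pars$wt

  null <- pw * (pars$mutA / pw) * (pars$mutB / pw)
  exp_rates <- expected_double_rates(v$wt, v$mutA, v$mutB)
  corrected_null <- plain(kinetic_parameters(exp_rates))
  observed <- pars$double

  spec <- specific_epistasis(v$double, exp_rates)
  nonspecific <- corrected_null / null
  apparent <- observed / null
  corrected <- observed / corrected_null

  fold_errors <- NULL
  if (!is.null(data$measured)) {
    fold_errors <- lapply(names(data$measured), function(nm) {
      m <- data$measured[[nm]]
      common <- intersect(names(m), .PARAM_NAMES)
      fe <- fold_error(as.numeric(m[common]), pars[[nm]][common])
      names(fe) <- common
      list(fold_error = fe, flagged = names(fe)[fe > 1.5])
    })
    names(fold_errors) <- names(data$measured)
  }

  warnings <- character()
  if (!is.null(data$bound_flags)) {
    for (nm in names(data$bound_flags)) {
      if (length(data$bound_flags[[nm]])) {
        warnings <- c(warnings, paste0(
          nm, ": ", paste(data$bound_flags[[nm]], collapse = ", "),
          " reported as a bound; used at face value"))
      }
    }
  }

  structure(
    list(mechanism = data$mechanism,
         parameters = pars,
         expected_rates = exp_rates,
         specific_epistasis = spec,
         null = null, corrected_null = corrected_null, observed = observed,
         nonspecific_epsilon = nonspecific,
         apparent_epsilon = apparent,
         corrected_epsilon = corrected,
         fold_errors = fold_errors,
         warnings = warnings),
    class = "correction_report"
  )
}

#' @export
print.correction_report <- function(x, ...) {
  cat("<correction_report> ", x$mechanism, " mechanism\n", sep = "")
  cat("specific epistasis per rate constant (observed/expected):\n")
  print(signif(x$specific_epistasis, 3))
  tab <- rbind(null = x$null, corrected_null = x$corrected_null,
               observed = x$observed,
               nonspecific_eps = x$nonspecific_epsilon,
               apparent_eps = x$apparent_epsilon,
               corrected_eps = x$corrected_epsilon)
  print(signif(tab, 3))
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  - ", w, "\n", sep = "")
  }
  invisible(x)
}
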