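#' Multiplicative null prediction for a double mutant
#'
#' The null model assumes strictly additive free-energy effects, i.e.
#' multiplicative parameter fold-changes: the predicted double-mutant
#' parameter is p_wt * (p1/p_wt) * (p2/p_wt).
#'
#' @param p_wt,p1,p2 Wild-type and single-mutant parameter values
#'   (positive; vectorised).
#' @return Predicted double-mutant parameter.
#' @export
null_predicted <- function(p_wt, p1, p2) {
  .check_positive(p_wt = p_wt, p1 = p1, p2 = p2)
  p_wt * (p1 / p_wt) * (p2 / p_wt)
}

#' Epistasis factor
#'
#' epsilon = observed / predicted, the ratio of the observed double-mutant
#' parameter (or fold-change) to the multiplicative null prediction.
#' epsilon > 1 is positive epistasis, epsilon < 1 negative.
#'
#' @param observed,predicted Positive parameter values (vectorised).
#' @return The epistasis factor epsilon.
#' @export
epsilon <- function(observed, predicted) {
  .check_positive(observed = observed, predicted = predicted)
  observed / predicted
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      stop("`", nm, "` must be positive and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Core vectorised classifier on log scales. lf1, lf2: single log
# fold-changes vs wt; lobs: observed double log fold-change vs wt.
# Significance: |log eps| >= log(threshold). A mutation "flips" when its
# effect exceeds the same fold threshold in magnitude in BOTH backgrounds
# with opposite signs; sub-threshold effects count as neutral, so they can
# never flip. 0 flips -> magnitude, 1 -> sign, 2 -> reciprocal_sign.
.classify_log <- function(lf1, lf2, lobs, threshold) {
  lt <- log(threshold)
  leps <- lobs - lf1 - lf2
  sig <- abs(leps) >= lt
  b1 <- lobs - lf2 # effect of mutation 1 in the mutation-2 background
  b2 <- lobs - lf1
  flip1 <- (lf1 >= lt & b1 <= -lt) | (lf1 <= -lt & b1 >= lt)
  flip2 <- (lf2 >= lt & b2 <= -lt) | (lf2 <= -lt & b2 >= lt)
  nflip <- flip1 + flip2
  type <- rep("none", length(leps))
  type[sig & nflip == 0L] <- "magnitude"
  type[sig & nflip == 1L] <- "sign"
  type[sig & nflip == 2L] <- "reciprocal_sign"
  sgn <- rep("none", length(leps))
  sgn[sig & leps > 0] <- "positive"
  sgn[sig & leps < 0] <- "negative"
  list(epsilon = exp(leps), significant = sig, sign = sgn, type = type)
}

#' Classify epistasis of a double mutant
#'
#' A pair is significant when its epistasis factor deviates from 1 by at
#' least the fold threshold in either direction (|log eps| >= log
#' threshold). Significant pairs are positive (eps > 1) or negative
#' (eps < 1), and typed by how each mutation's effect behaves across
#' genetic backgrounds: mutation 1's effect in the wild-type background is
#' log(p1/p_wt) and in the mutation-2 background log(p12/p2). A mutation
#' "flips" when its effect exceeds the fold threshold in magnitude in
#' both backgrounds with opposite signs; an effect within the threshold
#' of neutral is indistinguishable from noise and counts as neutral, so
#' it can never flip. No flip = magnitude epistasis, exactly one = sign,
#' both = reciprocal sign.
#'
#' @param p_wt,p1,p2,p12 Wild-type, single-mutant and observed
#'   double-mutant parameter values (positive; vectorised).
#' @param threshold Fold threshold > 1 (default 1.5).
#' @return A `data.frame` with columns `epsilon`, `significant`, `sign`
#'   (`"positive"`, `"negative"` or `"none"`), and `type` (`"none"`,
#'   `"magnitude"`, `"sign"`, `"reciprocal_sign"`).
#' @export
classify_epistasis <- function(p_wt, p1, p2, p12, threshold = 1.5) {
  .check_positive(p_wt = p_wt, p1 = p1, p2 = p2, p12 = p12)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 1) {
    stop("`threshold` must be a single fold > 1", call. = FALSE)
  }
  cl <- .classify_log(log(p1 / p_wt), log(p2 / p_wt), log(p12 / p_wt),
                      threshold)
  data.frame(epsilon = cl$epsilon, significant = cl$significant,
             sign = cl$sign, type = cl$type)
}

# Per-parameter log quantities needed for epistasis, from a variant_table.
.pair_logs <- function(table, param) {
  lw <- log(table$wt[[param]])
  lf <- log(table$singles[[param]]) - lw
  i <- table$pairs$i
  j <- table$pairs$j
  list(lf1 = lf[i], lf2 = lf[j],
       lobs = log(table$pairs[[param]]) - lw)
}

#' Per-pair epistasis records for every kinetic parameter
#'
#' Long-format table with one row per (pair, parameter): observed and
#' null-predicted fold-changes versus wild type, the epistasis factor,
#' one significance flag per threshold, and the sign/type classification
#' at the primary (first) threshold.
#'
#' @param table A `variant_table`.
#' @param thresholds Ascending fold thresholds > 1
#'   (default `c(1.5, 2, 5, 10)`); the first is the primary threshold used
#'   for classification.
#' @return A `data.table` with columns `i`, `j`, `parameter`,
#'   `observed_fold`, `predicted_fold`, `epsilon`,
#'   `significant_<threshold>` (one per threshold), `sign`, `type`.
#' @export
epistasis_records <- function(table, thresholds = c(1.5, 2, 5, 10)) {
  stopifnot(inherits(table, "variant_table"))
  .check_thresholds(thresholds)
  out <- lapply(.PARAM_NAMES, function(p) {
    lg <- .pair_logs(table, p)
    cl <- .classify_log(lg$lf1, lg$lf2, lg$lobs, thresholds[1L])
    leps <- lg$lobs - lg$lf1 - lg$lf2
    dt <- data.table::data.table(
      i = table$pairs$i, j = table$pairs$j, parameter = p,
      observed_fold = exp(lg$lobs),
      predicted_fold = exp(lg$lf1 + lg$lf2),
      epsilon = cl$epsilon)
    for (th in thresholds) {
      dt[[paste0("significant_", as.character(th))]] <- abs(leps) >= log(th)
    }
    dt$sign <- cl$sign
    dt$type <- cl$type
    dt
  })
  data.table::rbindlist(out)
}

.check_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) || !length(thresholds) ||
      any(thresholds <= 1) || is.unsorted(thresholds, strictly = TRUE)) {
    stop("`thresholds` must be strictly ascending folds > 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Prevalence and classification summary of non-specific epistasis
#'
#' For every kinetic parameter, reports: the percentage of all pairs with
#' significant epistasis at each fold threshold; the magnitude / sign /
#' reciprocal-sign class shares at the primary (first) threshold,
#' expressed as percent of all pairs so the three classes sum to the
#' primary prevalence; and the positive / negative split expressed as
#' percent of the significant pairs.
#'
#' @param table A `variant_table` (>= 1 pair).
#' @param thresholds Ascending fold thresholds > 1.
#' @return An object of class `epistasis_summary`: per-parameter lists
#'   with `prevalence_pct` (named by threshold), `class_pct`
#'   (magnitude/sign/reciprocal_sign), `sign_pct` (positive/negative),
#'   and raw `counts`; plus run metadata (n, bounds, seed, mechanism).
#' @export
summarize_epistasis <- function(table, thresholds = c(1.5, 2, 5, 10)) {
  stopifnot(inherits(table, "variant_table"))
  .check_thresholds(thresholds)
  n_pairs <- nrow(table$pairs)
  if (!n_pairs) stop("variant table has no pairs", call. = FALSE)

  params <- lapply(.PARAM_NAMES, function(p) {
    lg <- .pair_logs(table, p)
    cl <- .classify_log(lg$lf1, lg$lf2, lg$lobs, thresholds[1L])
    leps <- lg$lobs - lg$lf1 - lg$lf2
    prevalence <- vapply(thresholds, function(th) {
      100 * sum(abs(leps) >= log(th)) / n_pairs
    }, numeric(1L))
    names(prevalence) <- as.character(thresholds)
    n_sig <- sum(cl$significant)
    class_counts <- c(
      magnitude = sum(cl$type == "magnitude"),
      sign = sum(cl$type == "sign"),
      reciprocal_sign = sum(cl$type == "reciprocal_sign"))
    sign_counts <- c(positive = sum(cl$sign == "positive"),
                     negative = sum(cl$sign == "negative"))
    list(
      prevalence_pct = prevalence,
      class_pct = 100 * class_counts / n_pairs,
      sign_pct = if (n_sig) 100 * sign_counts / n_sig
                 else c(positive = NA_real_, negative = NA_real_),
      counts = c(n_pairs = n_pairs, n_significant = n_sig,
                 class_counts, sign_counts)
    )
  })
  names(params) <- .PARAM_NAMES
  structure(
    list(parameters = params, thresholds = thresholds,
         n_pairs = n_pairs, n = table$n, bounds = table$bounds,
         seed = table$seed, mechanism = table$mechanism,
         temperature = table$temperature),
    class = "epistasis_summary"
  )
}

#' @export
print.epistasis_summary <- function(x, ...) {
  cat("<epistasis_summary> ", x$mechanism, " mechanism, ", x$n_pairs,
      " pairs (n = ", x$n, ")\n", sep = "")
  th <- as.character(x$thresholds)
  cat(sprintf("%-11s %s  %s\n", "parameter",
              paste(sprintf("%7s", paste0(th, "x")), collapse = ""),
              "mag/sign/recip (pos%)"))
  for (p in names(x$parameters)) {
    s <- x$parameters[[p]]
    cat(sprintf("%-11s %s  %4.1f/%3.1f/%3.1f (%s)\n", p,
                paste(sprintf("%6.1f%%", s$prevalence_pct), collapse = ""),
                s$class_pct[["magnitude"]], s$class_pct[["sign"]],
                s$class_pct[["reciprocal_sign"]],
                if (is.na(s$sign_pct[["positive"]])) "-"
                else sprintf("%.1f", s$sign_pct[["positive"]])))
  }
  invisible(x)
}

#' One-call perturbation simulation
#'
#' Samples a mutation library, builds the full single/double variant
#' table, and summarises epistasis — the whole in silico experiment in
#' one call.
#'
#' @param mechanism `"simple"` or `"complex"`.
#' @param n Number of single mutations (default 1000, giving 499,500
#'   unordered doubles).
#' @param bounds Uniform sampling bounds in kcal/mol (default -2..2).
#' @param seed Integer seed for reproducibility.
#' @param temperature Kelvin.
#' @param thresholds Fold thresholds for the summary.
#' @return List with `mutations`, `table` (`variant_table`) and `summary`
#'   (`epistasis_summary`).
#' @export
simulate_epistasis <- function(mechanism = c("simple", "complex"), n = 1000,
                               bounds = c(-2, 2), seed = NULL,
                               temperature = .DEFAULT_TEMPERATURE_K,
                               thresholds = c(1.5, 2, 5, 10)) {
  mechanism <- match.arg(mechanism)
  profile <- default_profile(
    if (mechanism == "simple") "simple_wt" else "complex_wt", temperature)
  mutations <- sample_mutations(n, bounds, mechanism, seed)
  table <- build_variant_table(profile, mutations)
  list(mutations = mutations, table = table,
       summary = summarize_epistasis(table, thresholds))
}
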