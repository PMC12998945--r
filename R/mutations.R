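#' Sample random additive free-energy perturbations ("mutations")
#'
#' Each in silico mutation perturbs the free energy of every rate-relevant
#' state of the mechanism by an independent draw from a uniform
#' distribution on `bounds` (default -2 to 2 kcal/mol). A single mutation
#' is allowed to perturb every state at once, mirroring the empirical
#' observation that real mutations typically shift several barrier and
#' ground-state energies together. Draws are ordered mutation by mutation
#' and, within a mutation, state by state in the canonical state order, so
#' a library is fully reproducible from its seed.
#'
#' @param n Number of mutations (>= 1).
#' @param bounds Length-2 numeric, lower and upper bound in kcal/mol.
#' @param mechanism `"simple"` (4 perturbed states) or `"complex"` (6).
#' @param seed Optional integer seed; when supplied the caller's RNG state
#'   is left untouched.
#' @return An object of class `mutation_set`: an `n` x n_states matrix of
#'   delta-G values (`$dG`) plus the sampling metadata.
#' @export
sample_mutations <- function(n, bounds = c(-2, 2),
                             mechanism = c("simple", "complex"),
                             seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(bounds) || length(bounds) != 2L || any(!is.finite(bounds)) ||
      bounds[1L] >= bounds[2L]) {
    stop("`bounds` must be c(low, high) with low < high", call. = FALSE)
  }
  states <- .states_for(mechanism)
  draw <- function() {
    matrix(stats::runif(n * length(states), bounds[1L], bounds[2L]),
           nrow = n, byrow = TRUE, dimnames = list(NULL, states))
  }
  dG <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(
    list(dG = dG, mechanism = mechanism, bounds = as.numeric(bounds),
         seed = seed, n = as.integer(n)),
    class = "mutation_set"
  )
}

#' @export
print.mutation_set <- function(x, ...) {
  cat("<mutation_set> ", x$n, " mutations, ", x$mechanism,
      " mechanism, bounds [", x$bounds[1L], ", ", x$bounds[2L],
      "] kcal/mol", if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n",
      sep = "")
  invisible(x)
}

#' Extract one mutation's effect vector
#'
#' @param mutations A `mutation_set`.
#' @param i Mutation index.
#' @return Named numeric vector of delta-G per state (kcal/mol).
#' @export
mutation_effect <- function(mutations, i) {
  stopifnot(inherits(mutations, "mutation_set"))
  if (i < 1L || i > mutations$n) stop("mutation index out of range", call. = FALSE)
  mutations$dG[i, ]
}

#' Apply additive mutational effects to a profile
#'
#' Per state, the output energy is the wild-type energy plus the sum of
#' the effects' delta-G values; the order of the effects is irrelevant.
#' Applying two effects at once is how a strictly additive double mutant
#' is constructed.
#'
#' @param profile An `fe_profile`.
#' @param ... One or more effects: named numeric vectors (delta-G per
#'   state, kcal/mol) covering all states of the profile.
#' @return A new `fe_profile` with perturbed energies.
#' @export
apply_effects <- function(profile, ...) {
  stopifnot(inherits(profile, "fe_profile"))
  effects <- list(...)
  if (!length(effects)) return(profile)
  states <- names(profile$energies)
  g <- profile$energies
  for (e in effects) {
    if (is.null(names(e)) || !all(states %in% names(e))) {
      stop("effect must name every state of the profile: ",
           paste(setdiff(states, names(e)), collapse = ", "), call. = FALSE)
    }
    g <- g + as.numeric(e[states])
  }
  energy_profile(profile$mechanism, g, profile$temperature)
}

# Unordered pair indices i < j for n items, column-major over j.
.pair_index <- function(n) {
  n <- as.integer(n)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  list(i = i, j = j)
}

#' Kinetic parameters for a full single + double mutant library
#'
#' Computes microscopic rate constants and kinetic parameters for the
#' wild type, every single mutant, and every unordered pair of mutations
#' (the double mutant's free energies being the wild type plus both
#' delta-G vectors). For each pair the multiplicative null prediction —
#' wild type times the two singles' fold-changes — is stored alongside the
#' observed parameters. Because rate constants are exponentials of
#' additive energies, every pair's microscopic rate constants are exactly
#' the wild type times the two singles' fold-changes; epistasis in the
#' composite parameters is therefore purely non-specific.
#'
#' The computation works on log-rate perturbations, so a 1000-mutation
#' library (499,500 pairs) completes in seconds.
#'
#' @param profile Wild-type `fe_profile`.
#' @param mutations A `mutation_set` for the same mechanism, n >= 2.
#' @return An object of class `variant_table`: `$singles` and `$pairs`
#'   `data.table`s of kinetic parameters (pairs carry `pred_*` null
#'   columns), the wild-type parameters `$wt`, and provenance metadata.
#' @export
build_variant_table <- function(profile, mutations) {
  stopifnot(inherits(profile, "fe_profile"), inherits(mutations, "mutation_set"))
  if (profile$mechanism != mutations$mechanism) {
    stop("profile and mutations use different mechanisms", call. = FALSE)
  }
  n <- mutations$n
  if (n < 2L) stop("need at least 2 mutations to form pairs", call. = FALSE)

  mech <- profile$mechanism
  rt <- .R_KCAL_PER_MOL_K * profile$temperature
  defs <- .rate_defs_for(mech)
  wt_rates <- rates_from_profile(profile)
  log_kw <- log(wt_rates$k)
  wt_par <- kinetic_parameters(wt_rates)

  # Per-single change in log rate constant: barrier change over RT.
  dG <- mutations$dG
  D <- vapply(defs, function(d) -(dG[, d[1L]] - dG[, d[2L]]) / rt, numeric(n))

  single_k <- lapply(seq_along(defs), function(r) exp(log_kw[r] + D[, r]))
  names(single_k) <- names(defs)
  single_par <- do.call(
    if (mech == "simple") .kin_simple else .kin_complex, single_k)

  ij <- .pair_index(n)
  pair_k <- lapply(seq_along(defs), function(r) {
    exp(log_kw[r] + D[ij$i, r] + D[ij$j, r])
  })
  names(pair_k) <- names(defs)
  pair_par <- do.call(
    if (mech == "simple") .kin_simple else .kin_complex, pair_k)

  # Null prediction: log p_wt + single log fold-changes of both mutants.
  log_fold <- lapply(.PARAM_NAMES, function(p) {
    log(single_par[[p]]) - log(wt_par[[p]])
  })
  names(log_fold) <- .PARAM_NAMES
  pred <- lapply(.PARAM_NAMES, function(p) {
    exp(log(wt_par[[p]]) + log_fold[[p]][ij$i] + log_fold[[p]][ij$j])
  })
  names(pred) <- paste0("pred_", .PARAM_NAMES)

  singles <- data.table::as.data.table(
    c(list(id = seq_len(n)), single_par))
  pairs <- data.table::as.data.table(
    c(list(i = ij$i, j = ij$j), pair_par, pred))

  structure(
    list(wt = wt_par, singles = singles, pairs = pairs,
         mechanism = mech, temperature = profile$temperature,
         n = n, bounds = mutations$bounds, seed = mutations$seed),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", x$mechanism, " mechanism: ", x$n,
      " singles, ", nrow(x$pairs), " unordered pairs\n", sep = "")
  cat("wt: k_cat = ", signif(x$wt[["k_cat"]], 4), " 1/s, K_M = ",
      signif(x$wt[["K_M"]] * 1e6, 4), " uM, kcat/K_M = ",
      signif(x$wt[["efficiency"]], 4), " 1/(M s)\n", sep = "")
  invisible(x)
}
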