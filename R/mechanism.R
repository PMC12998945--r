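# Physical constants. Energies are kcal/mol throughout; concentrations molar.
.kB_J_PER_K <- 1.380649e-23
.PLANCK_J_S <- 6.62607015e-34
.R_KCAL_PER_MOL_K <- 1.98720425e-3

.DEFAULT_TEMPERATURE_K <- 298.15

# Canonical state order per mechanism. "_ts" marks a transition state:
# "E+S_ts" is the binding transition state (E+S)++, "ES_ts" the chemical
# transition state (ES)++, "EP_ts" the product-release transition state.
# The free E+P state never enters a rate constant and is not represented.
.STATE_ORDER <- list(
  simple  = c("E+S", "E+S_ts", "ES", "ES_ts"),
  complex = c("E+S", "E+S_ts", "ES", "ES_ts", "EP", "EP_ts")
)

# Each microscopic rate constant is A * exp(-(G_ts - G_ground)/RT) for the
# (transition state, ground state) pair listed here.
.RATE_DEFS <- list(
  simple = list(
    k1       = c("E+S_ts", "E+S"),
    k_minus1 = c("E+S_ts", "ES"),
    k2       = c("ES_ts",  "ES")
  ),
  complex = list(
    k1       = c("E+S_ts", "E+S"),
    k_minus1 = c("E+S_ts", "ES"),
    k2       = c("ES_ts",  "ES"),
    k_minus2 = c("ES_ts",  "EP"),
    k3       = c("EP_ts",  "EP")
  )
)

.states_for <- function(mechanism) .STATE_ORDER[[mechanism]]
.rate_defs_for <- function(mechanism) .RATE_DEFS[[mechanism]]

#' Free-energy profile of an enzyme catalytic cycle
#'
#' Defines the reaction coordinate of a Michaelis-Menten style mechanism by
#' the Gibbs free energy of every ground and transition state. The `simple`
#' mechanism is E + S <-> ES -> E + P (states `E+S`, `E+S_ts`, `ES`,
#' `ES_ts`); the `complex` mechanism adds a reversible chemical step and an
#' irreversible product-release step through an intermediate `EP` (states
#' `EP` and `EP_ts`). The free E + P state never enters any rate constant
#' and is not part of the profile.
#'
#' @param mechanism `"simple"` or `"complex"`.
#' @param energies Named numeric vector of Gibbs free energies in
#'   kcal/mol, one entry per state of the mechanism. Names with a `_ts`
#'   suffix denote transition states.
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @return An object of class `fe_profile`.
#' @seealso [default_profile()] for the built-in wild-type profiles,
#'   [rates_from_profile()] to convert to microscopic rate constants.
#' @examples
#' p <- energy_profile("simple",
#'   c("E+S" = 0, "E+S_ts" = 10, "ES" = -5, "ES_ts" = 11))
#' kinetic_parameters(rates_from_profile(p))
#' @export
energy_profile <- function(mechanism = c("simple", "complex"), energies,
                           temperature = .DEFAULT_TEMPERATURE_K) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)", call. = FALSE)
  }
  req <- .states_for(mechanism)
  if (is.null(names(energies))) {
    stop("`energies` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(req, names(energies))
  if (length(missing)) {
    stop("missing free energy for state(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- as.numeric(energies[req])
  names(e) <- req
  if (any(!is.finite(e))) {
    stop("non-finite free energy for state(s): ",
         paste(req[!is.finite(e)], collapse = ", "), call. = FALSE)
  }
  structure(
    list(mechanism = mechanism, energies = e, temperature = temperature),
    class = "fe_profile"
  )
}

#' Built-in wild-type free-energy profiles
#'
#' `simple_wt` places E+S at 0.0, the binding transition state at 10.0, ES
#' at -5.0 and the chemical transition state at 11.0 kcal/mol, yielding
#' kinetic parameters within the range of median values measured for
#' natural enzymes (k_cat ~ 11.5 1/s, K_M ~ 255 uM). `complex_wt` keeps
#' these energies and adds EP at -9.0 and the product-release transition
#' state at 9.0 kcal/mol, making the chemical step rate limiting.
#'
#' @param name `"simple_wt"` or `"complex_wt"`.
#' @param temperature Absolute temperature in kelvin.
#' @return An `fe_profile`.
#' @export
default_profile <- function(name = c("simple_wt", "complex_wt"),
                            temperature = .DEFAULT_TEMPERATURE_K) {
  name <- match.arg(name)
  simple <- c("E+S" = 0.0, "E+S_ts" = 10.0, "ES" = -5.0, "ES_ts" = 11.0)
  if (name == "simple_wt") {
    energy_profile("simple", simple, temperature)
  } else {
    energy_profile("complex", c(simple, "EP" = -9.0, "EP_ts" = 9.0), temperature)
  }
}

#' @export
print.fe_profile <- function(x, ...) {
  cat("<fe_profile> ", x$mechanism, " mechanism, T = ", x$temperature, " K\n",
      sep = "")
  print(x$energies)
  invisible(x)
}

#' Transition-state-theory pre-exponential factor
#'
#' Returns the Eyring frequency factor A = k_B * T / h. The same numeric
#' value is used as the prefactor of both unimolecular (1/s) and
#' bimolecular (1/(M s)) steps; no diffusion-limit correction is applied,
#' so the bimolecular binding rate may exceed the diffusion limit.
#'
#' @param temperature Absolute temperature in kelvin.
#' @return The prefactor, about 6.21e12 at 298.15 K.
#' @export
thermal_prefactor <- function(temperature = .DEFAULT_TEMPERATURE_K) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  .kB_J_PER_K * temperature / .PLANCK_J_S
}

#' Rate constant from an activation free energy
#'
#' Evaluates rate = A * exp(-(G_ts - G_ground) / (R * T)) with
#' A = k_B * T / h and R in kcal/(mol K). Vectorised over the energies.
#'
#' @param g_transition Transition-state free energy, kcal/mol.
#' @param g_ground Ground-state free energy, kcal/mol.
#' @param temperature Absolute temperature in kelvin.
#' @return The rate constant (1/s for unimolecular steps, 1/(M s) for the
#'   bimolecular binding step; the numeric value is identical).
#' @export
arrhenius_rate <- function(g_transition, g_ground,
                           temperature = .DEFAULT_TEMPERATURE_K) {
  if (any(!is.finite(g_transition)) || any(!is.finite(g_ground))) {
    stop("free energies must be finite", call. = FALSE)
  }
  a <- thermal_prefactor(temperature)
  a * exp(-(g_transition - g_ground) / (.R_KCAL_PER_MOL_K * temperature))
}

#' Microscopic rate constants from a free-energy profile
#'
#' Applies [arrhenius_rate()] to every (transition state, ground state)
#' pair of the mechanism: k1 and k_minus1 share the binding transition
#' state, k2 (and for the complex mechanism k_minus2) share the chemical
#' transition state, and k3 crosses the product-release barrier. Only
#' energy differences matter: shifting every state by a constant leaves
#' all rate constants unchanged.
#'
#' @param profile An `fe_profile`.
#' @return An object of class `rate_constants`: named rates (`k1`,
#'   `k_minus1`, `k2` and, for the complex mechanism, `k_minus2`, `k3`)
#'   plus the mechanism kind.
#' @export
rates_from_profile <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  defs <- .rate_defs_for(profile$mechanism)
  g <- profile$energies
  k <- vapply(defs, function(d) {
    arrhenius_rate(g[[d[1L]]], g[[d[2L]]], profile$temperature)
  }, numeric(1L))
  rate_constants(k, mechanism = profile$mechanism)
}

#' Construct a set of microscopic rate constants
#'
#' @param k Named numeric vector with entries `k1`, `k_minus1`, `k2` and,
#'   for the complex mechanism, `k_minus2` and `k3`. `k1` is bimolecular
#'   (1/(M s)); all others are unimolecular (1/s). All rates must be
#'   positive except `k_minus2`, which may be zero (an effectively
#'   irreversible chemical step, as in acyl-enzyme mechanisms where no
#'   reverse rate is reported).
#' @param mechanism `"simple"` or `"complex"`; inferred from the names of
#'   `k` when omitted.
#' @return An object of class `rate_constants`.
#' @export
rate_constants <- function(k, mechanism = NULL) {
  k <- unlist(k)
  if (is.null(mechanism)) {
    mechanism <- if (all(c("k_minus2", "k3") %in% names(k)) ||
                     "k3" %in% names(k)) "complex" else "simple"
  }
  mechanism <- match.arg(mechanism, c("simple", "complex"))
  req <- names(.rate_defs_for(mechanism))
  if (mechanism == "complex" && !"k_minus2" %in% names(k)) {
    k[["k_minus2"]] <- 0
  }
  missing <- setdiff(req, names(k))
  if (length(missing)) {
    stop("missing rate constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  k <- as.numeric(k[req])
  names(k) <- req
  bad <- !is.finite(k) | k < 0 | (k == 0 & req != "k_minus2")
  if (any(bad)) {
    stop("rate constants must be positive (k_minus2 may be zero): ",
         paste(req[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(mechanism = mechanism, k = k), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("<rate_constants> ", x$mechanism, " mechanism\n", sep = "")
  print(x$k)
  invisible(x)
}

# Vectorised kinetic-parameter kernels. Inputs are equal-length rate
# vectors; outputs a list of equal-length parameter vectors.
.kin_simple <- function(k1, k_minus1, k2) {
  list(
    k_cat      = k2,
    K_M        = (k_minus1 + k2) / k1,
    K_D        = k_minus1 / k1,
    efficiency = k1 * k2 / (k_minus1 + k2)
  )
}

.kin_complex <- function(k1, k_minus1, k2, k_minus2, k3) {
  den <- k2 + k_minus2 + k3
  num <- k2 * k3 + k_minus1 * k_minus2 + k_minus1 * k3
  list(
    k_cat      = k2 * k3 / den,
    K_M        = num / (k1 * den),
    K_D        = k_minus1 / k1,
    efficiency = k1 * k2 * k3 / num
  )
}

.kin_params <- function(mechanism, k) {
  if (mechanism == "simple") {
    .kin_simple(k[["k1"]], k[["k_minus1"]], k[["k2"]])
  } else {
    .kin_complex(k[["k1"]], k[["k_minus1"]], k[["k2"]],
                 k[["k_minus2"]], k[["k3"]])
  }
}

.PARAM_NAMES <- c("k_cat", "K_M", "K_D", "efficiency")

#' Kinetic parameters of a variant
#'
#' Composite observables from microscopic rate constants. Simple
#' mechanism: k_cat = k2, K_M = (k_minus1 + k2)/k1, K_D = k_minus1/k1,
#' efficiency = k_cat/K_M = k1 k2/(k_minus1 + k2). Complex mechanism
#' (steady state through the EP intermediate):
#' k_cat = k2 k3/(k2 + k_minus2 + k3),
#' K_M = (k2 k3 + k_minus1 k_minus2 + k_minus1 k3)/(k1 (k2 + k_minus2 + k3)),
#' efficiency = k1 k2 k3/(k2 k3 + k_minus1 k_minus2 + k_minus1 k3); K_D is
#' unchanged. Units: k_cat 1/s, K_M and K_D molar, efficiency 1/(M s).
#'
#' @param rates A `rate_constants` object.
#' @return An object of class `kinetic_params`: named numeric vector with
#'   entries `k_cat`, `K_M`, `K_D`, `efficiency`.
#' @export
kinetic_parameters <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  p <- unlist(.kin_params(rates$mechanism, as.list(rates$k)))
  structure(p[.PARAM_NAMES], class = "kinetic_params",
            mechanism = rates$mechanism)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> (", attr(x, "mechanism"), " mechanism)\n", sep = "")
  cat(sprintf("  k_cat      = %.4g 1/s\n", x[["k_cat"]]))
  cat(sprintf("  K_M        = %.4g uM\n", x[["K_M"]] * 1e6))
  cat(sprintf("  K_D        = %.4g uM\n", x[["K_D"]] * 1e6))
  cat(sprintf("  kcat/K_M   = %.4g 1/(M s)\n", x[["efficiency"]]))
  invisible(x)
}
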