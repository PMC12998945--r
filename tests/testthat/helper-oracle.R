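# Independent oracles: plain-formula evaluation used to compute expected
# values, deliberately not sharing code with the package internals.

ORACLE_R <- 1.98720425e-3 # kcal/(mol K)
ORACLE_T <- 298.15

oracle_prefactor <- function(temp = ORACLE_T) {
  1.380649e-23 * temp / 6.62607015e-34
}

oracle_rate <- function(g_ts, g_ground, temp = ORACLE_T) {
  oracle_prefactor(temp) * exp(-(g_ts - g_ground) / (ORACLE_R * temp))
}

# Wild-type energies of the two reference profiles.
ORACLE_SIMPLE_G <- c("E+S" = 0, "E+S_ts" = 10, "ES" = -5, "ES_ts" = 11)
ORACLE_COMPLEX_G <- c(ORACLE_SIMPLE_G, "EP" = -9, "EP_ts" = 9)

oracle_simple_rates <- function(g = ORACLE_SIMPLE_G, temp = ORACLE_T) {
  c(k1 = oracle_rate(g[["E+S_ts"]], g[["E+S"]], temp),
    k_minus1 = oracle_rate(g[["E+S_ts"]], g[["ES"]], temp),
    k2 = oracle_rate(g[["ES_ts"]], g[["ES"]], temp))
}

oracle_complex_rates <- function(g = ORACLE_COMPLEX_G, temp = ORACLE_T) {
  c(oracle_simple_rates(g, temp),
    k_minus2 = oracle_rate(g[["ES_ts"]], g[["EP"]], temp),
    k3 = oracle_rate(g[["EP_ts"]], g[["EP"]], temp))
}

oracle_kin_simple <- function(k) {
  c(k_cat = k[["k2"]],
    K_M = (k[["k_minus1"]] + k[["k2"]]) / k[["k1"]],
    K_D = k[["k_minus1"]] / k[["k1"]],
    efficiency = k[["k1"]] * k[["k2"]] / (k[["k_minus1"]] + k[["k2"]]))
}

oracle_kin_complex <- function(k) {
  den <- k[["k2"]] + k[["k_minus2"]] + k[["k3"]]
  num <- k[["k2"]] * k[["k3"]] + k[["k_minus1"]] * k[["k_minus2"]] +
    k[["k_minus1"]] * k[["k3"]]
  c(k_cat = k[["k2"]] * k[["k3"]] / den,
    K_M = num / (k[["k1"]] * den),
    K_D = k[["k_minus1"]] / k[["k1"]],
    efficiency = k[["k1"]] * k[["k2"]] * k[["k3"]] / num)
}

oracle_km_epsilon <- function(a1, b1, a2, b2, km1, k2) {
  (a1 * a2 * km1 + b1 * b2 * k2) * (km1 + k2) /
    ((a1 * km1 + b1 * k2) * (a2 * km1 + b2 * k2))
}

# Random valid fe_profile for property tests (energies need not have
# positive barriers; rates stay positive regardless).
random_profile <- function(mechanism = "simple") {
  states <- if (mechanism == "simple") names(ORACLE_SIMPLE_G)
            else names(ORACLE_COMPLEX_G)
  g <- stats::runif(length(states), -10, 15)
  names(g) <- states
  energy_profile(mechanism, g)
}
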