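test_that("fold_error is symmetric and matches the printed spot checks", {
  expect_equal(fold_error(2200, 1917), 1.15, tolerance = 0.01)
  expect_equal(fold_error(101, 50), 2.02, tolerance = 0.005)
  expect_gt(fold_error(101, 50), 1.5) # flagged by the 1.5-fold screen
  expect_equal(fold_error(3.7, 3.7), 1)
  expect_equal(fold_error(2, 8), fold_error(8, 2))
  expect_error(fold_error(0, 1), "positive")
})

test_that("expected_double_rates is the per-rate multiplicative null", {
  wt <- rate_constants(c(k1 = 100, k_minus1 = 10, k2 = 1))
  mA <- rate_constants(c(k1 = 50, k_minus1 = 10, k2 = 3))
  mB <- rate_constants(c(k1 = 200, k_minus1 = 10, k2 = 0.5))
  ed <- expected_double_rates(wt, mA, mB)
  expect_equal(ed$k, c(k1 = 100, k_minus1 = 10, k2 = 1.5))
  expect_equal(expected_double_rates(wt, wt, mB)$k, mB$k) # neutral mutA

  # additive synthetic doubles carry zero specific epistasis
  pr <- default_profile("complex_wt")
  m <- sample_mutations(2, mechanism = "complex", seed = 19)
  r_wt <- rates_from_profile(pr)
  r_a <- rates_from_profile(apply_effects(pr, mutation_effect(m, 1)))
  r_b <- rates_from_profile(apply_effects(pr, mutation_effect(m, 2)))
  r_d <- rates_from_profile(
    apply_effects(pr, mutation_effect(m, 1), mutation_effect(m, 2)))
  expect_equal(specific_epistasis(r_d, expected_double_rates(r_wt, r_a, r_b)),
               c(k1 = 1, k_minus1 = 1, k2 = 1, k_minus2 = 1, k3 = 1),
               tolerance = 1e-10)

  simple <- rate_constants(c(k1 = 1, k_minus1 = 1, k2 = 1))
  expect_error(expected_double_rates(r_wt, r_a, simple), "mechanism")
})

test_that("specific epistasis isolates injected rate-level deviations", {
  wt <- rate_constants(c(k1 = 1e5, k_minus1 = 60, k2 = 10))
  mA <- rate_constants(c(k1 = 2e5, k_minus1 = 30, k2 = 5))
  mB <- rate_constants(c(k1 = 5e4, k_minus1 = 90, k2 = 20))
  exp_d <- expected_double_rates(wt, mA, mB)
  obs <- rate_constants(c(k1 = exp_d$k[["k1"]],
                          k_minus1 = exp_d$k[["k_minus1"]],
                          k2 = 2 * exp_d$k[["k2"]]))
  se <- specific_epistasis(obs, exp_d)
  expect_equal(se, c(k1 = 1, k_minus1 = 1, k2 = 2))
})

test_that("correction report decomposes apparent into nonspecific x corrected", {
  pr <- default_profile("simple_wt")
  m <- sample_mutations(2, seed = 23)
  r_wt <- rates_from_profile(pr)
  r_a <- rates_from_profile(apply_effects(pr, mutation_effect(m, 1)))
  r_b <- rates_from_profile(apply_effects(pr, mutation_effect(m, 2)))
  # observed double with genuine specific epistasis on two rates
  k_d <- expected_double_rates(r_wt, r_a, r_b)$k
  k_d[["k2"]] <- k_d[["k2"]] * 3
  k_d[["k_minus1"]] <- k_d[["k_minus1"]] * 0.5
  set <- experimental_variant_set(r_wt, r_a, r_b, rate_constants(k_d))
  rep <- correction_report(set)
  expect_equal(rep$apparent_epsilon,
               rep$nonspecific_epsilon * rep$corrected_epsilon,
               tolerance = 1e-10)
  expect_equal(rep$specific_epistasis[["k2"]], 3, tolerance = 1e-10)
  expect_equal(rep$specific_epistasis[["k_minus1"]], 0.5, tolerance = 1e-10)
  # K_D nonspecific epistasis is always 1 (ratio of two rate constants)
  expect_equal(rep$nonspecific_epsilon[["K_D"]], 1, tolerance = 1e-10)

  # multiplicative double: corrected specific epsilon is exactly 1 and
  # nonspecific equals the pure-ensemble prediction
  set0 <- experimental_variant_set(
    r_wt, r_a, r_b, expected_double_rates(r_wt, r_a, r_b))
  rep0 <- correction_report(set0)
  expect_equal(rep0$corrected_epsilon,
               setNames(rep(1, 4), names(rep0$corrected_epsilon)),
               tolerance = 1e-10)
  expect_equal(rep0$nonspecific_epsilon, rep0$apparent_epsilon,
               tolerance = 1e-12)
})

test_that("uniform fold effects on all rates produce no nonspecific epistasis", {
  wt <- rate_constants(c(k1 = 1e5, k_minus1 = 60, k2 = 10))
  mA <- rate_constants(0.2 * wt$k)
  mB <- rate_constants(4 * wt$k)
  dd <- expected_double_rates(wt, mA, mB)
  rep <- correction_report(experimental_variant_set(wt, mA, mB, dd))
  expect_equal(rep$nonspecific_epsilon,
               setNames(rep(1, 4), names(rep$nonspecific_epsilon)),
               tolerance = 1e-10)
})

test_that("the k_minus1 x0.1/x0.1 worked case gives nonspecific eps(K_M) ~ 2.845", {
  wt <- rates_from_profile(default_profile("simple_wt"))
  k_a <- wt$k; k_a[["k_minus1"]] <- 0.1 * k_a[["k_minus1"]]
  mA <- rate_constants(k_a)
  dd <- expected_double_rates(wt, mA, mA)
  rep <- correction_report(experimental_variant_set(wt, mA, mA, dd))
  expect_equal(rep$nonspecific_epsilon[["K_M"]], 2.845099, tolerance = 1e-6)
  expect_equal(rep$corrected_epsilon[["K_M"]], 1, tolerance = 1e-10)
  # matches the closed form with alpha = 0.1, beta = 1 for both mutations
  expect_equal(rep$nonspecific_epsilon[["K_M"]],
               oracle_km_epsilon(0.1, 1, 0.1, 1, wt$k[["k_minus1"]],
                                 wt$k[["k2"]]),
               tolerance = 1e-12)
})

test_that("measured parameters only feed fold-error screening; bounds warn", {
  wt <- rate_constants(c(k1 = 1e5, k_minus1 = 60, k2 = 10))
  mA <- rate_constants(c(k1 = 9e4, k_minus1 = 70, k2 = 8))
  dd <- expected_double_rates(wt, mA, mA)
  measured <- list(wt = c(k_cat = 22, K_M = 7.5e-4)) # computed K_M = 7e-4
  set <- experimental_variant_set(wt, mA, mA, dd, measured = measured,
                                  bound_flags = list(double = "k2"))
  rep <- correction_report(set)
  expect_equal(rep$fold_errors$wt$fold_error[["k_cat"]], 2.2)
  expect_identical(rep$fold_errors$wt$flagged, "k_cat")
  expect_match(rep$warnings, "double.*k2")
  # epsilons identical with and without measurements
  rep2 <- correction_report(experimental_variant_set(wt, mA, mA, dd))
  expect_equal(rep$apparent_epsilon, rep2$apparent_epsilon)

  expect_error(
    experimental_variant_set(wt, mA, mA, dd, measured = list(xx = c(k_cat = 1))),
    "xx")
  expect_error(
    experimental_variant_set(wt, mA, mA, dd, bound_flags = list(wt = "k9")),
    "k9")
})
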