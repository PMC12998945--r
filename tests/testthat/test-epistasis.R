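test_that("null_predicted and epsilon implement the multiplicative null", {
  expect_equal(null_predicted(10, 20, 30), 60)
  expect_equal(null_predicted(7, 7, 13), 13) # neutral first mutation
  expect_error(null_predicted(0, 1, 1), "positive")

  expect_equal(epsilon(5, 5), 1)
  expect_error(epsilon(-1, 2), "positive")

  # worked case: both singles scale k_minus1 by 0.1 only (frozen oracle:
  # K_M_wt = 256.25 uM, single K_M = 61.62 uM, predicted 14.82 uM)
  k <- oracle_simple_rates()
  km_wt <- (k[["k_minus1"]] + k[["k2"]]) / k[["k1"]]
  km_1 <- (0.1 * k[["k_minus1"]] + k[["k2"]]) / k[["k1"]]
  pred <- null_predicted(km_wt, km_1, km_1)
  expect_equal(pred * 1e6, 14.81644, tolerance = 1e-6)
  km_12 <- (0.01 * k[["k_minus1"]] + k[["k2"]]) / k[["k1"]]
  expect_equal(epsilon(km_12, pred), 2.845099, tolerance = 1e-6)
})

test_that("classification follows the thresholded-flip rule", {
  # exact multiplicativity: not significant
  r <- classify_epistasis(1, 2, 2, 4, 1.5)
  expect_equal(r$epsilon, 1)
  expect_identical(r$sign, "none")
  expect_identical(r$type, "none")

  # positive magnitude: both effects beneficial in both backgrounds
  r <- classify_epistasis(1, 2, 2, 8, 1.5)
  expect_equal(r$epsilon, 2)
  expect_identical(c(r$sign, r$type), c("positive", "magnitude"))

  # background effects 0.8x and 0.75x are inside the 1.5-fold noise band,
  # so these stay magnitude epistasis despite the strict sign change
  r <- classify_epistasis(1, 2, 3, 2.4, 1.5)
  expect_equal(r$epsilon, 0.4)
  expect_identical(c(r$sign, r$type), c("negative", "magnitude"))
  r <- classify_epistasis(1, 2, 2, 1.5, 1.5)
  expect_equal(r$epsilon, 0.375)
  expect_identical(c(r$sign, r$type), c("negative", "magnitude"))

  # one genuine above-threshold flip (mutation 1: 2x -> 0.6x)
  r <- classify_epistasis(1, 2, 3, 1.8, 1.5)
  expect_equal(r$epsilon, 0.3)
  expect_identical(c(r$sign, r$type), c("negative", "sign"))

  # both flip above threshold (2x -> 1/6x, 3x -> 1/4x)
  r <- classify_epistasis(1, 2, 3, 0.5, 1.5)
  expect_identical(c(r$sign, r$type), c("negative", "reciprocal_sign"))

  expect_error(classify_epistasis(1, 2, 2, 4, threshold = 1), "threshold")
  expect_error(classify_epistasis(1, -2, 2, 4), "positive")
})

test_that("simple mechanism: k_cat and K_D are exactly non-epistatic", {
  sim <- simulate_epistasis("simple", n = 40, seed = 5)
  for (p in c("k_cat", "K_D")) {
    lg <- kinepistasis:::.pair_logs(sim$table, p)
    eps <- exp(lg$lobs - lg$lf1 - lg$lf2)
    expect_equal(eps, rep(1, length(eps)), tolerance = 1e-10)
    expect_equal(sim$summary$parameters[[p]]$prevalence_pct,
                 setNames(rep(0, 4), c("1.5", "2", "5", "10")))
  }
  # K_M and efficiency epsilons are exact reciprocals (since eps(kcat)=1)
  km <- kinepistasis:::.pair_logs(sim$table, "K_M")
  ef <- kinepistasis:::.pair_logs(sim$table, "efficiency")
  expect_equal((km$lobs - km$lf1 - km$lf2) + (ef$lobs - ef$lf1 - ef$lf2),
               rep(0, nrow(sim$table$pairs)), tolerance = 1e-10)
})

test_that("complex mechanism: K_D stays non-epistatic, k_cat does not", {
  sim <- simulate_epistasis("complex", n = 40, seed = 6)
  kd <- kinepistasis:::.pair_logs(sim$table, "K_D")
  expect_equal(exp(kd$lobs - kd$lf1 - kd$lf2),
               rep(1, nrow(sim$table$pairs)), tolerance = 1e-10)
  kc <- kinepistasis:::.pair_logs(sim$table, "k_cat")
  expect_gt(max(abs(kc$lobs - kc$lf1 - kc$lf2)), 0.01)
})

test_that("pipeline epsilon(K_M) equals the closed form on extracted folds", {
  sim <- simulate_epistasis("simple", n = 30, seed = 9)
  tb <- sim$table
  k <- rates_from_profile(default_profile("simple_wt"))$k
  # per-single folds on k_minus1 and k2 from the raw delta-G draws
  rt <- 1.98720425e-3 * 298.15
  dG <- sim$mutations$dG
  alpha <- exp(-(dG[, "E+S_ts"] - dG[, "ES"]) / rt)
  beta <- exp(-(dG[, "ES_ts"] - dG[, "ES"]) / rt)
  lg <- kinepistasis:::.pair_logs(tb, "K_M")
  eps_pipe <- exp(lg$lobs - lg$lf1 - lg$lf2)
  i <- tb$pairs$i; j <- tb$pairs$j
  eps_eq <- oracle_km_epsilon(alpha[i], beta[i], alpha[j], beta[j],
                              k[["k_minus1"]], k[["k2"]])
  expect_equal(eps_pipe, eps_eq, tolerance = 1e-8)
})

test_that("summary shares are internally consistent", {
  sim <- simulate_epistasis("simple", n = 200, seed = 10)
  s <- sim$summary$parameters$efficiency
  expect_equal(sum(s$class_pct), s$prevalence_pct[["1.5"]], tolerance = 1e-9)
  expect_equal(sum(s$sign_pct), 100, tolerance = 1e-9)
  expect_equal(s$counts[["n_pairs"]], choose(200, 2))
  # single non-epistatic pair: zero everywhere
  pr <- default_profile("simple_wt")
  m <- sample_mutations(2, seed = 1)
  m$dG[, ] <- 0 # two null mutations
  s0 <- summarize_epistasis(build_variant_table(pr, m))
  expect_true(all(vapply(s0$parameters,
                         function(p) all(p$prevalence_pct == 0), logical(1))))
  expect_error(summarize_epistasis(sim$table, thresholds = c(2, 1.5)),
               "ascending")
})

test_that("epistasis_records carries folds, flags and classes per parameter", {
  sim <- simulate_epistasis("simple", n = 10, seed = 13)
  rec <- epistasis_records(sim$table)
  expect_equal(nrow(rec), 4 * choose(10, 2))
  expect_setequal(unique(rec$parameter),
                  c("k_cat", "K_M", "K_D", "efficiency"))
  expect_equal(rec$epsilon, rec$observed_fold / rec$predicted_fold,
               tolerance = 1e-12)
  # significance flags are nested across thresholds
  expect_true(all(rec$significant_2[rec$significant_5]))
  expect_true(all(rec$significant_1.5[rec$significant_2]))
  # k_cat rows are never significant in the simple mechanism
  expect_false(any(rec$significant_1.5[rec$parameter == "k_cat"]))
})
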