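test_that("combination index matches its definition on a hand-computed case", {
  res <- combination_index(5, 10, 0.5,
                           list(dm = 10, m = 1), list(dm = 20, m = 1))
  expect_equal(res$ci, 1.0)
  expect_equal(res$dxa, 10)
  expect_equal(res$dxb, 20)
  expect_error(
    combination_index(5, 10, 1, list(dm = 10, m = 1), list(dm = 20, m = 1)),
    "undefined"
  )
  expect_error(
    combination_index(0, 10, 0.5, list(dm = 10, m = 1), list(dm = 20, m = 1)),
    "doses"
  )
})

test_that("a drug combined with itself is Loewe-additive at any split and dose", {
  model <- list(dm = 3.7, m = 1.9)
  for (split in c(0.2, 0.5, 0.8)) {
    for (total in c(0.5, 3.7, 20)) {
      fa <- predict_fa(model, total)
      res <- combination_index(split * total, (1 - split) * total, fa,
                               model, model)
      expect_equal(res$ci, 1, tolerance = 1e-12)
    }
  }
})

test_that("CI is invariant under a common rescaling of dose units", {
  m_a <- list(dm = 2, m = 1.4); m_b <- list(dm = 9, m = 2.6)
  res1 <- combination_index(1.5, 4, 0.37, m_a, m_b)
  scaled_a <- list(dm = 2 * 1000, m = 1.4)
  scaled_b <- list(dm = 9 * 1000, m = 2.6)
  res2 <- combination_index(1500, 4000, 0.37, scaled_a, scaled_b)
  expect_equal(res1$ci, res2$ci, tolerance = 1e-12)
})

test_that("constant-ratio design keeps the dose ratio fixed at every level", {
  d <- constant_ratio_design("A", "B", 10, 20)
  expect_equal(d$rho_a + d$rho_b, 1)
  expect_true(d$rho_a > 0 && d$rho_a < 1)
  expect_equal(d$levels$dose_a / d$levels$dose_b,
               rep(10 / 20, nrow(d$levels)))
  expect_equal(d$levels$multiplier, c(1/8, 1/4, 1/2, 1, 2, 4))
})

test_that("dose series returns the design's fractions and multiples", {
  expect_equal(design_dose_series(16), c(2, 4, 8, 16, 32, 64))
  expect_equal(design_dose_series(1), c(0.125, 0.25, 0.5, 1, 2, 4))
  expect_equal(design_dose_series(7, multipliers = 1), 7)
  expect_error(design_dose_series(-1), "positive")
})

test_that("metal-binding equivalent ratios follow ligand denticity", {
  expect_equal(metal_complex_ratio("hexadentate")$label, "1:1")
  expect_equal(metal_complex_ratio("tridentate")$label, "2:1")
  expect_equal(metal_complex_ratio("tridentate")$chelator, 2L)
  expect_error(metal_complex_ratio("bidentate"))
})

test_that("sham self-mixture refits to the drug's own parameters", {
  model <- list(dm = 1, m = 1)
  design <- constant_ratio_design("A", "A'", 1, 1)
  total <- design$levels$total
  fit <- fit_mixture(design, total, predict_fa(model, total))
  expect_equal(fit$dm, 1, tolerance = 1e-9)
  expect_equal(fit$m, 1, tolerance = 1e-9)
})

test_that("equal-slope constant-CI mixture has the closed-form median-effect curve", {
  # with equal slopes the mixture solving the CI equation is itself
  # median-effect with dm_mix = ci_star / (rho_a/dm_a + rho_b/dm_b)
  m_a <- list(dm = 10, m = 1); m_b <- list(dm = 20, m = 1)
  design <- constant_ratio_design("A", "B", 10, 20)
  ci_star <- 1
  dm_mix <- ci_star / (design$rho_a / 10 + design$rho_b / 20)
  total <- design_dose_series(dm_mix, c(1/8, 1/4, 1/2, 1, 2, 4))
  fa <- vapply(total, function(D) {
    solve_combination_fa(D, design$rho_a, design$rho_b, m_a, m_b, ci_star)$fa
  }, numeric(1))
  fit <- fit_mixture(design, total, fa)
  expect_equal(fit$dm, dm_mix, tolerance = 1e-6)
  expect_equal(fit$m, 1, tolerance = 1e-6)
})

test_that("noisy mixtures still yield finite fits across experiments", {
  plate <- plate_config(noise_sd = 0.05, seed = 99)
  wells <- simulate_combination(agent_spec("A", 10, 1.5),
                                agent_spec("B", 20, 2),
                                interaction_spec(1), plate)
  per_dose <- collapse_replicates(normalize_wells(wells))
  design <- constant_ratio_design("A", "B", 10, 20)
  for (d in split(per_dose, per_dose$experiment_id)) {
    fit <- fit_mixture(design, d$total_dose, d$fa)
    expect_true(is.finite(fit$dm) && is.finite(fit$m))
  }
})

test_that("sham Fa-CI profile is identically 1", {
  model <- list(dm = 2.5, m = 1.7)
  design <- constant_ratio_design("A", "A'", 3, 7)  # asymmetric split
  prof <- fa_ci_curve(model, model, model, design)
  expect_equal(nrow(prof), 99)
  expect_lt(max(abs(prof$ci - 1)), 1e-9)
})

test_that("equal-slope constant-CI system yields a uniform Fa-CI profile", {
  m_a <- list(dm = 10, m = 2); m_b <- list(dm = 20, m = 2)
  design <- constant_ratio_design("A", "B", 10, 20)
  ci_star <- 0.3
  dm_mix <- (ci_star / (design$rho_a / 10 + design$rho_b / 20))^1 # m = 2 shared
  # mixture curve from dense noise-free generated points
  total <- 10^seq(log10(dm_mix) - 1.2, log10(dm_mix) + 1.2, length.out = 25)
  fa <- vapply(total, function(D) {
    solve_combination_fa(D, design$rho_a, design$rho_b, m_a, m_b, ci_star)$fa
  }, numeric(1))
  mixture <- fit_mixture(design, total, fa)
  prof <- fa_ci_curve(m_a, m_b, mixture, design)
  expect_lt(max(abs(prof$ci - ci_star)), 1e-6)
})

test_that("Loewe-additive generation with unequal slopes gives a CI profile crossing 1", {
  # equal dm, different m: the generated mixture is additive by construction
  # but not itself median-effect, so the fitted profile bends through 1
  # rather than sitting on it
  m_a <- list(dm = 5, m = 1); m_b <- list(dm = 5, m = 3)
  design <- constant_ratio_design("A", "B", 5, 5)
  total <- 10^seq(log10(5) - 1.5, log10(5) + 1.5, length.out = 40)
  fa <- vapply(total, function(D) {
    solve_combination_fa(D, design$rho_a, design$rho_b, m_a, m_b, 1)$fa
  }, numeric(1))
  mixture <- fit_mixture(design, total, fa)
  prof <- fa_ci_curve(m_a, m_b, mixture, design)
  crossing_fa <- prof$fa[which(diff(sign(prof$ci - 1)) != 0)]
  expect_gte(length(crossing_fa), 1)
  expect_lt(min(prof$ci), 1)
  expect_gt(max(prof$ci), 1)
})

test_that("fa_ci_curve matches the bisection brute-force oracle", {
  grid <- seq(0.01, 0.99, by = 0.01)
  systems <- list(
    list(a = list(dm = 10, m = 1), b = list(dm = 20, m = 1),
         mix = list(dm = 13, m = 1)),
    list(a = list(dm = 0.004, m = 2.3), b = list(dm = 16.9, m = 1.5),
         mix = list(dm = 9, m = 1.8)),
    list(a = list(dm = 5, m = 1), b = list(dm = 5, m = 3),
         mix = list(dm = 5, m = 2))
  )
  for (sys in systems) {
    design <- constant_ratio_design("A", "B", sys$a$dm, sys$b$dm)
    prof <- fa_ci_curve(sys$a, sys$b, sys$mix, design, fa_grid = grid)
    oracle <- brute_force_fa_ci(sys$a, sys$b, sys$mix, design, grid)
    expect_lt(max(abs(prof$ci - oracle) / oracle), 1e-8)
  }
})

test_that("per-experiment CI at a design point uses each experiment's own fits", {
  model <- list(dm = 4, m = 2)
  s <- noise_free_series(4, 2)
  fits <- lapply(1:4, function(i) fit_median_effect(s$dose, s$fa))
  names(fits) <- paste0("exp", 1:4)
  design <- constant_ratio_design("A", "A'", 4, 4)
  fa_obs <- setNames(rep(predict_fa(model, 8), 4), names(fits))
  res <- ci_at_design_point(design, 1, fits, fits, fa_obs)
  expect_equal(nrow(res), 4)
  expect_equal(res$ci, rep(1, 4), tolerance = 1e-9)

  # a missing fit is excluded and reported, not dropped
  fits_missing <- fits; fits_missing[["exp2"]] <- NULL
  res2 <- ci_at_design_point(design, 1, fits_missing, fits, fa_obs)
  expect_true(is.na(res2$ci[res2$experiment_id == "exp2"]))
  expect_match(res2$flag[res2$experiment_id == "exp2"], "missing")
  expect_equal(sum(is.finite(res2$ci)), 3)
})

test_that("cross-experiment aggregation reports mean, sample SD and n", {
  agg <- aggregate_experiments(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(agg$mean, 5)
  expect_equal(agg$sd, sqrt(32 / 7), tolerance = 1e-12)
  expect_equal(agg$n, 8)

  exact <- aggregate_experiments(rep(1, 4))
  expect_equal(exact$mean, 1)
  expect_equal(exact$sd, 0)

  single <- aggregate_experiments(0.5)
  expect_true(is.na(single$sd))
  expect_match(single$flag, "SD undefined")
  expect_error(aggregate_experiments(rep(NA_real_, 3)), "no valid values")
})
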