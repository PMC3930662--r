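test_that("single-agent simulation is deterministic and noise-free-exact", {
  spec <- agent_spec("X", 10, 2)
  plate0 <- plate_config(noise_sd = 0, seed = 5)
  w <- simulate_single_agent(spec, plate0)
  # controls read exactly baseline; dose = Dm reads exactly half of it
  expect_true(all(w$signal[w$is_control] == 1))
  at_dm <- w$signal[!w$is_control & w$dose_a == 10]
  expect_equal(at_dm, rep(0.5, length(at_dm)))

  plate <- plate_config(noise_sd = 0.05, seed = 5)
  w1 <- simulate_single_agent(spec, plate)
  w2 <- simulate_single_agent(spec, plate)
  expect_identical(w1, w2)
  w3 <- simulate_single_agent(spec, plate_config(noise_sd = 0.05, seed = 6))
  expect_false(identical(w1$signal, w3$signal))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(runif(1))
  invisible(simulate_single_agent(agent_spec("X", 1, 1),
                                  plate_config(seed = 9)))
  after <- runif(2)
  expect_identical(before[2:3], after)
})

test_that("constant-CI root solve agrees with a grid-scan bracket oracle", {
  m_a <- list(dm = 10, m = 1.5); m_b <- list(dm = 20, m = 2.5)
  design <- constant_ratio_design("A", "B", 10, 20)
  lhs <- function(fa, D) {
    design$rho_a * D / dose_for_fa(m_a, fa) +
      design$rho_b * D / dose_for_fa(m_b, fa)
  }
  for (ci_star in c(0.3, 1, 2)) {
    for (D in design$levels$total) {
      sol <- solve_combination_fa(D, design$rho_a, design$rho_b,
                                  m_a, m_b, ci_star)
      expect_false(sol$clamped)
      # root satisfies the CI equation to high precision
      expect_lt(abs(lhs(sol$fa, D) - ci_star), 1e-6)
      # and lies inside the sign-change bracket of a 1e-3-step scan
      grid <- seq(1e-3, 1 - 1e-3, by = 1e-3)
      vals <- lhs(grid, D) - ci_star
      k <- which(diff(sign(vals)) != 0)[1]
      # the root may coincide with a grid point up to solver tolerance
      expect_true(sol$fa >= grid[k] - 1e-6 && sol$fa <= grid[k + 1] + 1e-6)
    }
  }
})

test_that("generated combination effect is monotone in total dose", {
  for (ci_star in c(0.2, 1, 2.5)) {
    w <- simulate_combination(agent_spec("A", 5, 1.2),
                              agent_spec("B", 40, 2.8),
                              interaction_spec(ci_star),
                              plate_config(noise_sd = 0, seed = 3))
    d <- collapse_replicates(normalize_wells(w))
    for (e in split(d, d$experiment_id)) {
      expect_true(all(diff(e$fa[order(e$total_dose)]) >= 0))
    }
  }
})

test_that("sham combination generation reproduces the single agent", {
  spec <- agent_spec("A", 8, 1.7)
  w <- simulate_combination(spec, agent_spec("A2", 8, 1.7),
                            interaction_spec(1),
                            plate_config(noise_sd = 0, seed = 1))
  d <- collapse_replicates(normalize_wells(w))
  expect_equal(d$fa, predict_fa_true(d$total_dose, 8, 1.7), tolerance = 1e-9)
})

test_that("noise-free analysis of a full study recovers all ground truth", {
  panel <- list(agent_spec("A", 16.902, 1.6), agent_spec("B", 0.004, 2.2))
  pairs <- list(list(a = "A", b = "B", interaction = interaction_spec(0.5)))
  st <- generate_study(panel, pairs, plate_config(noise_sd = 0, seed = 21))
  rep <- run_study(st)
  for (k in seq_along(panel)) {
    truth <- st$manifest$true_dm_a[st$manifest$arm == panel[[k]]$agent_id]
    est <- rep$ic50_table$ic50_mean[rep$ic50_table$agent == panel[[k]]$agent_id]
    expect_lt(abs(est - truth) / truth, 1e-9)
  }
  expect_lt(max(abs(rep$ci_by_experiment$ci - 0.5)), 1e-9)
})

test_that("study generation counts arms and rejects duplicate agents", {
  panel <- list(agent_spec("A", 1, 1), agent_spec("B", 2, 1),
                agent_spec("C", 3, 1), agent_spec("D", 4, 1))
  pairs <- list(list(a = "A", b = "B", interaction = interaction_spec(0.5)),
                list(a = "C", b = "D", interaction = interaction_spec(2)))
  st <- generate_study(panel, pairs, plate_config(n_experiments = 4, seed = 1))
  arms <- unique(paste(st$wells$agent_a, st$wells$agent_b))
  expect_equal(length(arms), 6)   # 4 single + 2 combination arms
  expect_equal(nrow(st$manifest), 6)
  expect_equal(length(unique(st$wells$experiment_id)), 4)

  expect_error(
    generate_study(list(agent_spec("A", 1, 1), agent_spec("A", 2, 1))),
    "duplicate"
  )
  expect_error(
    generate_study(panel[1:2],
                   list(list(a = "A", b = "Z",
                             interaction = interaction_spec(1)))),
    "missing from the panel"
  )
})

test_that("control normalisation is exact without noise and unbiased with it", {
  w0 <- simulate_single_agent(agent_spec("X", 2, 1),
                              plate_config(noise_sd = 0, seed = 4))
  ctl0 <- w0$signal[w0$is_control]
  expect_equal(mean(ctl0), 1)
  plate <- plate_config(noise_sd = 0.05, control_wells = 8, seed = 4)
  w <- simulate_single_agent(agent_spec("X", 2, 1), plate)
  ctl <- w$signal[w$is_control & w$experiment_id == "exp01"]
  expect_lt(abs(mean(ctl) - 1), 3 * 0.05 / sqrt(8))
})

test_that("example panel carries the literature-scale potencies", {
  panel <- example_panel()
  dms <- vapply(panel, `[[`, numeric(1), "true_dm")
  expect_equal(dms, c(16.902, 14.004, 19.137, 0.004))
  ratios <- vapply(panel, function(s) metal_complex_ratio(s$denticity_class)$label,
                   character(1))
  expect_equal(ratios, c("1:1", "2:1", "2:1", "2:1"))
})

test_that("per-experiment Dm jitter produces heterogeneous but valid experiments", {
  plate <- plate_config(noise_sd = 0, dm_jitter_sd = 0.2, seed = 8)
  w <- simulate_single_agent(agent_spec("X", 10, 2), plate)
  d <- collapse_replicates(normalize_wells(w))
  dms <- vapply(split(d, d$experiment_id), function(e) {
    fit_median_effect(e$dose_a, e$fa)$dm
  }, numeric(1))
  expect_gt(sd(dms), 0)
  expect_true(all(dms > 0))
})
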