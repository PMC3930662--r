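# Independent oracles used across tests. These deliberately avoid the
# closed-form inversions in the package: doses are recovered from the forward
# model by bisection only.

# bisection solve of predict-forward fa(D) = fa for D, on a log-dose bracket
bisect_dose_for_fa <- function(model, fa, lo = 1e-12, hi = 1e12,
                               tol = 1e-14) {
  f <- function(logd) 1 / (1 + (model$dm / 10^logd)^model$m) - fa
  stats::uniroot(f, lower = log10(lo), upper = log10(hi), tol = tol)$root |>
    (\(x) 10^x)()
}

# brute-force Fa-CI evaluation: every dose solved by bisection
brute_force_fa_ci <- function(model_a, model_b, mixture, design, fa_grid) {
  vapply(fa_grid, function(fa) {
    D <- bisect_dose_for_fa(mixture, fa)
    da <- design$rho_a * D
    db <- design$rho_b * D
    da / bisect_dose_for_fa(model_a, fa) + db / bisect_dose_for_fa(model_b, fa)
  }, numeric(1))
}

# noise-free dose/fa series from known parameters
noise_free_series <- function(dm, m, multipliers = c(1/8, 1/4, 1/2, 1, 2, 4)) {
  dose <- design_dose_series(dm, multipliers)
  list(dose = dose, fa = predict_fa_true(dose, dm, m))
}

# random valid median-effect models under a fixed seed
random_models <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(dm = 10^stats::runif(1, -3, 2), m = stats::runif(1, 0.5, 4))
  })
}
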