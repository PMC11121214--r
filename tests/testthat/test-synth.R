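test_that("the toy track Monte Carlo is seeded, calibrated, and overdispersed", {
  geom <- target_geometry(2.3, 3.4)
  # determinism under a fixed seed
  a <- simulate_icsd(track_params(1, 0.5, 0.8, n_histories = 5000, seed = 42), geom)
  b <- simulate_icsd(track_params(1, 0.5, 0.8, n_histories = 5000, seed = 42), geom)
  expect_identical(unclass(a), unclass(b))
  # vanishing rate concentrates all mass at nu = 0
  tiny <- simulate_icsd(track_params(1e-9, n_histories = 2000, seed = 1), geom)
  expect_equal(unclass(tiny)[1], 1)
  # pure Poisson mode: empirical mean within 3 standard errors of lambda * h
  n <- 20000
  pois <- simulate_icsd(track_params(1.2, 0, 0, n_histories = n, seed = 7), geom)
  mu <- 1.2 * 3.4
  expect_lt(abs(m1(pois) - mu), 3 * sqrt(mu / n))
  # clustered mode is overdispersed
  cl <- simulate_icsd(track_params(1.2, 1.0, 0, n_histories = n, seed = 8), geom)
  p <- unclass(cl); nu <- seq_along(p) - 1
  vmr <- (sum(nu^2 * p) - m1(cl)^2) / m1(cl)
  expect_gt(vmr, 1.5)
  expect_error(simulate_icsd(track_params(1), "not a geometry"))
})

test_that("mean cluster size shrinks as radial spread grows", {
  geom <- target_geometry(2.0, 3.0)
  means <- vapply(c(0, 0.5, 1, 2), function(s) {
    m1(simulate_icsd(track_params(2, 0.5, s, n_histories = 8000, seed = 101), geom))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("analytic table matches the compound-Poisson track-model moments", {
  tab <- synthetic_icsd_table(
    particles = default_particles()[c(2, 5), ],
    energies = c(1, 10, 100),
    geometries = tibble::tibble(target_d_nm = c(1, 2.3), target_h_nm = c(1.48, 3.4)),
    cluster_multiplicity_mean = 0.6, radial_sigma_nm = 1.0
  )
  g <- quantity_grid(tab, p_grid = numeric(0), k_values = 2)
  lam <- g$let_keV_per_um / 30
  keep <- 1 - exp(-(g$target_d_nm / 2)^2 / 2)
  expect_equal(g$m1, lam * g$target_h_nm * 1.6 * keep, tolerance = 1e-6)
  # simulated spectra respect the core ordering and thinning identities
  x <- collect_icsds(tab)$icsd[[1]]
  expect_lte(r2(x, 0.5), fk(x, 2))
  expect_lt(abs(fk(thin_icsd(x, 0.5), 2) - r2(x, 0.5)), 1e-10)
})

test_that("monte carlo ICSD mean converges to the analytic mean in 1/sqrt(n)", {
  geom <- target_geometry(2.3, 3.4)
  lam <- 1.5; m <- 0.6
  truth <- lam * 3.4 * (1 + m)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    x <- simulate_icsd(track_params(lam, m, 0, n_histories = n, seed = 33), geom)
    abs(m1(x) - truth)
  }, numeric(1))
  # 3-sigma band for the compound-Poisson mean at each n
  se <- sqrt(lam * 3.4 * (1 + m) * (1 + 2 * m) / c(1e3, 1e4, 1e5))
  expect_true(all(errs < 3 * se))
})

test_that("synthetic survival records embed the exact cross-section identity", {
  grid <- small_test_grid(p_grid = c(0.2, 0.35, 1))
  spec <- synth_study_spec(true_p = 0.35, true_K = 57, n_records = 40,
                           sigma_log = 0, seed = 13)
  recs <- generate_survival_dataset(spec, grid)
  expect_equal(nrow(recs), 40)
  # construction identity: Eq-style cross section reproduces K * R2 exactly
  sig <- inactivation_cross_section(recs$alpha, recs$beta, recs$let_keV_per_um)
  expect_lt(max(abs(sig - 57 * recs$r2_true)), 1e-9)
  expect_lt(max(abs(sig - recs$sigma_um2)), 1e-9)
  # alpha/beta policy honoured
  expect_equal(recs$alpha / recs$beta, rep(5, 40), tolerance = 1e-9)
  # determinism given the seed
  recs2 <- generate_survival_dataset(spec, grid)
  expect_equal(as.data.frame(recs2), as.data.frame(recs), tolerance = 1e-15)
  # noisy records still satisfy the identity against their own sigma
  spec_n <- synth_study_spec(true_p = 0.35, n_records = 20, sigma_log = 0.3, seed = 14)
  noisy <- generate_survival_dataset(spec_n, grid)
  sig_n <- inactivation_cross_section(noisy$alpha, noisy$beta, noisy$let_keV_per_um)
  expect_lt(max(abs(sig_n - noisy$sigma_um2)), 1e-9)
  expect_gt(stats::sd(log(noisy$sigma_um2 / (57 * noisy$r2_true))), 0.1)
  expect_error(synth_study_spec(n_records = 0), "n_records")
})

test_that("fixed-beta policy floors infeasible records and logs the adjustment", {
  grid <- small_test_grid(p_grid = c(0.35, 1))
  spec <- synth_study_spec(true_p = 0.35, n_records = 30, sigma_log = 0,
                           beta_policy = list(type = "fixed", value = 0.3), seed = 15)
  msgs <- capture.output(recs <- generate_survival_dataset(spec, grid),
                         type = "message")
  if (any(recs$beta_floored)) {
    expect_true(any(grepl("beta floored", msgs)))
    expect_true(all(recs$beta[recs$beta_floored] == 0))
  }
  sig <- inactivation_cross_section(recs$alpha, recs$beta, recs$let_keV_per_um)
  expect_lt(max(abs(sig - recs$sigma_um2)), 1e-9)
})
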