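test_that("modified chi-square is the plain sum of squared differences", {
  expect_equal(modified_chi2(tibble::tibble(sigma = 57 * 0.4, r2 = 0.4), K = 57), 0)
  expect_equal(modified_chi2(tibble::tibble(sigma = c(2, 4), r2 = c(1, 1)), K = 3), 2)
  expect_error(modified_chi2(tibble::tibble(sigma = numeric(0), r2 = numeric(0)), 1),
               "empty")
  # convex parabola in K with vertex at sum(sigma r) / sum(r^2)
  set.seed(21)
  d <- tibble::tibble(sigma = runif(30, 1, 60), r2 = runif(30, 0.01, 1))
  ks <- seq(0.1, 200, by = 0.05)
  chi <- vapply(ks, function(k) modified_chi2(d, k), numeric(1))
  expect_equal(ks[which.min(chi)], sum(d$sigma * d$r2) / sum(d$r2^2), tolerance = 0.05)
})

test_that("optimal K: closed form, grid agreement, homogeneity", {
  d <- tibble::tibble(sigma = 57 * c(0.1, 0.5, 0.9), r2 = c(0.1, 0.5, 0.9))
  expect_equal(optimal_K(d), 57)
  expect_equal(optimal_K(tibble::tibble(sigma = c(2, 4), r2 = c(1, 1))), 3)
  set.seed(22)
  d2 <- tibble::tibble(sigma = runif(40, 1, 80), r2 = runif(40, 0.05, 1))
  expect_lte(abs(optimal_K(d2) - optimal_K(d2, mode = "grid")), 1)
  expect_equal(optimal_K(dplyr::mutate(d2, sigma = 3 * sigma)), 3 * optimal_K(d2))
  expect_error(optimal_K(tibble::tibble(sigma = 1, r2 = 0)), "unidentifiable")
})

test_that("coefficient of determination matches hand computations", {
  expect_equal(coefficient_of_determination(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(coefficient_of_determination(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(coefficient_of_determination(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(coefficient_of_determination(c(1, 1), c(1, 2)), "zero variance")
  expect_error(coefficient_of_determination(1, 1), "at least two")
})

test_that("grid_fit recovers a noise-free ground truth and normalizes the surface", {
  grid <- small_test_grid(p_grid = seq(0.2, 1, by = 0.05))
  spec <- synth_study_spec(true_p = 0.4, true_K = 57, n_records = 30,
                           sigma_log = 0, seed = 5)
  recs <- generate_survival_dataset(spec, grid)
  fit <- grid_fit(recs, grid)
  expect_s3_class(fit, "icsd_fit")
  expect_equal(fit$best$p, 0.4)
  expect_lt(abs(fit$best$K_um2 - 57) / 57, 0.01)
  expect_equal(fit$best$target_d_nm, 2.3)
  expect_equal(max(fit$surface$chi2_norm), 1)
  expect_equal(min(fit$surface$chi2), fit$best$chi2)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # residuals vanish at the exact solution
  expect_lt(max(abs(fit$residuals$residual_um2)), 1e-8)
})

test_that("grid_fit excludes uninterpolable records with reason codes", {
  grid <- small_test_grid()
  spec <- synth_study_spec(true_p = 0.4, n_records = 10, sigma_log = 0, seed = 2)
  recs <- generate_survival_dataset(spec, grid)
  recs$energy_MeV_per_u[1] <- 1e5               # outside the grid span
  recs$particle[2] <- "56Fe"                    # not tabulated
  expect_message(fit <- grid_fit(recs, grid), "excluded 2 of 10")
  expect_setequal(fit$excluded$reason, c("energy_out_of_span", "particle_not_in_grid"))
  expect_equal(fit$n_used, 8)
  recs_bad <- recs
  recs_bad$particle <- "56Fe"
  expect_error(suppressMessages(grid_fit(recs_bad, grid)), "all records excluded")
})

test_that("k grid mode and closed form agree within one grid step", {
  grid <- small_test_grid()
  spec <- synth_study_spec(true_p = 0.4, n_records = 25, sigma_log = 0.1, seed = 9)
  recs <- generate_survival_dataset(spec, grid)
  f1 <- grid_fit(recs, grid, k_mode = "closed_form")
  f2 <- grid_fit(recs, grid, k_mode = "grid")
  expect_lte(abs(f1$best$K_um2 - f2$best$K_um2), 1)
  expect_equal(f1$best$p, f2$best$p)
})

test_that("broom methods and the heatmap work on a fit", {
  grid <- small_test_grid()
  spec <- synth_study_spec(true_p = 0.4, n_records = 15, sigma_log = 0, seed = 4)
  fit <- grid_fit(generate_survival_dataset(spec, grid), grid)
  td <- tidy(fit)
  expect_equal(td$term, c("p", "target_d_nm", "target_h_nm", "K_um2"))
  gl <- glance(fit)
  expect_equal(gl$n_records, 15)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "best: p")
})

test_that("quality curves expose ordered Fk columns and the R2/M1 ratio", {
  grid <- small_test_grid() |> dplyr::filter(particle == "11B")
  qc <- quality_curves(grid, p = 0.35)
  expect_true(all(c("energy_MeV_per_u", "let_keV_per_um", "m1", "r2", "r2_over_m1") %in% names(qc)))
  fks <- as.matrix(qc[, sprintf("f%d", 2:7)])
  expect_true(all(diff(t(fks)) <= 1e-12))       # F2 >= F3 >= ... >= F7 row-wise
  expect_equal(qc$r2_over_m1, qc$r2 / qc$m1)
  # at p = 1 the r2 column is F2
  qc1 <- quality_curves(grid, p = 1)
  expect_equal(qc1$r2, qc1$f2, tolerance = 1e-12)
  expect_s3_class(plot_quality_curves(qc), "ggplot")
  expect_error(quality_curves(grid, p = 0.123), "not tabulated")
})
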