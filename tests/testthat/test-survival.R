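test_that("dose_at_survival solves the LQ iso-effect equation", {
  expect_equal(dose_at_survival(1, 0, 0.05), -log(0.05), tolerance = 1e-12)
  # quadratic-formula oracle, frozen from numeric root finding
  expect_equal(dose_at_survival(0.2, 0.05, 0.05), 5.994664, tolerance = 1e-6)
  expect_equal(dose_at_survival(0.2, 0.05, 0.05), numeric_dose(0.2, 0.05, 0.05),
               tolerance = 1e-10)
  # defining identity, relative residual < 1e-10
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 0.05, 2); b <- runif(1, 0, 0.3); s <- runif(1, 0.01, 0.9)
    d <- dose_at_survival(a, b, s)
    expect_lt(abs(a * d + b * d^2 + log(s)) / abs(log(s)), 1e-10)
  }
  expect_error(dose_at_survival(0, 0, 0.05), "no positive root")
  expect_error(dose_at_survival(1, 0, 1.5), "survival")
})

test_that("negative-beta correction preserves the iso-survival dose and lowers alpha", {
  unchanged <- correct_negative_beta(1.0, 0.02)
  expect_equal(unchanged$alpha, 1.0)
  expect_equal(unchanged$beta, 0.02)
  expect_false(unchanged$corrected)

  # oracle: root-find the original dose, then alpha' = -ln(S) / D
  corr <- correct_negative_beta(1.0, -0.05, survival_level = 0.05)
  d0 <- numeric_dose(1.0, -0.05, 0.05)
  expect_equal(corr$alpha, -log(0.05) / d0, tolerance = 1e-9)
  expect_equal(corr$alpha, 0.8166, tolerance = 1e-4)
  expect_equal(corr$beta, 0)

  set.seed(8)
  for (i in 1:30) {
    # draw pairs whose curve does reach 5% survival: alpha^2 > -4 beta ln(S)
    b <- -runif(1, 0.001, 0.05)
    a <- runif(1, 1.1 * sqrt(-4 * b * -log(0.05)), 2.5)
    cc <- correct_negative_beta(a, b)
    expect_true(cc$valid)
    expect_lt(cc$alpha, a)  # always adjusted downward
    # dose at the working level is preserved
    d_orig <- numeric_dose(a, b, 0.05)
    d_corr <- dose_at_survival(cc$alpha, 0, 0.05)
    expect_lt(abs(d_orig - d_corr), 1e-9)
  }
  # curve never reaching the survival level is flagged invalid
  steep <- correct_negative_beta(0.1, -0.5)
  expect_false(steep$valid)
})

test_that("RBE is a ratio of iso-survival doses with graceful skipping", {
  same <- rbe_at_survival(tibble::tibble(alpha = 0.5, beta = 0.03,
                                         alpha_ref = 0.5, beta_ref = 0.03))
  expect_equal(same$rbe, 1)
  tbl <- rbe_at_survival(tibble::tibble(alpha = 1, beta = 0,
                                        alpha_ref = 0.2, beta_ref = 0.02))
  expect_equal(tbl$rbe, numeric_dose(0.2, 0.02, 0.05) / (-log(0.05) / 1),
               tolerance = 1e-9)
  expect_equal(tbl$rbe, 2.744, tolerance = 1e-3)
  # doubling the ion alpha (beta = 0) doubles RBE
  dbl <- rbe_at_survival(tibble::tibble(alpha = 2, beta = 0,
                                        alpha_ref = 0.2, beta_ref = 0.02))
  expect_equal(dbl$rbe, 2 * tbl$rbe, tolerance = 1e-12)
  # reciprocity: swapping sides inverts RBE
  swp <- rbe_at_survival(tibble::tibble(alpha = 0.2, beta = 0.02,
                                        alpha_ref = 1, beta_ref = 0))
  expect_equal(swp$rbe, 1 / tbl$rbe, tolerance = 1e-12)
  # missing reference: NA result plus reason-coded exclusion
  expect_message(
    mis <- rbe_at_survival(tibble::tibble(alpha = 1, beta = 0,
                                          alpha_ref = NA_real_, beta_ref = NA_real_)),
    "skipped")
  expect_true(is.na(mis$rbe))
  expect_equal(attr(mis, "exclusions")$reason, "missing_reference")
})

test_that("inactivation cross section matches its closed forms and the slope oracle", {
  expect_equal(inactivation_cross_section(1.25, 0, 100), 0.1602 * 100 * 1.25)
  expect_equal(inactivation_cross_section(1, 0.05, 100),
               0.1602 * 100 * sqrt(1 + 4 * 0.05 * (-log(0.05))), tolerance = 1e-12)
  expect_equal(inactivation_cross_section(1, 0.05, 100), 20.26, tolerance = 1e-3)
  expect_gte(inactivation_cross_section(1, 0.05, 100),
             inactivation_cross_section(1, 0, 100))
  expect_error(inactivation_cross_section(1, 0, -5), "positive")
  # sqrt form equals the local log-survival slope at D_S: (k/rho) LET (a + 2 b D)
  set.seed(9)
  for (i in 1:30) {
    a <- runif(1, 0.1, 2); b <- runif(1, 0, 0.2); let <- runif(1, 5, 500)
    cst <- lq_constants()
    d <- dose_at_survival(a, b, cst$survival_level)
    slope_form <- cst$dose_fluence_constant * let * (a + 2 * b * d)
    expect_lt(abs(inactivation_cross_section(a, b, let, cst) - slope_form), 1e-9)
  }
  # density scales the cross section inversely
  half <- lq_constants(rho_g_per_cm3 = 2)
  expect_equal(inactivation_cross_section(1, 0, 100, half),
               inactivation_cross_section(1, 0, 100) / 2)
})

test_that("survival tables parse, categorize and correct records", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_survival_fixture(f, list(
    c("V79", "1H", 1, 1, 5, 8, 0.5, 0.05, 0.2, 0.02, "exp1"),
    c("V79", "2H", 1, 2, 5, 8, 0.6, -0.01, 0.2, 0.02, "exp2"),   # corrected
    c("V79", "4He", 2, 4, 2, 80, 1.2, 0.0, "", "", "exp3"),      # no reference
    c("V79", "12C", 6, 12, 10, 170, 1.5, 0.1, 0.2, 0.02, "exp4")
  ))
  tbl <- read_survival_table(f)
  expect_equal(nrow(tbl), 4)
  expect_equal(tbl$category, c("Hydrogen", "Hydrogen", "Helium", "Heavy"))
  expect_true(tbl$beta_corrected[2])
  expect_equal(tbl$beta[2], 0)
  expect_lt(tbl$alpha[2], 0.6)
  expect_true(is.na(tbl$alpha_ref[3]))

  # empty file: empty tibble plus warning
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_survival_fixture(f2, list())
  expect_warning(empty <- read_survival_table(f2), "empty")
  expect_equal(nrow(empty), 0)

  # missing mandatory column is named
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("cell_line,ion_symbol\nV79,1H", f3)
  expect_error(read_survival_table(f3), "alpha_Gy-1")
})
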