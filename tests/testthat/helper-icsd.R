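# shared fixtures built in code

random_icsd <- function(nu_max = sample(3:25, 1)) {
  w <- stats::rexp(nu_max + 1)^2
  icsd(w / sum(w))
}

# brute-force binomial double sum: P(at least 2 lesions | nu ionizations)
brute_r2_weight <- function(nu, p) {
  if (nu < 2) return(0)
  k <- 2:nu
  sum(choose(nu, k) * p^k * (1 - p)^(nu - k))
}

# independent iso-survival dose: root-find alpha*D + beta*D^2 + log(S) = 0;
# for beta < 0 the first crossing lies before the parabola's vertex
numeric_dose <- function(alpha, beta, survival) {
  f <- function(d) alpha * d + beta * d^2 + log(survival)
  upper <- if (beta < 0) -alpha / (2 * beta) else 1e4
  stats::uniroot(f, c(1e-12, upper), tol = 1e-13)$root
}

# small deterministic quantity grid reused across fit tests
small_test_grid <- function(p_grid = seq(0.2, 1, by = 0.05),
                            geometries = tibble::tibble(target_d_nm = 2.3, target_h_nm = 3.4)) {
  tab <- synthetic_icsd_table(
    particles = default_particles()[c(1, 4, 6), ],
    energies = 10^seq(log10(0.5), 2.5, length.out = 8),
    geometries = geometries
  )
  quantity_grid(tab, p_grid = p_grid)
}

# one-distribution point-mass ICSD table in the long CSV dialect
point_mass_table <- function(nu = 3) {
  nu_at <- nu
  tibble::tibble(
    particle = "4He", energy_MeV_per_u = 10, let_keV_per_um = 25,
    target_d_nm = 2.3, target_h_nm = 3.4,
    nu = 0:nu_at, probability = c(rep(0, nu_at), 1)
  )
}

# survival-table CSV fixture with the documented dash-named columns
write_survival_fixture <- function(path, rows) {
  header <- c("cell_line", "ion_symbol", "Z", "A", "energy_MeV_per_u",
              "let_keV_per_um", "alpha_Gy-1", "beta_Gy-2",
              "alpha_ref_Gy-1", "beta_ref_Gy-2", "source_label")
  lines <- c(paste(header, collapse = ","),
             vapply(rows, function(r) paste(r, collapse = ","), character(1)))
  writeLines(lines, path)
  path
}
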