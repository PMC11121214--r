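#' Toy track-segment model parameters
#'
#' Parameters of the compound-Poisson track model used by [simulate_icsd()]:
#' primary ionizations along the cylinder axis as a 1-D Poisson process with
#' rate `mean_ionizations_per_nm` (proportional to LET divided by a nominal
#' mean energy per ionization), each primary spawning `1 + Geometric`
#' secondary ionizations with mean `cluster_multiplicity_mean`, each ionization
#' displaced laterally by an isotropic 2-D Gaussian of standard deviation
#' `radial_sigma_nm` and counted only if it lands inside the cylinder.
#'
#' @param mean_ionizations_per_nm Primary-ionization rate along the axis, 1/nm.
#' @param cluster_multiplicity_mean Mean number of extra ionizations per
#'   primary (0 gives a pure Poisson ICSD).
#' @param radial_sigma_nm Lateral displacement scale of ionizations, nm.
#' @param n_histories Number of simulated primary-particle traversals.
#' @param seed Optional integer seed; when given, results are reproducible and
#'   recorded in the ICSD metadata.
#' @return A list of class `track_params`.
#' @export
track_params <- function(mean_ionizations_per_nm, cluster_multiplicity_mean = 0,
                         radial_sigma_nm = 0, n_histories = 100000L, seed = NULL) {
  stopifnot(mean_ionizations_per_nm > 0, cluster_multiplicity_mean >= 0,
            radial_sigma_nm >= 0, n_histories >= 1)
  structure(list(mean_ionizations_per_nm = mean_ionizations_per_nm,
                 cluster_multiplicity_mean = cluster_multiplicity_mean,
                 radial_sigma_nm = radial_sigma_nm,
                 n_histories = as.integer(n_histories), seed = seed),
            class = "track_params")
}

#' Simulate an ICSD with the toy track-segment Monte Carlo
#'
#' One history is one primary traversal along the axis chord of the cylinder
#' (pencil beam). The number of in-cylinder ionizations per history is
#' tallied into an ICSD. With zero multiplicity and zero radial spread the
#' result is exactly Poisson with mean `rate * height`; positive multiplicity
#' produces the overdispersion characteristic of real track structure
#' (variance-to-mean ratio `1 + 2 * multiplicity`); positive radial spread
#' thins counts by the in-cylinder probability
#' `1 - exp(-(d/2)^2 / (2 * sigma^2))`.
#'
#' This generator stands in for full track-structure transport: it reproduces
#' the statistical anatomy of nanodosimetric spectra (Poisson primaries,
#' clustered secondaries, geometric escape) without claiming physical
#' fidelity to any transport code.
#'
#' @param params A [track_params()] object.
#' @param geometry A [target_geometry()].
#' @return An [icsd] with metadata recording the parameters and seed.
#' @examples
#' x <- simulate_icsd(track_params(1, n_histories = 2000, seed = 7), target_geometry(2.3, 3.4))
#' m1(x)  # close to 1 * 3.4
#' @export
simulate_icsd <- function(params, geometry) {
  stopifnot(inherits(params, "track_params"), inherits(geometry, "target_geometry"))
  run <- function() {
    n_hist <- params$n_histories
    n_prim <- stats::rpois(n_hist, params$mean_ionizations_per_nm * geometry$height_nm)
    total_prim <- sum(n_prim)
    if (total_prim == 0) {
      counts <- c(n_hist)
    } else {
      hist_id <- rep.int(seq_len(n_hist), n_prim)
      m <- params$cluster_multiplicity_mean
      n_ion <- if (m > 0) 1L + stats::rgeom(total_prim, 1 / (1 + m)) else rep(1L, total_prim)
      ion_hist <- rep.int(hist_id, n_ion)
      if (params$radial_sigma_nm > 0) {
        s <- params$radial_sigma_nm
        dx <- stats::rnorm(length(ion_hist), 0, s)
        dy <- stats::rnorm(length(ion_hist), 0, s)
        ion_hist <- ion_hist[dx^2 + dy^2 <= (geometry$diameter_nm / 2)^2]
      }
      per_hist <- tabulate(ion_hist, nbins = n_hist)
      counts <- tabulate(per_hist + 1L, nbins = max(per_hist) + 1L)
    }
    counts
  }
  counts <- if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
  normalize_icsd(counts, meta = list(
    generator = "toy_track_mc", n_histories = params$n_histories, seed = params$seed,
    mean_ionizations_per_nm = params$mean_ionizations_per_nm,
    cluster_multiplicity_mean = params$cluster_multiplicity_mean,
    radial_sigma_nm = params$radial_sigma_nm,
    target = format(geometry)
  ))
}

#' Toy LET model
#'
#' A Bethe-like power law `LET = k1 * Z^2 / E^exponent` capped harmonically by
#' a Z-dependent saturation value `cap_scale * Z^cap_exponent`, so LET rises
#' as energy falls and flattens at the stopping-power maximum. Purely a
#' convention for generating internally consistent synthetic radiation
#' qualities; no agreement with tabulated stopping powers is claimed.
#'
#' @param z Atomic number(s).
#' @param energy_MeV_per_u Energy per nucleon, MeV/u.
#' @param k1,exponent Power-law scale (keV/um at 1 MeV/u for protons) and
#'   energy exponent.
#' @param cap_scale,cap_exponent Saturation LET scale and its Z dependence.
#' @return LET in keV/um.
#' @examples
#' toy_let(1, 1)    # ~ proton at 1 MeV
#' toy_let(6, 10)   # carbon at 10 MeV/u
#' @export
toy_let <- function(z, energy_MeV_per_u, k1 = 27, exponent = 0.78,
                    cap_scale = 90, cap_exponent = 1.3) {
  if (any(energy_MeV_per_u <= 0)) stop("energy must be positive")
  bethe <- k1 * z^2 / energy_MeV_per_u^exponent
  cap <- cap_scale * z^cap_exponent
  1 / (1 / bethe + 1 / cap)
}

#' Default simulated projectile set
#'
#' @return A tibble of (particle, z, a): 1H, 4He, 7Li, 11B, 12C, 14N, 16O,
#'   28Si — the ion set covering hydrogen through silicon.
#' @export
default_particles <- function() {
  tibble::tibble(
    particle = c("1H", "4He", "7Li", "11B", "12C", "14N", "16O", "28Si"),
    z = c(1L, 2L, 3L, 5L, 6L, 7L, 8L, 14L),
    a = c(1L, 4L, 7L, 11L, 12L, 14L, 16L, 28L)
  )
}

default_geometries <- function() {
  d <- c(1.0, 1.5, 2.0, 2.3)
  tibble::tibble(target_d_nm = d, target_h_nm = round(1.48 * d, 2))
}

# in-cylinder probability for one laterally displaced ionization
radial_keep_prob <- function(diameter_nm, radial_sigma_nm) {
  if (radial_sigma_nm == 0) return(1)
  1 - exp(-(diameter_nm / 2)^2 / (2 * radial_sigma_nm^2))
}

#' Synthetic ICSD table over particles, energies and geometries
#'
#' Builds the long-form ICSD table (the same dialect [read_icsd_table()]
#' reads) for a family of radiation qualities. LET comes from [toy_let()];
#' the primary-ionization rate is `LET / mean_energy_per_ionization_eV`
#' (1 keV/um equals 1 eV/nm). The `"analytic"` method evaluates the track
#' model's exact compound-Poisson distribution (secondary clusters thinned by
#' the in-cylinder probability, then compounded over Poisson primaries) and is
#' deterministic; `"montecarlo"` runs [simulate_icsd()] per quality.
#'
#' @param particles Tibble with columns `particle`, `z` (and optionally `a`).
#' @param energies Energies per nucleon, MeV/u (default: 40 points log-spaced
#'   over 0.2-1000 MeV/u).
#' @param geometries Tibble with columns `target_d_nm`, `target_h_nm`
#'   (default: diameters 1-2.3 nm with height/diameter = 1.48).
#' @param mean_energy_per_ionization_eV Nominal energy per ionization used to
#'   convert LET to the primary rate (toy convention, default 30 eV).
#' @param cluster_multiplicity_mean,radial_sigma_nm Track-model parameters,
#'   see [track_params()].
#' @param method `"analytic"` (exact, default) or `"montecarlo"`.
#' @param n_histories Histories per quality for the Monte Carlo method.
#' @param seed Base seed for the Monte Carlo method (one derived seed per
#'   quality).
#' @return A long-form ICSD tibble.
#' @export
synthetic_icsd_table <- function(particles = default_particles(),
                                 energies = 10^seq(log10(0.2), 3, length.out = 40),
                                 geometries = default_geometries(),
                                 mean_energy_per_ionization_eV = 30,
                                 cluster_multiplicity_mean = 0.6,
                                 radial_sigma_nm = 1.0,
                                 method = c("analytic", "montecarlo"),
                                 n_histories = 100000L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("particle", "z") %in% names(particles)),
            all(c("target_d_nm", "target_h_nm") %in% names(geometries)))
  if (nrow(geometries) == 0) stop("at least one geometry is required")
  cases <- tidyr::crossing(particles, tibble::tibble(energy_MeV_per_u = energies), geometries)
  cases$let_keV_per_um <- toy_let(cases$z, cases$energy_MeV_per_u)

  one <- function(i) {
    lam <- cases$let_keV_per_um[i] / mean_energy_per_ionization_eV  # per nm
    geom <- target_geometry(cases$target_d_nm[i], cases$target_h_nm[i])
    if (method == "analytic") {
      x <- analytic_track_icsd(lam, geom, cluster_multiplicity_mean, radial_sigma_nm)
    } else {
      case_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
      x <- simulate_icsd(track_params(lam, cluster_multiplicity_mean, radial_sigma_nm,
                                      n_histories, seed = case_seed), geom)
    }
    tibble::tibble(
      particle = cases$particle[i],
      energy_MeV_per_u = cases$energy_MeV_per_u[i],
      let_keV_per_um = cases$let_keV_per_um[i],
      target_d_nm = cases$target_d_nm[i],
      target_h_nm = cases$target_h_nm[i],
      nu = 0:attr(x, "nu_max"),
      probability = icsd_probs(x)
    )
  }
  purrr::map_dfr(seq_len(nrow(cases)), one)
}

# exact ICSD of the track model: thin the per-primary cluster-size pmf by the
# in-cylinder probability, then compound over Poisson(lambda * h) primaries
analytic_track_icsd <- function(rate_per_nm, geometry, multiplicity_mean, radial_sigma_nm) {
  mu <- rate_per_nm * geometry$height_nm
  keep <- radial_keep_prob(geometry$diameter_nm, radial_sigma_nm)
  cl <- cluster_size_pmf(multiplicity_mean)  # sizes 1..L
  if (keep < 1) {
    sizes <- seq_along(cl)
    thinned <- vapply(0:max(sizes), function(m) sum(cl * stats::dbinom(m, sizes, keep)), numeric(1))
    # fold the zero-count mass into the Poisson: primaries yielding no counted
    # ionization are invisible
    p0 <- thinned[1]
    mu <- mu * (1 - p0)
    cl <- thinned[-1] / (1 - p0)
  }
  total_mean <- mu * sum(seq_along(cl) * cl)
  second_moment <- sum(seq_along(cl)^2 * cl)
  total_var <- mu * second_moment
  nu_max <- max(10L, ceiling(total_mean + 12 * sqrt(max(total_var, 1)) + 20))
  probs <- compound_poisson_pmf(mu, cl, nu_max)
  icsd(probs / sum(probs), meta = list(generator = "analytic_track",
                                       rate_per_nm = rate_per_nm,
                                       keep_prob = keep))
}

#' Specification of a synthetic survival study
#'
#' Ground-truth design for the closed-loop recovery experiment: survival
#' records are constructed so that the inactivation cross section satisfies
#' `sigma = true_K * R2(true_p; geometry)` exactly before noise, then
#' multiplicative lognormal noise is applied and the LQ parameters are solved
#' back from the noisy cross section.
#'
#' @param true_p,true_K Ground-truth lesion probability and scale (um^2).
#' @param geometry [target_geometry()] whose grid defines the truth.
#' @param n_records Number of survival records (the study scale of ~150
#'   monoenergetic V79 curves sets the default).
#' @param sigma_log Standard deviation of `log(noise)`; 0 gives exact records.
#' @param beta_policy Either `list(type = "ratio", value = r)` (fixed
#'   alpha/beta ratio in Gy; default 5 Gy, typical of V79 cells) or
#'   `list(type = "fixed", value = beta)`. Infeasible fixed betas are floored
#'   to 0 and flagged.
#' @param alpha_ref,beta_ref Reference-photon LQ parameters attached to every
#'   record.
#' @param max_let Records are drawn only up to this LET (keV/um).
#' @param survival_level Working survival level for the inversion.
#' @param seed Integer seed.
#' @return A list of class `synth_study_spec`.
#' @export
synth_study_spec <- function(true_p = 0.35, true_K = 57,
                             geometry = target_geometry(2.3, 3.4),
                             n_records = 150L, sigma_log = 0.2,
                             beta_policy = list(type = "ratio", value = 5),
                             alpha_ref = 0.184, beta_ref = 0.02,
                             max_let = 528, survival_level = 0.05, seed = 1L) {
  stopifnot(true_p >= 0, true_p <= 1, true_K > 0, n_records >= 1, sigma_log >= 0,
            beta_policy$type %in% c("ratio", "fixed"),
            survival_level > 0, survival_level < 1)
  structure(list(true_p = true_p, true_K = true_K, geometry = geometry,
                 n_records = as.integer(n_records), sigma_log = sigma_log,
                 beta_policy = beta_policy, alpha_ref = alpha_ref,
                 beta_ref = beta_ref, max_let = max_let,
                 survival_level = survival_level, seed = as.integer(seed)),
            class = "synth_study_spec")
}

#' Generate a synthetic survival dataset with known ground truth
#'
#' Draws radiation qualities (particle uniformly among those in the grid,
#' energy log-uniform within the grid span, rejected above `max_let`),
#' computes the true `R2(true_p)` by energy interpolation at the spec's
#' geometry, sets `sigma = true_K * R2 * exp(rnorm(0, sigma_log))`, and solves
#' the cross-section relation backwards for `(alpha, beta)` under the beta
#' policy, so that recomputing [inactivation_cross_section()] from the stored
#' parameters reproduces the noisy `sigma` exactly.
#'
#' @param spec A [synth_study_spec()].
#' @param grid A [quantity_grid()] containing the spec's geometry and a
#'   tabulated `R2` column for `true_p`.
#' @param constants [lq_constants()] (its survival level is overridden by the
#'   spec's).
#' @return A tibble of survival records (tidy columns as in
#'   [read_survival_table()]) plus `sigma_um2` and `r2_true`; attribute
#'   `truth` stores the spec.
#' @export
generate_survival_dataset <- function(spec, grid, constants = lq_constants()) {
  stopifnot(inherits(spec, "synth_study_spec"))
  constants$survival_level <- spec$survival_level
  g <- spec$geometry
  sub <- grid[abs(grid$target_d_nm - g$diameter_nm) < 1e-9 &
                abs(grid$target_h_nm - g$height_nm) < 1e-9, ]
  if (nrow(sub) == 0) stop("spec geometry not present in grid")
  col <- r2_col_name(spec$true_p)
  if (!col %in% names(sub)) stop("true_p not tabulated in grid (no column ", col, ")")
  parts <- default_particles()
  parts <- parts[parts$particle %in% unique(sub$particle), ]
  if (nrow(parts) == 0) stop("no known particles in grid")

  withr::with_seed(spec$seed, {
    recs <- vector("list", spec$n_records)
    loge <- -log(spec$survival_level)
    for (i in seq_len(spec$n_records)) {
      # rejection-sample a quality below the LET ceiling
      for (try in 1:1000) {
        j <- sample.int(nrow(parts), 1)
        psub <- sub[sub$particle == parts$particle[j], ]
        e_rng <- range(psub$energy_MeV_per_u)
        e <- 10^stats::runif(1, log10(e_rng[1]), log10(e_rng[2]))
        let <- toy_let(parts$z[j], e)
        if (let <= spec$max_let) break
      }
      r2_true <- interpolate_quantity(psub, e, col)
      noise <- if (spec$sigma_log > 0) exp(stats::rnorm(1, 0, spec$sigma_log)) else 1
      sigma <- spec$true_K * r2_true * noise
      s_eff <- sigma * constants$rho_g_per_cm3 / (constants$dose_fluence_constant * let)
      if (spec$beta_policy$type == "ratio") {
        b <- 4 * loge / spec$beta_policy$value
        alpha <- (-b + sqrt(b^2 + 4 * s_eff^2)) / 2
        beta <- alpha / spec$beta_policy$value
        beta_floored <- FALSE
      } else {
        beta <- spec$beta_policy$value
        if (s_eff^2 < 4 * beta * loge) {  # infeasible: floor beta
          beta <- 0
          beta_floored <- TRUE
        } else beta_floored <- FALSE
        alpha <- sqrt(s_eff^2 - 4 * beta * loge)
      }
      recs[[i]] <- tibble::tibble(
        cell_line = "V79-synthetic", ion_symbol = parts$particle[j],
        particle = parts$particle[j], z = parts$z[j], a = parts$a[j],
        energy_MeV_per_u = e, let_keV_per_um = let,
        alpha = alpha, beta = beta,
        alpha_ref = spec$alpha_ref, beta_ref = spec$beta_ref,
        source_label = sprintf("synthetic seed=%d rec=%d", spec$seed, i),
        sigma_um2 = sigma, r2_true = r2_true, beta_floored = beta_floored
      )
    }
    out <- dplyr::bind_rows(recs)
    n_floor <- sum(out$beta_floored)
    if (n_floor > 0) {
      rlang::inform(sprintf("generate_survival_dataset: beta floored to 0 for %d record(s)", n_floor))
    }
    attr(out, "truth") <- spec
    out
  })
}
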