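#' Ionization cluster size distribution (ICSD)
#'
#' An ICSD is the discrete probability distribution `P_nu` of the number of
#' ionizations `nu` (the cluster size, including `nu = 0`) produced in a
#' nanometre-scale target by a single primary-particle traversal. It is the
#' central object of all nanodosimetric statistics in this package: the mean
#' cluster size [m1()], the cumulative probabilities [fk()], the binomially
#' weighted lesion statistic [r2()], and binomial thinning [thin_icsd()] all
#' consume it.
#'
#' The distribution is stored dense from `nu = 0` to `nu_max = length(probs) - 1`;
#' no tail beyond `nu_max` is ever extrapolated. Probabilities must be
#' non-negative and close to 1: sums within `1e-6` of 1 are silently
#' renormalized (counts-to-probability rounding), anything further off is an
#' error.
#'
#' @param probs Numeric vector of probabilities for cluster sizes
#'   `0, 1, ..., length(probs) - 1`.
#' @param meta Optional named list of provenance (radiation quality, target
#'   geometry, number of simulated histories, seed, ...).
#' @return An object of class `icsd`: the probability vector with attributes
#'   `meta` and `nu_max`.
#' @examples
#' x <- icsd(c(0.5, 0.3, 0.2))
#' m1(x)
#' @seealso [normalize_icsd()] to build one from raw counts,
#'   [parametric_icsd()] for analytic families, [simulate_icsd()] for the toy
#'   track-structure Monte Carlo.
#' @export
icsd <- function(probs, meta = list()) {
  probs <- as.numeric(probs)
  if (length(probs) == 0) stop("empty spectrum: no probabilities supplied")
  if (anyNA(probs)) stop("ICSD probabilities must not contain NA")
  if (any(probs < 0)) stop("ICSD probabilities must be non-negative")
  s <- sum(probs)
  if (s == 0) stop("empty spectrum: all probabilities are zero")
  if (abs(s - 1) > 1e-6) {
    stop(sprintf("ICSD probabilities sum to %.8g, further than 1e-6 from 1; normalize counts with normalize_icsd()", s))
  }
  if (abs(s - 1) > 1e-9) probs <- probs / s
  structure(probs, meta = meta, nu_max = length(probs) - 1L, class = "icsd")
}

#' Build an ICSD from raw counts
#'
#' Measured or simulated spectra arrive as event counts per cluster size;
#' this converts them to probabilities summing to 1.
#'
#' @param raw_counts Numeric vector of non-negative counts for cluster sizes
#'   `0, 1, ..., length(raw_counts) - 1`.
#' @inheritParams icsd
#' @return An [icsd] object.
#' @examples
#' normalize_icsd(c(1, 1, 2))
#' @export
normalize_icsd <- function(raw_counts, meta = list()) {
  raw_counts <- as.numeric(raw_counts)
  if (length(raw_counts) == 0 || anyNA(raw_counts)) {
    stop("counts must be a non-empty numeric vector without NA")
  }
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  s <- sum(raw_counts)
  if (s == 0) stop("empty spectrum: all counts are zero")
  icsd(raw_counts / s, meta = meta)
}

#' @export
print.icsd <- function(x, ...) {
  nu_max <- attr(x, "nu_max")
  cat(sprintf("<icsd> nu = 0..%d, M1 = %.4g, F2 = %.4g\n", nu_max, m1(x), fk(x, 2)))
  meta <- attr(x, "meta")
  if (length(meta)) {
    keys <- names(meta)[vapply(meta, function(v) is.atomic(v) && length(v) == 1, logical(1))]
    if (length(keys)) {
      cat("  meta:", paste(sprintf("%s=%s", keys, vapply(meta[keys], format, character(1))), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.icsd <- function(x, ...) {
  tibble::tibble(nu = 0:attr(x, "nu_max"), probability = as.numeric(unclass(x)))
}

icsd_probs <- function(x) {
  stopifnot(inherits(x, "icsd"))
  as.numeric(unclass(x))
}

#' Cylindrical target geometry
#'
#' The sensitive volume of the (real or simulated) nanodosimeter: a cylinder
#' of given diameter and height in nanometres, representing a short DNA
#' segment (roughly one helical turn for 2.3 x 3.4 nm).
#'
#' @param diameter_nm,height_nm Positive cylinder dimensions in nm.
#' @return An object of class `target_geometry`.
#' @examples
#' target_geometry(2.3, 3.4)
#' @export
target_geometry <- function(diameter_nm, height_nm) {
  stopifnot(is.numeric(diameter_nm), is.numeric(height_nm), length(diameter_nm) == 1, length(height_nm) == 1)
  if (!is.finite(diameter_nm) || diameter_nm <= 0) stop("diameter_nm must be > 0")
  if (!is.finite(height_nm) || height_nm <= 0) stop("height_nm must be > 0")
  structure(list(diameter_nm = diameter_nm, height_nm = height_nm), class = "target_geometry")
}

#' @export
format.target_geometry <- function(x, ...) {
  sprintf("%g x %g nm^2 (diameter x height)", x$diameter_nm, x$height_nm)
}

#' @export
print.target_geometry <- function(x, ...) {
  cat("<target_geometry>", format(x), "\n")
  invisible(x)
}

#' One-row tibble describing a radiation quality
#'
#' @param symbol Ion label, e.g. `"4He"`.
#' @param z,a Atomic and mass number (`z <= a`).
#' @param energy_MeV_per_u Kinetic energy per nucleon, MeV/u.
#' @param let_keV_per_um Linear energy transfer, keV/um (an input here; no
#'   stopping-power calculation is attempted).
#' @return A one-row tibble with the five columns above.
#' @examples
#' radiation_quality("4He", 2, 4, 10, 25)
#' @export
radiation_quality <- function(symbol, z, a, energy_MeV_per_u, let_keV_per_um) {
  stopifnot(is.character(symbol), length(symbol) == 1)
  z <- as.integer(z); a <- as.integer(a)
  if (z < 1 || a < 1 || z > a) stop("require 1 <= z <= a")
  if (!is.finite(energy_MeV_per_u) || energy_MeV_per_u <= 0) stop("energy_MeV_per_u must be > 0")
  if (!is.finite(let_keV_per_um) || let_keV_per_um <= 0) stop("let_keV_per_um must be > 0")
  tibble::tibble(
    particle = symbol, z = z, a = a,
    energy_MeV_per_u = energy_MeV_per_u, let_keV_per_um = let_keV_per_um
  )
}

#' Analytic ICSD families
#'
#' Exact, truncated-and-renormalized distributions used as fixtures and as the
#' deterministic backbone of the synthetic quantity grids:
#'
#' * `"poisson"`: cluster size is Poisson with mean `mean` — the track model
#'   with no secondary-electron clustering.
#' * `"compound_poisson"`: a Poisson(`mean_primaries`) number of primary
#'   ionizations, each spawning `1 + Geometric` secondaries with mean
#'   `multiplicity_mean` extra ionizations (a Neyman-A-like, overdispersed
#'   count). Mean cluster size is `mean_primaries * (1 + multiplicity_mean)`.
#' * `"point_mass"`: all mass at cluster size `nu`.
#'
#' @param family One of `"poisson"`, `"compound_poisson"`, `"point_mass"`.
#' @param mean Poisson mean (family `"poisson"`).
#' @param mean_primaries,multiplicity_mean Compound-Poisson parameters.
#' @param nu Support point (family `"point_mass"`).
#' @param nu_max Truncation point; chosen automatically (tail mass `< 1e-12`)
#'   when `NULL`. If the requested truncation discards mass `>= 1e-9` the
#'   result is renormalized and flagged in `meta$renormalized`.
#' @return An [icsd] object.
#' @examples
#' m1(parametric_icsd("poisson", mean = 3))
#' m1(parametric_icsd("compound_poisson", mean_primaries = 2, multiplicity_mean = 1.5))
#' @export
parametric_icsd <- function(family = c("poisson", "compound_poisson", "point_mass"),
                            mean = NULL, mean_primaries = NULL, multiplicity_mean = NULL,
                            nu = NULL, nu_max = NULL) {
  family <- match.arg(family)
  if (family == "point_mass") {
    stopifnot(!is.null(nu), nu >= 0, nu == round(nu))
    probs <- c(rep(0, nu), 1)
    return(icsd(probs, meta = list(family = family, nu = nu)))
  }
  if (family == "poisson") {
    stopifnot(!is.null(mean), mean >= 0)
    if (is.null(nu_max)) nu_max <- max(5L, stats::qpois(1 - 1e-13, mean) + 10L)
    probs <- stats::dpois(0:nu_max, mean)
  } else {
    stopifnot(!is.null(mean_primaries), mean_primaries >= 0,
              !is.null(multiplicity_mean), multiplicity_mean >= 0)
    mu <- mean_primaries
    m <- multiplicity_mean
    total_mean <- mu * (1 + m)
    total_var <- mu * (1 + m) * (1 + 2 * m)
    if (is.null(nu_max)) nu_max <- ceiling(total_mean + 12 * sqrt(max(total_var, 1)) + 20)
    probs <- compound_poisson_pmf(mu, cluster_size_pmf(m), nu_max)
  }
  tail_mass <- max(0, 1 - sum(probs))
  meta <- list(family = family, renormalized = tail_mass >= 1e-9, tail_mass = tail_mass)
  icsd(probs / sum(probs), meta = meta)
}

# pmf of one primary's cluster size 1 + Geometric(mean m), truncated where the
# tail falls below 1e-15
cluster_size_pmf <- function(multiplicity_mean) {
  if (multiplicity_mean == 0) return(1)
  prob <- 1 / (1 + multiplicity_mean)
  n <- max(3L, ceiling(stats::qgeom(1 - 1e-15, prob)) + 2L)
  pmf <- stats::dgeom(0:(n - 1L), prob)
  pmf / sum(pmf)
}

# Compound-Poisson pmf on 0..nu_max via the probability generating function
# evaluated on the DFT grid: exp(mu * (C(z) - 1)). Stable for large mu where a
# Panjer-style recursion starting from exp(-mu) would underflow. cluster_pmf
# is indexed from cluster size 1. Aliasing is negligible when nu_max is chosen
# so the true tail mass is tiny.
compound_poisson_pmf <- function(mu, cluster_pmf, nu_max) {
  n <- nu_max + 1L
  cvec <- numeric(n)
  idx <- seq_len(min(length(cluster_pmf), n - 1L))
  cvec[1L + idx] <- cluster_pmf[idx]
  chat <- stats::fft(cvec)
  pmf <- Re(stats::fft(exp(mu * (chat - 1)), inverse = TRUE)) / n
  pmf[pmf < 0] <- 0
  pmf
}
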