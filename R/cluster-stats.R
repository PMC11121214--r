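#' Mean ionization cluster size M1
#'
#' First moment of the ICSD, `sum(nu * P_nu)`, taken over all events including
#' `nu = 0` (a traversal with no ionization counts as an event of size zero).
#' M1 plays the role of a geometrically restricted LET: it counts ionizations
#' actually landing in the nanometric target.
#'
#' @param x An [icsd] object.
#' @return Mean cluster size (dimensionless), in `[0, nu_max]`.
#' @examples
#' m1(parametric_icsd("point_mass", nu = 3))
#' @export
m1 <- function(x) {
  p <- icsd_probs(x)
  sum((seq_along(p) - 1) * p)
}

#' Cumulative cluster-size probability Fk
#'
#' Probability of a cluster of size `k` or larger, `sum_{nu >= k} P_nu`. The
#' classical nanodosimetric radiation-quality parameter: `F2` is the
#' probability of at least the two ionizations minimally needed for a DNA
#' double-strand break. `F0 = 1` and `Fk` is non-increasing in `k`.
#'
#' @param x An [icsd] object.
#' @param k Integer threshold(s) `>= 0`; vectorized.
#' @return Numeric vector of cumulative probabilities, same length as `k`.
#' @examples
#' fk(icsd(c(0.5, 0.3, 0.2)), k = 0:3)
#' @export
fk <- function(x, k) {
  p <- icsd_probs(x)
  if (anyNA(k) || any(k < 0) || any(k != round(k))) stop("k must be non-negative integers")
  cum_tail <- rev(cumsum(rev(p)))  # cum_tail[j] = P(nu >= j - 1)
  vapply(as.integer(k), function(ki) {
    if (ki >= length(p)) 0 else cum_tail[ki + 1L]
  }, numeric(1))
}

#' Binomial lesion weight w(nu, p)
#'
#' Probability that a cluster of `nu` ionizations produces at least two
#' sub-lethal lesions when each ionization independently converts to a lesion
#' with probability `p`:
#' `w(nu, p) = 1 - (1 - p)^nu - nu * p * (1 - p)^(nu - 1)`.
#' This is the smooth weighting function that [r2()] applies to the ICSD in
#' place of the step weight (0 below `k`, 1 at or above) implicit in [fk()].
#' `w` is 0 at `nu` 0 and 1 (fewer than two ionizations cannot yield two
#' lesions), 1 in the large-`nu` or `p = 1` limit, and non-decreasing in both
#' arguments.
#'
#' @param nu Non-negative integer cluster size(s); vectorized.
#' @param p Lesion probability per ionization, in `[0, 1]`; vectorized
#'   (recycled against `nu`).
#' @return Weights in `[0, 1]`.
#' @examples
#' r2_weight(3, 0.35)
#' @export
r2_weight <- function(nu, p) {
  if (anyNA(nu) || any(nu < 0) || any(nu != round(nu))) stop("nu must be non-negative integers")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  n <- max(length(nu), length(p))
  nu <- rep_len(as.numeric(nu), n)
  p <- rep_len(as.numeric(p), n)
  w <- numeric(n)
  big <- nu >= 2 & p > 0
  one <- big & p == 1
  w[one] <- 1
  reg <- big & !one
  if (any(reg)) {
    # (1-p)^nu in log space: accurate deep into the p -> 1 regime
    lq <- log1p(-p[reg])
    w[reg] <- 1 - exp(nu[reg] * lq) - nu[reg] * p[reg] * exp((nu[reg] - 1) * lq)
  }
  pmin(pmax(w, 0), 1)
}

#' Binomially weighted damage statistic R2(p)
#'
#' The probability that a single particle traversal produces at least two
#' sub-lethal lesions in the target:
#' `R2(p) = sum_nu P_nu * w(nu, p)` with the binomial weight [r2_weight()].
#' Unlike the cumulative probability `Fk`, whose integer index forces a hard
#' step in the cluster-size weighting, `R2` varies continuously with the
#' per-ionization lesion probability `p`, and reduces exactly to `F2` at
#' `p = 1`.
#'
#' @param x An [icsd] object.
#' @param p Lesion probability (or vector of probabilities) in `[0, 1]`.
#' @return `R2(p)` for each requested `p`; always within `[0, F2]` and
#'   non-decreasing in `p`.
#' @examples
#' pois <- parametric_icsd("poisson", mean = 3)
#' r2(pois, p = c(0.35, 1))
#' fk(pois, 2)  # equals r2 at p = 1
#' @export
r2 <- function(x, p) {
  probs <- icsd_probs(x)
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]")
  nu <- seq_along(probs) - 1
  vapply(p, function(pp) sum(probs * r2_weight(nu, pp)), numeric(1))
}

#' Binomial thinning of an ICSD (detector-efficiency convolution)
#'
#' Each ionization in a cluster is independently registered with probability
#' `eta` (the ion counting efficiency of a nanodosimeter), giving the measured
#' distribution `Q_m = sum_{nu >= m} P_nu * C(nu, m) * eta^m * (1-eta)^(nu-m)`.
#' Thinning underlies the measurement equivalence for `R2`: computing `F2` on
#' a spectrum thinned with efficiency `eta = p` equals computing `R2(p)` on
#' the true spectrum, and the mean scales exactly as
#' `M1(thin(P, eta)) = eta * M1(P)`.
#'
#' @param x An [icsd] object.
#' @param eta Registration efficiency in `[0, 1]`.
#' @return The thinned [icsd] (same `nu_max`; the upper tail just carries
#'   zero mass).
#' @examples
#' p2 <- parametric_icsd("point_mass", nu = 2)
#' as_tibble(thin_icsd(p2, 0.5))
#' @export
thin_icsd <- function(x, eta) {
  probs <- icsd_probs(x)
  if (length(eta) != 1 || is.na(eta) || eta < 0 || eta > 1) stop("eta must be a single value in [0, 1]")
  if (eta == 1) return(x)
  nu <- seq_along(probs) - 1
  q <- vapply(nu, function(m) sum(probs * stats::dbinom(m, nu, eta)), numeric(1))
  meta <- c(attr(x, "meta"), list(thinned_eta = eta))
  icsd(q / sum(q), meta = meta)
}

#' Cluster-size weighting profiles
#'
#' The two families of weighting functions applied to an ICSD: the hard step
#' of `Fk` (0 below `k`, 1 at or above `k`) and the smooth binomial weight of
#' `R2(p)`. Tabulating both over `nu` makes their difference visible: the step
#' entirely discards clusters below `k` and saturates immediately above, while
#' the binomial weight rises gradually from `nu = 2`.
#'
#' @param kind `"step_k"` (parameter: integer `k >= 2`) or `"binomial_p"`
#'   (parameter: `p` in `[0, 1]`).
#' @param param The threshold `k` or lesion probability `p`.
#' @param nu_max Largest cluster size tabulated.
#' @return A tibble with columns `nu` and `weight`.
#' @examples
#' weighting_profile("step_k", 5, nu_max = 10)
#' weighting_profile("binomial_p", 0.35, nu_max = 10)
#' @export
weighting_profile <- function(kind = c("step_k", "binomial_p"), param, nu_max = 30L) {
  kind <- match.arg(kind)
  nu <- 0:nu_max
  if (kind == "step_k") {
    if (length(param) != 1 || is.na(param) || param != round(param) || param < 2) {
      stop("step threshold k must be an integer >= 2: clusters below 2 cannot produce a DSB")
    }
    weight <- as.numeric(nu >= param)
  } else {
    if (length(param) != 1 || is.na(param) || param < 0 || param > 1) stop("p must lie in [0, 1]")
    weight <- r2_weight(nu, param)
  }
  tibble::tibble(nu = nu, weight = weight)
}
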