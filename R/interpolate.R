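#' Interpolate a grid quantity to an arbitrary energy
#'
#' Nanodosimetric quantities are tabulated on a fixed energy ladder; survival
#' experiments sit between its rungs. The grid values are interpolated with a
#' local second-order (three-point Lagrange) polynomial in `log10(energy)`,
#' through the bracketing triple of grid energies nearest to the query. The
#' interpolant reproduces grid values exactly at grid energies; queries outside
#' the grid span are refused (no extrapolation).
#'
#' @param grid A quantity grid (see [quantity_grid()]), or any subset of one.
#' @param energy Energies to interpolate to, MeV/u; vectorized.
#' @param quantity Column to interpolate, e.g. `"m1"`, `"f5"`, `"r2_p035"`.
#' @param particle,target_d_nm,target_h_nm Optional filters; after filtering,
#'   the grid must contain a single (particle, geometry) group.
#' @return Interpolated values, one per `energy`.
#' @examples
#' g <- quantity_grid(synthetic_icsd_table(
#'   particles = default_particles()[1, ], energies = c(1, 3, 10, 30),
#'   geometries = tibble::tibble(target_d_nm = 2.3, target_h_nm = 3.4)
#' ), p_grid = 0.35)
#' interpolate_quantity(g, energy = 5, quantity = "m1")
#' @export
interpolate_quantity <- function(grid, energy, quantity, particle = NULL,
                                 target_d_nm = NULL, target_h_nm = NULL) {
  grid <- filter_grid(grid, particle, target_d_nm, target_h_nm)
  if (!quantity %in% names(grid)) stop("quantity column not in grid: ", quantity)
  ord <- order(grid$energy_MeV_per_u)
  x <- log10(grid$energy_MeV_per_u[ord])
  y <- grid[[quantity]][ord]
  vapply(energy, function(e) lagrange3(x, y, log10(e)), numeric(1))
}

filter_grid <- function(grid, particle = NULL, target_d_nm = NULL, target_h_nm = NULL) {
  if (!is.null(particle)) grid <- grid[grid$particle == particle, ]
  if (!is.null(target_d_nm)) grid <- grid[abs(grid$target_d_nm - target_d_nm) < 1e-9, ]
  if (!is.null(target_h_nm)) grid <- grid[abs(grid$target_h_nm - target_h_nm) < 1e-9, ]
  groups <- unique(grid[intersect(c("particle", "target_d_nm", "target_h_nm"), names(grid))])
  if (nrow(grid) == 0) stop("no grid rows match the requested particle/geometry")
  if (nrow(groups) > 1) stop("grid contains multiple (particle, geometry) groups; filter first")
  if (anyDuplicated(grid$energy_MeV_per_u)) stop("duplicate grid energies")
  if (nrow(grid) < 3) stop("need at least three grid energies for quadratic interpolation")
  grid
}

# local three-point Lagrange quadratic through the nearest bracketing triple
lagrange3 <- function(x, y, xq) {
  n <- length(x)
  if (is.na(xq) || xq < x[1] - 1e-12 || xq > x[n] + 1e-12) {
    stop(sprintf("extrapolation refused: query energy 10^%.4g outside grid span [10^%.4g, 10^%.4g]",
                 xq, x[1], x[n]))
  }
  xq <- min(max(xq, x[1]), x[n])
  i <- findInterval(xq, x, rightmost.closed = TRUE)  # x[i] <= xq <= x[i+1]
  j <- if (i <= 1) 1L
       else if (i >= n - 1) n - 2L
       else if (xq - x[i] <= x[i + 1] - xq) i - 1L else i
  xs <- x[j:(j + 2)]; ys <- y[j:(j + 2)]
  l1 <- (xq - xs[2]) * (xq - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3]))
  l2 <- (xq - xs[1]) * (xq - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3]))
  l3 <- (xq - xs[1]) * (xq - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2]))
  sum(ys * c(l1, l2, l3))
}

#' Interpolate a quantity for an ion missing from the grid
#'
#' When a projectile was never tabulated directly (e.g. neon), its
#' nanodosimetric quantities are estimated from neighbouring ions: the
#' quantity is first interpolated to the requested energy per nucleon for each
#' donor ion, then a least-squares quadratic in atomic number `Z` is fitted
#' through the donors and evaluated at the target `Z`.
#'
#' @param grid A quantity grid containing several particles at one geometry.
#' @param target_z Atomic number of the missing ion.
#' @param energy Energy per nucleon, MeV/u (single value).
#' @param quantity Column to interpolate.
#' @param donor_z Atomic numbers of the donor ions (default: every `z` in the
#'   grid except `target_z`); at least three are required, spanning `target_z`.
#' @return The estimated quantity value.
#' @export
interpolate_missing_ion <- function(grid, target_z, energy, quantity, donor_z = NULL) {
  if (!"z" %in% names(grid)) stop("grid lacks a 'z' column")
  if (is.null(donor_z)) donor_z <- setdiff(sort(unique(grid$z)), target_z)
  if (length(donor_z) < 3) stop("need at least three donor ions for the quadratic in Z")
  if (target_z < min(donor_z) || target_z > max(donor_z)) {
    stop("target_z outside the donor Z range; extrapolation refused")
  }
  vals <- vapply(donor_z, function(zz) {
    sub <- grid[grid$z == zz, ]
    interpolate_quantity(sub, energy, quantity)
  }, numeric(1))
  fit <- stats::lm(vals ~ donor_z + I(donor_z^2))
  unname(stats::predict(fit, newdata = data.frame(donor_z = target_z)))
}
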