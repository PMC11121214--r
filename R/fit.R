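#' Modified chi-square of the proportional model sigma = K * R2
#'
#' Plain sum of squared differences between measured inactivation cross
#' sections and the scaled nanodosimetric statistic,
#' `sum_i (sigma_i - K * r2_i)^2`. Unweighted: survival databases rarely carry
#' usable per-record uncertainties.
#'
#' @param data Tibble with columns `sigma` (um^2) and `r2`.
#' @param K Proportionality constant, um^2.
#' @return The (non-negative) sum of squares; zero iff the proportionality is
#'   exact for every record.
#' @examples
#' modified_chi2(tibble::tibble(sigma = c(2, 4), r2 = c(1, 1)), K = 3)
#' @export
modified_chi2 <- function(data, K) {
  check_sigma_r2(data)
  sum((data$sigma - K * data$r2)^2)
}

#' Optimal proportionality constant K
#'
#' Minimizes [modified_chi2()] over `K`. The closed form is the least-squares
#' slope through the origin, `sum(sigma * r2) / sum(r2^2)`; the `"grid"` mode
#' reproduces a scan over candidate values and agrees with the closed form to
#' within one grid step.
#'
#' @inheritParams modified_chi2
#' @param mode `"closed_form"` (default) or `"grid"`.
#' @param k_range,k_step Scan range (um^2) and step for `"grid"` mode.
#' @return The minimizing `K` in um^2.
#' @examples
#' optimal_K(tibble::tibble(sigma = c(2, 4), r2 = c(1, 1)))
#' @export
optimal_K <- function(data, mode = c("closed_form", "grid"),
                      k_range = c(1, 200), k_step = 1) {
  check_sigma_r2(data)
  mode <- match.arg(mode)
  ss <- sum(data$r2^2)
  if (ss == 0) stop("all r2 values are zero; K is unidentifiable")
  if (mode == "closed_form") return(sum(data$sigma * data$r2) / ss)
  ks <- seq(k_range[1], k_range[2], by = k_step)
  chi <- vapply(ks, function(k) sum((data$sigma - k * data$r2)^2), numeric(1))
  ks[which.min(chi)]
}

check_sigma_r2 <- function(data) {
  missing <- setdiff(c("sigma", "r2"), names(data))
  if (length(missing)) stop("data lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(data) == 0) stop("empty record list")
  if (any(!is.finite(data$sigma)) || any(!is.finite(data$r2))) stop("sigma and r2 must be finite")
  invisible(data)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the observations. Model-agnostic, so proportional models built on
#' `R2(p)` and on any `Fk` can be compared on the same footing.
#'
#' @param observed,predicted Numeric vectors of equal length (`>= 2`).
#' @return The coefficient of determination (at most 1; can be negative for
#'   models worse than the mean).
#' @examples
#' coefficient_of_determination(c(1, 2, 3), c(1, 2, 4))
#' @export
coefficient_of_determination <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("observed and predicted differ in length")
  if (length(observed) < 2) stop("need at least two observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observations have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Lagrange triple (indices + weights) for one query; shared with lagrange3()
lagrange3_weights <- function(x, xq) {
  n <- length(x)
  if (is.na(xq) || xq < x[1] - 1e-12 || xq > x[n] + 1e-12) return(NULL)
  xq <- min(max(xq, x[1]), x[n])
  i <- findInterval(xq, x, rightmost.closed = TRUE)
  j <- if (i <= 1) 1L
       else if (i >= n - 1) n - 2L
       else if (xq - x[i] <= x[i + 1] - xq) i - 1L else i
  xs <- x[j:(j + 2)]
  w <- c((xq - xs[2]) * (xq - xs[3]) / ((xs[1] - xs[2]) * (xs[1] - xs[3])),
         (xq - xs[1]) * (xq - xs[3]) / ((xs[2] - xs[1]) * (xs[2] - xs[3])),
         (xq - xs[1]) * (xq - xs[2]) / ((xs[3] - xs[1]) * (xs[3] - xs[2])))
  list(idx = j:(j + 2), w = w)
}

#' Fit the proportional model sigma = K * R2(p; d) over a (p, d) grid
#'
#' For every target geometry in the quantity grid (optionally restricted by
#' `d_list`) and every lesion probability on the `p` grid, the survival
#' records' cross sections are paired with `R2(p)` interpolated to each
#' record's energy, the scale `K` is optimized, and the modified chi-square is
#' recorded. The chi-square surface is normalized to its maximum (so the worst
#' cell is exactly 1) and the minimum identifies the best `(p, d, K)`. Ties on
#' the surface are broken toward larger `d`, then smaller `p`, and reported.
#'
#' Records whose particle is absent from the grid or whose energy falls
#' outside the grid span for any requested geometry are excluded (with reason
#' codes) so every surface cell sees the same record set.
#'
#' @param records Tibble of survival records with columns `particle`,
#'   `energy_MeV_per_u` and either `sigma_um2` or (`alpha`, `beta`,
#'   `let_keV_per_um`) from which cross sections are computed.
#' @param grid A [quantity_grid()] covering the geometries and energies.
#' @param p_grid Lesion probabilities to scan (default: all tabulated in
#'   `grid`); each must be tabulated.
#' @param d_list Optional numeric vector of target diameters (nm) selecting
#'   geometries from `grid`.
#' @param k_mode,k_range,k_step Passed to [optimal_K()].
#' @param constants [lq_constants()] used when cross sections must be computed
#'   from LQ parameters.
#' @return An object of class `icsd_fit`: a list with elements `best` (one-row
#'   tibble: `p`, `target_d_nm`, `target_h_nm`, `K_um2`, `chi2`, `chi2_norm`,
#'   `n_ties`), `surface` (full normalized chi-square surface), `residuals`,
#'   `r_squared`, `model_comparison` (R2 vs each Fk proportional model at the
#'   best geometry), `excluded`, `n_used` and `p_grid`. Supports [tidy()],
#'   [glance()], `autoplot()` and `print()`.
#' @examples
#' \donttest{
#' tab <- synthetic_icsd_table(energies = 10^seq(-0.5, 2.5, length.out = 12))
#' g <- quantity_grid(tab, p_grid = seq(0.2, 1, 0.05))
#' spec <- synth_study_spec(n_records = 40, sigma_log = 0, seed = 1)
#' recs <- generate_survival_dataset(spec, g)
#' fit <- grid_fit(recs, g)
#' glance(fit)
#' }
#' @export
grid_fit <- function(records, grid, p_grid = NULL, d_list = NULL,
                     k_mode = c("closed_form", "grid"), k_range = c(1, 200),
                     k_step = 1, constants = lq_constants()) {
  k_mode <- match.arg(k_mode)
  missing <- setdiff(c("particle", "energy_MeV_per_u"), names(records))
  if (length(missing)) stop("records lack column(s): ", paste(missing, collapse = ", "))
  if (!"sigma_um2" %in% names(records)) {
    need <- setdiff(c("alpha", "beta", "let_keV_per_um"), names(records))
    if (length(need)) stop("records need sigma_um2 or alpha/beta/let_keV_per_um")
    records <- dplyr::mutate(records, sigma_um2 = inactivation_cross_section(
      .data$alpha, .data$beta, .data$let_keV_per_um, constants))
  }

  geoms <- dplyr::distinct(grid, .data$target_d_nm, .data$target_h_nm)
  if (!is.null(d_list)) {
    geoms <- geoms[geoms$target_d_nm %in% d_list | sapply(geoms$target_d_nm, function(d) any(abs(d - d_list) < 1e-9)), ]
  }
  if (nrow(geoms) == 0) stop("no geometries selected from the grid")

  if (is.null(p_grid)) p_grid <- grid_p_values(grid)
  p_cols <- r2_col_name(p_grid)
  absent <- setdiff(p_cols, names(grid))
  if (length(absent)) stop("p values not tabulated in grid: ", paste(absent, collapse = ", "))
  fk_cols <- grep("^f[0-9]+$", names(grid), value = TRUE)

  # interpolation weights per (record, geometry); exclusion is the union over
  # geometries so every surface cell compares the same records
  n_rec <- nrow(records)
  reasons <- character(n_rec)
  interp <- vector("list", nrow(geoms))  # [[g]]: list(r2mat n_rec x n_p, fkmat)
  for (g in seq_len(nrow(geoms))) {
    r2mat <- matrix(NA_real_, n_rec, length(p_cols))
    fkmat <- matrix(NA_real_, n_rec, length(fk_cols))
    for (i in seq_len(n_rec)) {
      if (reasons[i] != "") next
      sub <- grid[grid$particle == records$particle[i] &
                    abs(grid$target_d_nm - geoms$target_d_nm[g]) < 1e-9 &
                    abs(grid$target_h_nm - geoms$target_h_nm[g]) < 1e-9, ]
      if (nrow(sub) < 3) { reasons[i] <- "particle_not_in_grid"; next }
      ord <- order(sub$energy_MeV_per_u)
      sub <- sub[ord, ]
      lw <- lagrange3_weights(log10(sub$energy_MeV_per_u), log10(records$energy_MeV_per_u[i]))
      if (is.null(lw)) { reasons[i] <- "energy_out_of_span"; next }
      r2mat[i, ] <- lw$w %*% as.matrix(sub[lw$idx, p_cols, drop = FALSE])
      if (length(fk_cols)) fkmat[i, ] <- lw$w %*% as.matrix(sub[lw$idx, fk_cols, drop = FALSE])
    }
    interp[[g]] <- list(r2 = r2mat, fk = fkmat)
  }
  keep <- reasons == ""
  excluded <- tibble::tibble(row = which(!keep), reason = reasons[!keep])
  if (!any(keep)) stop("all records excluded (", paste(unique(excluded$reason), collapse = ", "), ")")
  if (nrow(excluded)) {
    rlang::inform(sprintf("grid_fit: excluded %d of %d records (%s)",
                          nrow(excluded), n_rec, paste(unique(excluded$reason), collapse = ", ")))
  }
  sigma <- records$sigma_um2[keep]

  surface <- purrr::map_dfr(seq_len(nrow(geoms)), function(g) {
    r2mat <- interp[[g]]$r2[keep, , drop = FALSE]
    purrr::map_dfr(seq_along(p_grid), function(j) {
      d <- tibble::tibble(sigma = sigma, r2 = r2mat[, j])
      K <- optimal_K(d, mode = k_mode, k_range = k_range, k_step = k_step)
      tibble::tibble(target_d_nm = geoms$target_d_nm[g], target_h_nm = geoms$target_h_nm[g],
                     p = p_grid[j], K_um2 = K, chi2 = modified_chi2(d, K))
    })
  })
  surface$chi2_norm <- surface$chi2 / max(surface$chi2)

  # best point; ties broken toward larger d then smaller p
  tol <- max(surface$chi2) * 1e-12
  is_tie <- surface$chi2 <= min(surface$chi2) + tol
  cand <- surface[is_tie, ]
  cand <- cand[order(-cand$target_d_nm, cand$p), ]
  best <- cand[1, ]
  best$n_ties <- nrow(cand)

  g_best <- which(abs(geoms$target_d_nm - best$target_d_nm) < 1e-9 &
                    abs(geoms$target_h_nm - best$target_h_nm) < 1e-9)
  j_best <- which(abs(p_grid - best$p) < 1e-12)
  r2_best <- interp[[g_best]]$r2[keep, j_best]
  fitted <- best$K_um2 * r2_best
  residuals <- records[keep, intersect(c("particle", "energy_MeV_per_u", "let_keV_per_um"), names(records))]
  residuals <- dplyr::mutate(residuals, sigma_um2 = sigma, r2 = r2_best,
                             fitted_um2 = fitted, residual_um2 = sigma - fitted)
  r_squared <- coefficient_of_determination(sigma, fitted)

  # single-Fk proportional models at the best geometry, for comparison
  model_comparison <- tibble::tibble(
    model = sprintf("R2(p=%.2f)", best$p), K_um2 = best$K_um2, r_squared = r_squared)
  if (length(fk_cols)) {
    fk_rows <- purrr::map_dfr(seq_along(fk_cols), function(j) {
      fvals <- interp[[g_best]]$fk[keep, j]
      if (sum(fvals^2) == 0) {
        return(tibble::tibble(model = toupper(fk_cols[j]), K_um2 = NA_real_, r_squared = NA_real_))
      }
      d <- tibble::tibble(sigma = sigma, r2 = fvals)
      K <- optimal_K(d, mode = k_mode, k_range = k_range, k_step = k_step)
      tibble::tibble(model = toupper(fk_cols[j]), K_um2 = K,
                     r_squared = coefficient_of_determination(sigma, K * fvals))
    })
    model_comparison <- dplyr::bind_rows(model_comparison, fk_rows)
  }

  structure(list(best = best, surface = surface, residuals = residuals,
                 r_squared = r_squared, model_comparison = model_comparison,
                 excluded = excluded, n_used = sum(keep), p_grid = p_grid,
                 k_mode = k_mode),
            class = "icsd_fit")
}

#' @export
print.icsd_fit <- function(x, ...) {
  b <- x$best
  cat("<icsd_fit> sigma ~ K * R2(p; d)\n")
  cat(sprintf("  best: p = %.3g, d = %g x %g nm, K = %.4g um^2 (chi2 = %.4g, %d record%s)\n",
              b$p, b$target_d_nm, b$target_h_nm, b$K_um2, b$chi2,
              x$n_used, if (x$n_used == 1) "" else "s"))
  cat(sprintf("  R^2 = %.4g; surface: %d cells, %d tie%s at the minimum\n",
              x$r_squared, nrow(x$surface), b$n_ties, if (b$n_ties == 1) "" else "s"))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded: %d record%s\n", nrow(x$excluded),
                if (nrow(x$excluded) == 1) "" else "s"))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters of an `icsd_fit`
#'
#' @param x An `icsd_fit` object from [grid_fit()].
#' @param ... Unused.
#' @return A tibble with columns `term` (`p`, `target_d_nm`, `target_h_nm`,
#'   `K_um2`) and `estimate`.
#' @export
tidy.icsd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p", "target_d_nm", "target_h_nm", "K_um2"),
    estimate = c(x$best$p, x$best$target_d_nm, x$best$target_h_nm, x$best$K_um2)
  )
}

#' One-row summary of an `icsd_fit`
#'
#' @inheritParams tidy.icsd_fit
#' @return A one-row tibble: `r.squared`, `chi2_min`, `n_records`,
#'   `n_excluded`, `n_surface_ties`.
#' @export
glance.icsd_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, chi2_min = x$best$chi2,
    n_records = x$n_used, n_excluded = nrow(x$excluded),
    n_surface_ties = x$best$n_ties
  )
}

#' Heatmap of the normalized chi-square surface
#'
#' @param object An `icsd_fit` from [grid_fit()].
#' @param ... Unused.
#' @return A ggplot: lesion probability `p` against target diameter `d`,
#'   filled by the chi-square normalized to the surface maximum; the best
#'   point is marked.
#' @export
autoplot.icsd_fit <- function(object, ...) {
  s <- object$surface
  ggplot2::ggplot(s, ggplot2::aes(x = .data$p, y = factor(.data$target_d_nm),
                                  fill = .data$chi2_norm)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, colour = "red", size = 2) +
    ggplot2::scale_fill_viridis_c(name = "chi2 / max", direction = -1) +
    ggplot2::labs(x = "lesion probability p", y = "target diameter d (nm)",
                  title = "Fit of sigma = K * R2(p; d)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-energy radiation-quality curves
#'
#' Tabulates, for one particle and geometry of a quantity grid, the curves
#' used to judge a radiation quality: LET, mean cluster size `m1`, `R2(p)`,
#' the ratio `R2(p) / M1` (an RBE-like quantity: lesion pairs per unit mean
#' cluster size, which peaks at intermediate ionization density and falls off
#' in the overkill regime), and the `Fk` columns.
#'
#' @param grid A quantity grid filtered to one (particle, geometry), or one
#'   that [interpolate_quantity()] would accept after filtering.
#' @param p Lesion probability; must be tabulated in the grid.
#' @return A tibble with one row per grid energy: `energy_MeV_per_u`,
#'   `let_keV_per_um`, `m1`, `r2`, `r2_over_m1` (0 where `m1` is 0), and the
#'   `f2 ... f7` columns present in the grid.
#' @export
quality_curves <- function(grid, p) {
  col <- r2_col_name(p)
  if (!col %in% names(grid)) stop("p = ", p, " not tabulated in grid (no column ", col, ")")
  groups <- dplyr::distinct(grid, .data$particle, .data$target_d_nm, .data$target_h_nm)
  if (nrow(groups) > 1) stop("grid contains multiple (particle, geometry) groups; filter first")
  fk_cols <- grep("^f[0-9]+$", names(grid), value = TRUE)
  grid |>
    dplyr::arrange(.data$energy_MeV_per_u) |>
    dplyr::transmute(
      energy_MeV_per_u = .data$energy_MeV_per_u,
      let_keV_per_um = .data$let_keV_per_um,
      m1 = .data$m1,
      r2 = .data[[col]],
      r2_over_m1 = ifelse(.data$m1 == 0, 0, .data[[col]] / .data$m1),
      dplyr::across(dplyr::all_of(fk_cols))
    )
}

#' Line plot of R2/M1 against LET or mean cluster size
#'
#' @param curves Output of [quality_curves()].
#' @param x `"let_keV_per_um"` or `"m1"`.
#' @return A ggplot of the RBE-like `R2/M1` curve.
#' @export
plot_quality_curves <- function(curves, x = c("let_keV_per_um", "m1")) {
  x <- match.arg(x)
  ggplot2::ggplot(curves, ggplot2::aes(x = .data[[x]], y = .data$r2_over_m1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = if (x == "m1") "mean cluster size M1" else "LET (keV/um)",
                  y = "R2(p) / M1") +
    ggplot2::theme_minimal()
}
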