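#' Derived nanodosimetric quantity grid
#'
#' Reduces an ICSD table to the per-quality summary used throughout the
#' radiobiological link: for every (particle, target geometry, energy) it
#' stores `m1`, the cumulative probabilities `f2 ... f7`, and `R2(p)` on a
#' grid of lesion probabilities (default `p` from 0.2 to 1 in steps of 0.01,
#' wide columns `r2_p020 ... r2_p100` with the suffix equal to `100 * p`).
#'
#' @param table A long-form ICSD table (see [read_icsd_table()]).
#' @param p_grid Lesion probabilities at which `R2` is tabulated.
#' @param k_values Thresholds for the `fk` columns.
#' @return A tibble (the quantity grid), one row per distribution, sorted by
#'   particle, geometry and energy.
#' @examples
#' tab <- synthetic_icsd_table(
#'   particles = default_particles()[1, ],
#'   energies = c(1, 10, 100),
#'   geometries = tibble::tibble(target_d_nm = 2.3, target_h_nm = 3.4)
#' )
#' quantity_grid(tab, p_grid = c(0.35, 1))
#' @export
quantity_grid <- function(table, p_grid = seq(0.2, 1, by = 0.01), k_values = 2:7) {
  if (length(p_grid) && (any(p_grid < 0) || any(p_grid > 1))) stop("p_grid must lie in [0, 1]")
  dists <- collect_icsds(table)
  quants <- purrr::map(dists$icsd, function(x) {
    row <- c(m1 = m1(x))
    if (length(k_values)) {
      fks <- fk(x, k_values)
      names(fks) <- sprintf("f%d", k_values)
      row <- c(row, fks)
    }
    if (length(p_grid)) {
      r2s <- r2(x, p_grid)
      names(r2s) <- r2_col_name(p_grid)
      row <- c(row, r2s)
    }
    tibble::as_tibble(as.list(row))
  })
  dplyr::bind_cols(dplyr::select(dists, -"icsd"), dplyr::bind_rows(quants)) |>
    dplyr::arrange(.data$particle, .data$target_d_nm, .data$target_h_nm, .data$energy_MeV_per_u)
}

r2_col_name <- function(p) sprintf("r2_p%03d", as.integer(round(100 * p)))

#' Lesion probabilities tabulated in a quantity grid
#'
#' @param grid A quantity grid (see [quantity_grid()]).
#' @return Sorted numeric vector of `p` values recovered from the `r2_p*`
#'   column names.
#' @export
grid_p_values <- function(grid) {
  cols <- grep("^r2_p[0-9]{3}$", names(grid), value = TRUE)
  sort(as.integer(sub("^r2_p", "", cols)) / 100)
}

#' @rdname quantity_grid
#' @param grid A quantity grid tibble.
#' @param path File to read or write (CSV).
#' @export
write_quantity_grid <- function(grid, path) {
  readr::write_csv(grid, path)
  invisible(path)
}

#' @rdname quantity_grid
#' @export
read_quantity_grid <- function(path) {
  grid <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(c(icsd_key_cols, "m1"), names(grid))
  if (length(missing)) stop("quantity grid lacks column(s): ", paste(missing, collapse = ", "))
  grid
}
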