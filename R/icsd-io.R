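#' @importFrom rlang .data
NULL

icsd_key_cols <- c("particle", "energy_MeV_per_u", "let_keV_per_um",
                   "target_d_nm", "target_h_nm")

#' Read / write ICSD tables
#'
#' ICSD tables are long-form CSV files with columns `particle`,
#' `energy_MeV_per_u`, `let_keV_per_um`, `target_d_nm`, `target_h_nm`, `nu`,
#' `probability`; all rows sharing the first five columns form one
#' distribution. On read, each distribution must have unique, contiguous-from-0
#' cluster sizes and probabilities closing to 1 within `1e-6` (then
#' renormalized exactly). A JSON mirror with the probabilities as an array per
#' distribution is read and written by the `_json` variants.
#'
#' @param path File to read or write.
#' @param table A long-form ICSD tibble (as returned by `read_icsd_table()` or
#'   [synthetic_icsd_table()]).
#' @return `read_icsd_table()`/`read_icsd_json()` return the long tibble;
#'   writers return `path` invisibly.
#' @export
read_icsd_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  validate_icsd_table(tbl)
}

#' @rdname read_icsd_table
#' @export
write_icsd_table <- function(table, path) {
  validate_icsd_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname read_icsd_table
#' @export
read_icsd_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbl <- tidyr::unnest(
    tibble::as_tibble(recs[icsd_key_cols]) |>
      dplyr::mutate(probability = if (is.list(recs$probs)) recs$probs else list(recs$probs)),
    "probability"
  )
  tbl <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icsd_key_cols))) |>
    dplyr::mutate(nu = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::relocate("nu", .before = "probability")
  validate_icsd_table(tbl)
}

#' @rdname read_icsd_table
#' @export
write_icsd_json <- function(table, path) {
  validate_icsd_table(table)
  recs <- table |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(icsd_key_cols, "nu")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icsd_key_cols))) |>
    dplyr::summarise(probs = list(.data$probability), .groups = "drop")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_icsd_table <- function(tbl) {
  need <- c(icsd_key_cols, "nu", "probability")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) stop("ICSD table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(tbl$probability < 0)) stop("ICSD table contains negative probabilities")
  checked <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icsd_key_cols))) |>
    dplyr::summarise(
      total = sum(.data$probability),
      dup = anyDuplicated(.data$nu) > 0,
      gap = !isTRUE(all.equal(sort(as.numeric(.data$nu)),
                              seq.int(0, max(.data$nu)), tolerance = 0)),
      .groups = "drop"
    )
  bad_group_label <- function(row) {
    paste(sprintf("%s=%s", icsd_key_cols, unlist(row[icsd_key_cols])), collapse = ", ")
  }
  for (i in seq_len(nrow(checked))) {
    row <- checked[i, ]
    if (row$dup) stop("duplicated cluster size nu within group: ", bad_group_label(row))
    if (row$gap) stop("cluster sizes must run 0..nu_max without gaps in group: ", bad_group_label(row))
    if (abs(row$total - 1) > 1e-6) {
      stop(sprintf("probabilities sum to %.8g (not 1) in group: %s", row$total, bad_group_label(row)))
    }
  }
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icsd_key_cols))) |>
    dplyr::mutate(probability = .data$probability / sum(.data$probability)) |>
    dplyr::ungroup()
}

#' Collect the distributions of an ICSD table into icsd objects
#'
#' @param table A long-form ICSD tibble.
#' @return A tibble with one row per distribution: the five key columns plus a
#'   list-column `icsd` of [icsd] objects.
#' @export
collect_icsds <- function(table) {
  table <- validate_icsd_table(table)
  table |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(icsd_key_cols, "nu")))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(icsd_key_cols))) |>
    dplyr::summarise(icsd = list(icsd(.data$probability)), .groups = "drop")
}
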