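#' Physical constants and conventions for the LQ link
#'
#' @param dose_fluence_constant Converts `LET [keV/um] * fluence [1/um^2]` to
#'   dose in Gy at unit density; 0.1602 when LET is in keV/um.
#' @param rho_g_per_cm3 Density of the irradiated matter; water-like tissue is
#'   close to 1.
#' @param survival_level Surviving fraction at which iso-effect quantities are
#'   evaluated (default 5%, where the cross-section vs LET relationship is
#'   particle-independent for V79 cells).
#' @return A list of class `lq_constants`.
#' @examples
#' lq_constants()
#' @export
lq_constants <- function(dose_fluence_constant = 0.1602, rho_g_per_cm3 = 1,
                         survival_level = 0.05) {
  stopifnot(dose_fluence_constant > 0, rho_g_per_cm3 > 0,
            survival_level > 0, survival_level < 1)
  structure(list(dose_fluence_constant = dose_fluence_constant,
                 rho_g_per_cm3 = rho_g_per_cm3,
                 survival_level = survival_level),
            class = "lq_constants")
}

#' Dose reaching a given surviving fraction under the LQ model
#'
#' Solves `alpha * D + beta * D^2 = -ln(S)` for the dose `D`; with `beta = 0`
#' this is `-ln(S) / alpha`, otherwise the positive root of the quadratic.
#'
#' @param alpha Linear LQ coefficient, 1/Gy; vectorized.
#' @param beta Quadratic LQ coefficient, 1/Gy^2; vectorized.
#' @param survival Surviving fraction in (0, 1).
#' @return Dose in Gy (same length as the recycled inputs).
#' @examples
#' dose_at_survival(1, 0, 0.05)  # -log(0.05)
#' @export
dose_at_survival <- function(alpha, beta, survival = 0.05) {
  if (any(survival <= 0) || any(survival >= 1)) stop("survival must lie in (0, 1)")
  n <- max(length(alpha), length(beta), length(survival))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n); survival <- rep_len(survival, n)
  loge <- -log(survival)
  disc <- alpha^2 + 4 * beta * loge
  if (any(beta == 0 & alpha <= 0)) stop("no positive root: alpha <= 0 with beta = 0")
  if (any(disc <= 0)) stop("no positive root: LQ curve never reaches the requested survival level")
  d <- ifelse(beta == 0, loge / alpha, (-alpha + sqrt(disc)) / (2 * beta))
  if (any(d <= 0 | !is.finite(d))) stop("no positive root for the requested survival level")
  d
}

#' Correct a negative quadratic LQ coefficient
#'
#' Survival-curve databases occasionally report `beta < 0` from statistical
#' fluctuation. The correction replaces such a pair by the purely linear model
#' `(alpha', 0)` with `alpha' = alpha + beta * D_S`, where `D_S` is the
#' original curve's dose at the working survival level `S`. This is the unique
#' linear model that reaches `S` at exactly the same dose as the original
#' curve, and it always lowers `alpha` (`beta < 0` implies `alpha' < alpha`).
#' Non-negative `beta` pairs pass through unchanged.
#'
#' @inheritParams dose_at_survival
#' @param survival_level Survival level preserved by the correction.
#' @return A tibble with columns `alpha`, `beta`, `corrected` (logical) and
#'   `valid` (`FALSE` when the corrected `alpha` is non-positive or the
#'   original curve never reaches the survival level; such records should be
#'   excluded).
#' @examples
#' correct_negative_beta(1, -0.05)
#' @export
correct_negative_beta <- function(alpha, beta, survival_level = 0.05) {
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  out <- tibble::tibble(alpha = alpha, beta = beta,
                        corrected = beta < 0, valid = TRUE)
  for (i in which(out$corrected)) {
    loge <- -log(survival_level)
    disc <- alpha[i]^2 + 4 * beta[i] * loge
    if (!is.finite(alpha[i]) || alpha[i] <= 0 || disc <= 0) {
      out$valid[i] <- FALSE
      next
    }
    d_s <- (-alpha[i] + sqrt(disc)) / (2 * beta[i])
    a_new <- alpha[i] + beta[i] * d_s  # == -log(survival_level) / d_s
    if (!is.finite(a_new) || a_new <= 0 || d_s <= 0) {
      out$valid[i] <- FALSE
    } else {
      out$alpha[i] <- a_new
      out$beta[i] <- 0
    }
  }
  out
}

#' Relative biological effectiveness at a survival level
#'
#' RBE is the ratio of the reference-photon dose to the ion dose producing the
#' same surviving fraction: `RBE = D_ref / D_ion`, each dose solved from its
#' LQ pair. Records lacking reference parameters get `NA` and are listed in
#' the `exclusions` attribute with a reason code.
#'
#' @param data A tibble with columns `alpha`, `beta` (ion, post-correction)
#'   and `alpha_ref`, `beta_ref` (reference photon radiation).
#' @param survival Surviving fraction defining the iso-effect (default 5%).
#' @return `data` with columns `dose_ion_Gy`, `dose_ref_Gy`, `rbe` appended;
#'   attribute `exclusions` is a tibble (row, reason) of skipped records.
#' @examples
#' rbe_at_survival(tibble::tibble(alpha = 1, beta = 0, alpha_ref = 0.2, beta_ref = 0.02))
#' @export
rbe_at_survival <- function(data, survival = 0.05) {
  need <- c("alpha", "beta", "alpha_ref", "beta_ref")
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("data lacks column(s): ", paste(missing, collapse = ", "))
  n <- nrow(data)
  dose_ion <- rep(NA_real_, n); dose_ref <- rep(NA_real_, n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    if (is.na(data$alpha_ref[i]) || is.na(data$beta_ref[i])) {
      reasons[i] <- "missing_reference"
      next
    }
    ion <- try(dose_at_survival(data$alpha[i], data$beta[i], survival), silent = TRUE)
    ref <- try(dose_at_survival(data$alpha_ref[i], data$beta_ref[i], survival), silent = TRUE)
    if (inherits(ion, "try-error")) { reasons[i] <- "invalid_ion_parameters"; next }
    if (inherits(ref, "try-error")) { reasons[i] <- "invalid_reference_parameters"; next }
    dose_ion[i] <- ion; dose_ref[i] <- ref
  }
  out <- dplyr::mutate(data, dose_ion_Gy = dose_ion, dose_ref_Gy = dose_ref,
                       rbe = dose_ref / dose_ion)
  excl <- tibble::tibble(row = which(reasons != ""), reason = reasons[reasons != ""])
  if (nrow(excl)) {
    rlang::inform(sprintf("rbe_at_survival: %d of %d records skipped (%s)",
                          nrow(excl), n,
                          paste(sprintf("%s: %d", names(table(excl$reason)), table(excl$reason)),
                                collapse = ", ")))
  }
  attr(out, "exclusions") <- excl
  out
}

#' Inactivation cross section from LQ parameters and LET
#'
#' The effective area per cell for lethal events at survival level `S`:
#' `sigma_S = (k / rho) * LET * sqrt(alpha^2 - 4 * beta * ln(S))`,
#' in um^2 with LET in keV/um, `alpha` in 1/Gy and `beta` in 1/Gy^2
#' (`k = 0.1602`). The square root equals the local slope of `-ln(survival)`
#' at the iso-survival dose, `alpha + 2 * beta * D_S`, so the `beta = 0` limit
#' reduces to the pure linear form `(k / rho) * LET * alpha`.
#'
#' @inheritParams dose_at_survival
#' @param let LET in keV/um; vectorized.
#' @param constants An [lq_constants()] object (conversion constant, density,
#'   survival level).
#' @return Cross sections in um^2.
#' @examples
#' inactivation_cross_section(1.25, 0, let = 100)  # 20.025
#' @export
inactivation_cross_section <- function(alpha, beta, let, constants = lq_constants()) {
  if (any(!is.finite(let)) || any(let <= 0)) stop("let must be positive")
  loge <- -log(constants$survival_level)
  disc <- alpha^2 + 4 * beta * loge
  if (any(disc < 0)) stop("alpha^2 - 4 beta ln(S) negative; correct parameters first")
  (constants$dose_fluence_constant / constants$rho_g_per_cm3) * let * sqrt(disc)
}

#' Ion category used for survival-data grouping
#'
#' `"Hydrogen"` covers protons and deuterons (Z = 1), `"Helium"` covers
#' helium-3/helium-4 and alpha particles (Z = 2), everything else is a heavy
#' ion.
#'
#' @param z Atomic number(s).
#' @return Character vector of categories.
#' @export
ion_category <- function(z) {
  dplyr::case_when(z == 1 ~ "Hydrogen", z == 2 ~ "Helium", TRUE ~ "Heavy")
}

survival_csv_cols <- c(
  cell_line = "cell_line", ion_symbol = "ion_symbol", z = "Z", a = "A",
  energy_MeV_per_u = "energy_MeV_per_u", let_keV_per_um = "let_keV_per_um",
  alpha = "alpha_Gy-1", beta = "beta_Gy-2",
  alpha_ref = "alpha_ref_Gy-1", beta_ref = "beta_ref_Gy-2",
  source_label = "source_label"
)

#' Read a survival-parameter table
#'
#' Reads a PIDE-style CSV of LQ survival parameters (columns `cell_line`,
#' `ion_symbol`, `Z`, `A`, `energy_MeV_per_u`, `let_keV_per_um`, `alpha_Gy-1`,
#' `beta_Gy-2`, `alpha_ref_Gy-1`, `beta_ref_Gy-2`, `source_label`), applies
#' the negative-beta correction ([correct_negative_beta()]), attaches the ion
#' category, and drops records whose corrected parameters are unusable.
#' Reference-radiation fields may be empty: such records are kept (they still
#' yield a cross section) but will be skipped by [rbe_at_survival()].
#'
#' @param path CSV file.
#' @param constants An [lq_constants()] object; its survival level drives the
#'   correction.
#' @return A tibble with tidy column names (`alpha`, `beta`, `alpha_ref`,
#'   `beta_ref`, ...), a `beta_corrected` flag and a `category` column;
#'   attribute `exclusions` lists dropped records with reason codes.
#' @export
read_survival_table <- function(path, constants = lq_constants()) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(unname(survival_csv_cols), names(raw))
  if (length(missing)) stop("survival table lacks column(s): ", paste(missing, collapse = ", "))
  tbl <- raw |>
    dplyr::select(dplyr::all_of(survival_csv_cols)) |>
    tibble::as_tibble()
  if (nrow(tbl) == 0) {
    warning("empty survival table: ", path)
    attr(tbl, "exclusions") <- tibble::tibble(row = integer(), reason = character())
    return(tbl)
  }
  tidy_survival_records(tbl, constants)
}

#' Apply corrections and categorization to survival records
#'
#' The in-memory counterpart of [read_survival_table()] for records already in
#' tidy form (columns `alpha`, `beta`, `let_keV_per_um`, `z`, ...).
#'
#' @param data Tibble of survival records.
#' @inheritParams read_survival_table
#' @return See [read_survival_table()].
#' @export
tidy_survival_records <- function(data, constants = lq_constants()) {
  if (any(!is.finite(data$let_keV_per_um)) || any(data$let_keV_per_um <= 0)) {
    stop("all records need a positive LET")
  }
  corr <- correct_negative_beta(data$alpha, data$beta, constants$survival_level)
  out <- data |>
    dplyr::mutate(alpha = corr$alpha, beta = corr$beta,
                  beta_corrected = corr$corrected,
                  category = ion_category(.data$z))
  reasons <- dplyr::case_when(
    !corr$valid ~ "invalid_lq_parameters",
    out$alpha <= 0 | is.na(out$alpha) ~ "alpha_nonpositive",
    TRUE ~ ""
  )
  excl <- tibble::tibble(row = which(reasons != ""), reason = reasons[reasons != ""])
  if (nrow(excl)) {
    rlang::inform(sprintf("survival table: excluded %d of %d records (%s)",
                          nrow(excl), nrow(out),
                          paste(unique(excl$reason), collapse = ", ")))
    out <- out[-excl$row, ]
  }
  attr(out, "exclusions") <- excl
  out
}

#' @rdname read_survival_table
#' @param data Tidy survival records (as returned by this reader).
#' @export
write_survival_table <- function(data, path) {
  keep <- intersect(names(survival_csv_cols), names(data))
  out <- data[keep]
  names(out) <- survival_csv_cols[keep]
  readr::write_csv(out, path)
  invisible(path)
}
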