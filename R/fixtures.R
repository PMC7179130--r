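# Validation fixtures -------------------------------------------------------
#
# The package ships the printed validation compounds (alkanols, alkanes and
# cycloalkanes, cage hydrocarbons, zwitterionic amino acids, and a subset of
# the ionic liquids) as name-curated structures together with their printed
# group-additivity predictions and experimental values.  They serve as the
# regression surface for the perception rules.

#' The bundled validation fixture set
#'
#' @return A tibble: `name`, `smiles` (curated structure), `phase`, `cp_ga`
#'   (printed group-additivity prediction, J/mol/K), `cp_exp` (experimental,
#'   J/mol/K), `source_table`, `needs_3d` (the printed value depends on
#'   geometry-only specials -- ring-angle bins or intramolecular hydrogen
#'   bridges -- that a connectivity-only structure cannot supply), and
#'   `imidazolium` (record carries the documented C2 correction).
#' @export
cp_fixtures <- function() {
  f <- system.file("extdata", "cp_fixtures.tsv", package = "cpgroups",
                   mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.delim(f))
  names(out)[names(out) == "source"] <- "source_table"
  out
}

#' Recompute the fixture set and compare with the printed predictions
#'
#' Every fixture is re-predicted from its structure with the bundled tables;
#' imidazolium salts are evaluated with the derived C2 correction and their
#' uncorrected offset is reported separately.  The comparison tolerance is
#' `max(0.25, 0.5%)` J/mol/K, which absorbs the two-decimal rounding of the
#' printed contributions.
#'
#' @param fixtures fixture tibble, by default [cp_fixtures()].
#' @param tol_abs,tol_rel absolute / relative tolerance components.
#' @return The fixture tibble with `cp_calc`, `dev` (calc - printed GA),
#'   `tol`, `pass`, and `uncorrected_offset` for imidazolium records; a
#'   per-table summary (MAPD against experiment, pass counts) is attached as
#'   attribute `"summary"`.
#' @export
cp_validate_fixtures <- function(fixtures = cp_fixtures(),
                                 tol_abs = 0.25, tol_rel = 0.005) {
  tabs <- list(liquid = cp_table("liquid"), solid = cp_table("solid"))
  calc <- numeric(nrow(fixtures))
  uncorr <- rep(NA_real_, nrow(fixtures))
  for (i in seq_len(nrow(fixtures))) {
    mol <- parse_smiles(fixtures$smiles[i], name = fixtures$name[i])
    tab <- tabs[[fixtures$phase[i]]]
    corr <- if (fixtures$imidazolium[i]) "derived" else "off"
    p <- suppressWarnings(
      predict_cp_one(mol, tab, invalid_groups = "allow",
                     imidazolium_correction = corr))
    calc[i] <- p$cp
    if (fixtures$imidazolium[i]) {
      p0 <- suppressWarnings(
        predict_cp_one(mol, tab, invalid_groups = "allow"))
      uncorr[i] <- p0$cp - fixtures$cp_ga[i]
    }
  }
  out <- fixtures
  out$cp_calc <- calc
  out$dev <- calc - out$cp_ga
  out$tol <- pmax(tol_abs, tol_rel * out$cp_ga)
  out$pass <- !is.na(out$dev) & abs(out$dev) <= out$tol
  out$uncorrected_offset <- uncorr
  smry <- dplyr::summarise(
    dplyr::group_by(out[!out$needs_3d, ], .data$source_table),
    n = dplyr::n(), n_pass = sum(.data$pass),
    mapd_exp = 100 * mean(abs(.data$cp_calc - .data$cp_exp) / .data$cp_exp),
    .groups = "drop")
  attr(out, "summary") <- smry
  out
}
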