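# Heat-capacity prediction --------------------------------------------------
#
# The model is plain additivity: Cp(298.15 K) = sum_i a_i A_i + sum_j b_j B_j,
# where A_i counts atom groups, B_j counts special groups, and a_i, b_j come
# from a phase-specific contribution table.  A prediction is refused (NA with
# a reason) rather than extrapolated when the molecule contains a group that
# is absent from the table, or -- under the default policy -- one whose
# contribution is not supported by at least three training molecules.

predict_cp_one <- function(mol, table,
                           cohn_mode = "n_minus_one",
                           invalid_groups = c("refuse", "allow"),
                           imidazolium_correction = c("off", "derived")) {
  invalid_groups <- match.arg(invalid_groups)
  imidazolium_correction <- match.arg(imidazolium_correction)
  if (imidazolium_correction == "derived") {
    table <- apply_imidazolium_correction(table)
  }
  refined_in_table <- any(table$atom_type %in% c("O(prim)", "O(sec)", "O(tert)"))

  counts <- tryCatch(
    perceive_groups(mol, cohn_mode = cohn_mode, refine = refined_in_table),
    error = function(e) e
  )
  if (inherits(counts, "error")) {
    return(list(cp = NA_real_, breakdown = NULL, missing_groups = character(0),
                invalid_used = character(0),
                note = conditionMessage(counts)))
  }

  # monatomic counter-ions (e.g. halides) carry no backbone group and hence
  # no contribution; flag them so the user knows the model assumes zero
  charged_monatomic <- sum(atom_degree(mol) == 0 & mol$atoms$charge != 0)
  note <- if (charged_monatomic > 0) {
    paste0(charged_monatomic,
           " charged monatomic component(s) contribute no group")
  } else NA_character_

  idx <- match(counts$key, table$key)
  specials_missing <- counts$kind == "special" & is.na(idx)
  if (any(specials_missing)) {
    warning("special group(s) without a table row ignored: ",
            paste(counts$key[specials_missing], collapse = ", "), call. = FALSE)
    counts <- counts[!specials_missing, , drop = FALSE]
    idx <- idx[!specials_missing]
  }
  missing <- counts$key[is.na(idx)]
  found <- which(!is.na(idx))
  invalid <- counts$key[found][!table$valid[idx[found]]]
  breakdown <- tibble::tibble(
    key = counts$key, kind = counts$kind, count = counts$count,
    contribution = table$contribution[idx],
    product = counts$count * table$contribution[idx]
  )
  cp <- if (length(missing) > 0 ||
            (invalid_groups == "refuse" && length(invalid) > 0)) {
    NA_real_
  } else {
    sum(breakdown$product)
  }
  list(cp = cp, breakdown = breakdown, missing_groups = missing,
       invalid_used = invalid, note = note)
}

#' Predict heat capacities for a table of molecules
#'
#' Takes a data frame with a SMILES column (or a bare character vector of
#' SMILES), perceives atom and special groups for each record, and evaluates
#' the additivity sum against a phase-specific contribution table.  Ion pairs
#' written as multi-component SMILES are treated as one record with the groups
#' of all components pooled.
#'
#' @param data a data frame containing `smiles` (and optionally `name`), or a
#'   character vector of SMILES strings.
#' @param phase `"liquid"` or `"solid"` (ignored when `table` is supplied).
#' @param table a `cp_table`; defaults to the bundled table for `phase`.
#' @param cohn_mode polyol-counting convention, see [count_special_groups()].
#' @param invalid_groups `"refuse"` (default) declines to predict from
#'   under-supported contributions; `"allow"` uses them anyway.
#' @param imidazolium_correction `"derived"` replaces the printed
#'   1,3-dialkylimidazolium C2 contribution by the internally derived value
#'   (see the package vignette); default `"off"`.
#' @return The input tibble with columns `cp` (J/mol/K at 298.15 K, `NA`
#'   when not computable), `n_missing`, `n_invalid`, `note`, and a
#'   list-column `breakdown` holding the per-group audit trail.
#' @examples
#' cp_predict(c("CCCCCC", "OCC1CCCCC1"), phase = "liquid")
#' @export
cp_predict <- function(data, phase = c("liquid", "solid"), table = NULL,
                       cohn_mode = "n_minus_one",
                       invalid_groups = "refuse",
                       imidazolium_correction = "off") {
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  data <- tibble::as_tibble(data)
  stopifnot("smiles" %in% names(data))
  if (is.null(table)) table <- cp_table(match.arg(phase))

  res <- purrr::map(data$smiles, function(s) {
    mol <- tryCatch(parse_smiles(s), error = function(e) e)
    if (inherits(mol, "error")) {
      return(list(cp = NA_real_, breakdown = NULL,
                  missing_groups = character(0), invalid_used = character(0),
                  note = conditionMessage(mol)))
    }
    predict_cp_one(mol, table, cohn_mode = cohn_mode,
                   invalid_groups = invalid_groups,
                   imidazolium_correction = imidazolium_correction)
  })
  data$cp <- purrr::map_dbl(res, "cp")
  data$n_missing <- purrr::map_int(res, ~ length(.x$missing_groups))
  data$n_invalid <- purrr::map_int(res, ~ length(.x$invalid_used))
  data$note <- purrr::map_chr(res, ~ {
    n <- .x$note
    m <- .x$missing_groups
    if (length(m) > 0) {
      paste0(c(if (!is.na(n)) n, paste0("missing: ", paste(m, collapse = ", "))),
             collapse = "; ")
    } else if (is.null(n) || is.na(n)) NA_character_ else n
  })
  data$breakdown <- purrr::map(res, "breakdown")
  data
}

#' Predict the heat capacity of a single molecule object
#'
#' Lower-level interface for an already-parsed molecule; returns the full
#' result list including the per-group breakdown.
#'
#' @param mol a `cp_mol`.
#' @inheritParams cp_predict
#' @return A list with elements `cp`, `breakdown`, `missing_groups`,
#'   `invalid_used`, `note`.
#' @export
predict_cp <- function(mol, table, ...) {
  stopifnot(inherits(mol, "cp_mol"))
  predict_cp_one(mol, table, ...)
}
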