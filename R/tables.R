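# Contribution tables -------------------------------------------------------
#
# The two phase-specific parameter tables (211 liquid entries, 197 solid
# entries, special groups included) ship with the package as TSV transcripts.
# A contribution is considered valid for prediction when it is supported by
# at least three independent molecules of the training set; under-supported
# rows are retained for transparency but refused by the default prediction
# policy.

# canonical keys for the special-group rows, matched on the atom-type text
SPECIAL_TYPE_MAP <- c("(COH)n" = "COHn",
                      "Endocyclic bonds" = "EndocyclicBonds",
                      "Angle60" = "Angle60",
                      "Angle90" = "Angle90",
                      "Angle102" = "Angle102",
                      "H" = "HHAcceptor")

# Derived replacement for the 1,3-dialkylimidazolium C2 contribution.  The
# printed value (-155.06 J/mol/K) underestimates every imidazolium salt of
# the validation set by one constant per cation; anchoring the group sum of
# 1-ethyl-3-methylimidazolium bromide (whose bromide counter-ion carries no
# group) to its printed prediction of 256.40 J/mol/K gives -55.19 J/mol/K.
# The correction is opt-in and never applied silently.
IMIDAZOLIUM_C2_KEY <- "C(+) aromatic|H:N2"
IMIDAZOLIUM_C2_DERIVED <- -55.19

#' Load a group-contribution table
#'
#' @param phase `"liquid"` or `"solid"`; selects the bundled table unless
#'   `file` points to a custom one (same TSV layout: entry, atom_type,
#'   neighbours, contribution, occurrences, molecules).
#' @param file optional path to a table in the package TSV format, e.g. one
#'   written by [cp_fit()].
#' @param support_min minimum number of supporting molecules for a row to be
#'   flagged valid.
#' @return A `cp_table` tibble with columns `entry`, `atom_type`,
#'   `neighbours`, `key`, `special`, `contribution`, `occurrences`,
#'   `molecules`, `valid`; the phase is kept as an attribute.
#' @examples
#' cp_table("liquid")
#' @export
cp_table <- function(phase = c("liquid", "solid"), file = NULL, support_min = 3L) {
  phase <- match.arg(phase)
  if (is.null(file)) {
    file <- system.file("extdata", paste0("cp_groups_", phase, ".tsv"),
                        package = "cpgroups", mustWork = TRUE)
  }
  raw <- utils::read.delim(file, colClasses = "character")
  need <- c("entry", "atom_type", "neighbours", "contribution",
            "occurrences", "molecules")
  if (!all(need %in% names(raw))) {
    stop("contribution table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  contribution <- suppressWarnings(as.numeric(raw$contribution))
  if (any(is.na(contribution))) {
    stop("non-numeric contribution in row(s): ",
         paste(raw$entry[is.na(contribution)], collapse = ", "), call. = FALSE)
  }
  special <- raw$atom_type %in% names(SPECIAL_TYPE_MAP) &
    !grepl("\\|", raw$atom_type)
  key <- ifelse(special, SPECIAL_TYPE_MAP[raw$atom_type],
                paste(raw$atom_type, raw$neighbours, sep = "|"))
  if (anyDuplicated(key)) {
    stop("duplicate group key in table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  molecules <- suppressWarnings(as.integer(raw$molecules))
  molecules[is.na(molecules)] <- 0L
  occurrences <- suppressWarnings(as.integer(raw$occurrences))
  occurrences[is.na(occurrences)] <- 0L
  out <- tibble::tibble(
    entry = raw$entry, atom_type = raw$atom_type, neighbours = raw$neighbours,
    key = unname(key), special = special, contribution = contribution,
    occurrences = occurrences, molecules = molecules,
    valid = molecules >= support_min
  )
  attr(out, "phase") <- phase
  class(out) <- c("cp_table", class(out))
  out
}

#' Published fit statistics for the bundled tables
#'
#' The goodness-of-fit summary printed alongside each contribution table
#' (training and cross-validated r-squared, average/standard deviations,
#' compound counts), for reference and comparison with re-derived fits.
#'
#' @param phase `"liquid"` or `"solid"`.
#' @return A tibble with columns `row`, `label`, `quantity`, `value`, `n`.
#' @export
cp_table_stats <- function(phase = c("liquid", "solid")) {
  phase <- match.arg(phase)
  file <- system.file("extdata", paste0("cp_fit_stats_", phase, ".tsv"),
                      package = "cpgroups", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(file))
}

apply_imidazolium_correction <- function(table) {
  i <- which(table$key == IMIDAZOLIUM_C2_KEY)
  if (length(i) == 1) table$contribution[i] <- IMIDAZOLIUM_C2_DERIVED
  table
}
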