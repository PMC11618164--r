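#' Activity/affinity ledger and ligand efficiency
#'
#' Activity values (IC50, EC50, Ki) and affinity values (Kd) are pooled as a
#' common ground, normalized to p(value) = -log10(molar value), and turned
#' into the ligand efficiency LE = 1.37 * p / hac used by the filter cascade
#' (gate: LE strictly greater than 0.3).
#'
#' @name affinity_ledger
NULL

UNIT_FACTORS <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
MEASURE_TYPES <- c("IC50", "EC50", "Ki", "Kd")

#' Read an activity table
#'
#' Tab-separated with header `entry_id het type value unit source`; records
#' with unrecognized type/unit or non-positive value are rejected with a
#' logged reason.
#'
#' @param path TSV file path
#' @return data.frame of valid `ActivityRecord` rows
#' @export
read_activity_table <- function(path) {
  df <- read_tsv(path)
  needed <- c("entry_id", "het", "type", "value", "unit")
  if (!all(needed %in% names(df))) {
    stop("activity table must have columns: ", paste(needed, collapse = ", "))
  }
  ok_type <- df$type %in% MEASURE_TYPES
  ok_unit <- df$unit %in% names(UNIT_FACTORS)
  ok_val <- is.finite(df$value) & df$value > 0
  bad <- !(ok_type & ok_unit & ok_val)
  if (any(bad)) {
    ov_log("activity table: rejecting %d record(s) (bad type/unit/value)",
           sum(bad))
  }
  df[!bad, , drop = FALSE]
}

#' Normalize a measured value to p(value)
#'
#' Converts the magnitude to molar and returns -log10 of it.
#'
#' @param value positive magnitude
#' @param unit one of M, mM, uM, nM, pM
#' @return p(value), unitless
#' @export
normalize_value <- function(value, unit) {
  if (!all(unit %in% names(UNIT_FACTORS))) {
    stop("unknown unit: ", paste(setdiff(unit, names(UNIT_FACTORS)),
                                 collapse = ", "))
  }
  if (any(!is.finite(value) | value <= 0)) {
    stop("value must be positive and finite")
  }
  unname(-log10(value * UNIT_FACTORS[unit]))
}

#' Ligand efficiency
#'
#' LE = 1.37 * p(value) / hac.
#'
#' @param p_value normalized potency, unitless
#' @param hac heavy atom count, >= 1
#' @return unitless ligand efficiency
#' @export
ligand_efficiency <- function(p_value, hac) {
  if (any(hac < 1)) stop("heavy atom count must be >= 1")
  1.37 * p_value / hac
}

#' Minimum estimated ligand efficiency over a ligand's records
#'
#' Pools all valid records mapped to one (entry_id, het) ligand and computes
#' the LE from the selected p(value). The default selection `min_p` takes the
#' minimum normalized potency (the weakest measurement), realizing the
#' minimum estimated LE; `min_molar` takes the lowest molar concentration
#' (the strongest measurement) instead.
#'
#' @param records data.frame of activity records (columns value, unit)
#' @param hac heavy atom count of the ligand
#' @param selection `"min_p"` (default) or `"min_molar"`
#' @return an `EfficiencyResult` list (p_value, ligand_efficiency, n_records)
#'   or `NULL` when no valid record exists
#' @export
min_le_for_ligand <- function(records, hac, selection = c("min_p", "min_molar")) {
  selection <- match.arg(selection)
  if (is.null(records) || !nrow(records)) return(NULL)
  valid <- records[is.finite(records$value) & records$value > 0 &
                     records$unit %in% names(UNIT_FACTORS), , drop = FALSE]
  if (!nrow(valid)) return(NULL)
  p <- unname(normalize_value(valid$value, valid$unit))
  p_sel <- if (selection == "min_p") min(p) else max(p)
  list(
    p_value = p_sel,
    ligand_efficiency = ligand_efficiency(p_sel, hac),
    n_records = nrow(valid)
  )
}
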