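# Shift tables (per-site predicted shifts + uncertainties for database
# structures) and assignment tables (experimental shifts for the query
# molecule) are plain CSV.

#' Read a per-site predicted shift table
#'
#' The CSV must have columns `structure_id`, `site_index`, `nucleus`,
#' `shift_ppm`, `uncertainty_ppm` — one row per (structure, site). These are
#' the predicted isotropic chemical shifts (with prediction uncertainties)
#' attached to every H and C site of the database structures.
#'
#' @param path CSV path.
#' @return data.frame with one record per row, row order preserved.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "site_index", "nucleus", "shift_ppm",
            "uncertainty_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("shift table format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  if (!is.numeric(df$shift_ppm) || any(!is.finite(df$shift_ppm))) {
    stop("shift table validation error: non-numeric shift_ppm", call. = FALSE)
  }
  if (!is.numeric(df$uncertainty_ppm) || any(!is.finite(df$uncertainty_ppm)) ||
      any(df$uncertainty_ppm <= 0)) {
    stop("shift table validation error: uncertainty_ppm must be > 0",
         call. = FALSE)
  }
  df$structure_id <- as.character(df$structure_id)
  df$site_index <- as.integer(df$site_index)
  df$nucleus <- as.character(df$nucleus)
  df
}

#' Write a shift table CSV
#' @param records data.frame as returned by [read_shift_table()].
#' @param path output path.
#' @export
write_shift_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an assignment table for a query molecule
#'
#' Each row assigns an experimental shift (ppm) to a labelled site of the
#' query molecule. Bonded C-H pairs whose cross peak is used for 2D
#' (HETCOR-style) selection share a `pair_id`; such a pair must consist of
#' one C and one H entry.
#'
#' @param label character site labels (must exist in the query structure).
#' @param nucleus element symbol per row ("H" or "C").
#' @param shift_ppm experimental shift per row.
#' @param ambiguous logical; marks assignments that cannot be tied to a
#'   unique atom (e.g. diastereotopic CH2 protons, symmetric aromatic sites).
#'   Usually computed with [flag_ambiguous_sites()] rather than set by hand.
#' @param pair_id optional integer/character pair key for bonded C-H entries.
#' @return data.frame of class `assignment_table`.
#' @export
assignment_table <- function(label, nucleus, shift_ppm,
                             ambiguous = FALSE, pair_id = NA) {
  df <- data.frame(label = as.character(label),
                   nucleus = as.character(nucleus),
                   shift_ppm = as.numeric(shift_ppm),
                   ambiguous = rep_len(as.logical(ambiguous), length(label)),
                   pair_id = rep_len(pair_id, length(label)),
                   stringsAsFactors = FALSE)
  if (!all(df$nucleus %in% c("H", "C"))) {
    stop("assignments support H and C nuclei only", call. = FALSE)
  }
  if (any(!is.finite(df$shift_ppm))) {
    stop("assignment validation error: non-finite shift", call. = FALSE)
  }
  dup <- duplicated(df$label)
  if (any(dup)) {
    stop("assignment validation error: duplicate site label(s) ",
         paste(unique(df$label[dup]), collapse = ", "), call. = FALSE)
  }
  for (pid in unique(df$pair_id[!is.na(df$pair_id)])) {
    sel <- df[!is.na(df$pair_id) & df$pair_id == pid, ]
    if (nrow(sel) != 2L || !setequal(sel$nucleus, c("C", "H"))) {
      stop("assignment validation error: pair ", pid,
           " must link exactly one C and one H entry", call. = FALSE)
    }
  }
  class(df) <- c("assignment_table", "data.frame")
  df
}

#' Read an assignment table from CSV
#'
#' Columns: `label`, `nucleus`, `shift_ppm`; optional `ambiguous` (logical)
#' and `pair_id`.
#' @param path CSV path.
#' @return an [assignment_table()].
#' @export
read_assignments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "nucleus", "shift_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("assignment format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  assignment_table(df$label, df$nucleus, df$shift_ppm,
                   ambiguous = if ("ambiguous" %in% names(df))
                     df$ambiguous else FALSE,
                   pair_id = if ("pair_id" %in% names(df))
                     df$pair_id else NA)
}
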