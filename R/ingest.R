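# Reading, validation, chamber filtering and condition pooling of
# per-cell segmentation tables.

#' Condition key
#'
#' Identifies one cultivation condition: strain, excess/limitation
#' durations, its role on the chip and the experiment it belongs to.
#' Controls must have duty cycle 1 (`excess_control`) or 0
#' (`limitation_control`).
#'
#' @param strain Strain label.
#' @param excess_s,limitation_s Phase durations, seconds.
#' @param role `"dynamic"`, `"excess_control"` or `"limitation_control"`.
#' @param experiment_id Experiment label.
#' @return An object of class `condition_key`.
#' @export
condition_key <- function(strain, excess_s, limitation_s,
                          role = c("dynamic", "excess_control",
                                   "limitation_control"),
                          experiment_id = "exp1") {
  role <- match.arg(role)
  if (role == "excess_control" && limitation_s != 0)
    stop("excess control must have limitation_s == 0", call. = FALSE)
  if (role == "limitation_control" && excess_s != 0)
    stop("limitation control must have excess_s == 0", call. = FALSE)
  structure(list(strain = strain, excess_s = excess_s,
                 limitation_s = limitation_s, role = role,
                 experiment_id = experiment_id),
            class = "condition_key")
}

.cell_table_required <- c("strain", "condition_id", "array_index",
                          "chamber_index", "frame", "time_h", "area_um2")
.cell_table_numeric <- c("array_index", "chamber_index", "frame", "time_h",
                         "area_um2", "gray_rfp", "gray_gfp", "gray_cfp",
                         "gray_uvgfp", "excess_s", "limitation_s")

#' Read and validate a per-cell measurement table
#'
#' Reads the long-format CSV produced by the segmentation pipeline (or
#' [export_cell_table()]): one row per detected cell per frame.  The
#' schema is validated, numeric columns are coerced (empty fluorescence
#' fields become `NA`, marking non-fluorescence frames), and rows with
#' non-positive or missing cell area are rejected with a message
#' reporting the count.
#'
#' @param path CSV file path.
#' @return A validated `cell_table` data frame, time axis in hours.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop(sprintf("empty cell table: '%s'", path), call. = FALSE)
  missing_cols <- setdiff(.cell_table_required, names(df))
  if (length(missing_cols))
    stop(sprintf("cell table '%s' is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in intersect(.cell_table_numeric, names(df))) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(is.na(v) & !(is.na(df[[col]]) | df[[col]] == ""))
      if (length(bad))
        stop(sprintf("unparseable value in column '%s' at row %d of '%s'",
                     col, bad[1], path), call. = FALSE)
      df[[col]] <- v
    }
  }
  bad_area <- is.na(df$area_um2) | df$area_um2 <= 0
  if (any(bad_area)) {
    message(sprintf("read_cell_table: rejected %d row(s) with non-positive area",
                    sum(bad_area)))
    df <- df[!bad_area, , drop = FALSE]
    if (nrow(df) == 0)
      stop("no valid rows left after area filtering", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Keep only the chambers with high pulse fidelity
#'
#' The oscillation loses definition along each array, so only the
#' chambers nearest the inlet are analyzed (the first 10 by default).
#'
#' @param table A `cell_table`.
#' @param max_chamber_index Largest chamber index retained (default 10).
#' @return The filtered `cell_table`; a message reports the retained
#'   chamber count per array, a warning flags an empty result.
#' @export
filter_chambers <- function(table, max_chamber_index = 10) {
  stopifnot(is.data.frame(table), "chamber_index" %in% names(table))
  keep <- table$chamber_index <= max_chamber_index
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no rows retained by the chamber filter", call. = FALSE)
  } else {
    per_array <- tapply(out$chamber_index, out$array_index,
                        function(x) length(unique(x)))
    message(sprintf("filter_chambers: retained %s chamber(s) on array(s) %s",
                    paste(per_array, collapse = "/"),
                    paste(names(per_array), collapse = "/")))
  }
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Pool all chambers of one condition
#'
#' Concatenates the per-chamber tables of a condition into a single
#' table (chamber provenance columns preserved), the unit on which
#' growth and population statistics are computed.
#'
#' @param tables A `cell_table` or a list of them.
#' @param key Optional [condition_key()] attached to the result.
#' @return The pooled `cell_table`.  Pooling fewer than 5 distinct
#'   chambers triggers a warning (the analysis convention is at least
#'   five chambers per condition); conflicting strain labels are an
#'   error.
#' @export
pool_condition <- function(tables, key = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1, all(vapply(tables, is.data.frame,
                                            logical(1))))
  out <- do.call(rbind, lapply(tables, as.data.frame))
  strains <- unique(out$strain)
  if (length(strains) > 1)
    stop(sprintf("conflicting strain labels under one condition: %s",
                 paste(strains, collapse = ", ")), call. = FALSE)
  n_chambers <- nrow(unique(out[, c("array_index", "chamber_index")]))
  if (n_chambers < 5)
    warning(sprintf(
      "only %d chamber(s) pooled; the analysis convention is at least 5 per condition",
      n_chambers), call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  attr(out, "condition_key") <- key
  out
}
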