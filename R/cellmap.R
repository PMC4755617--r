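#' The three-class cell vocabulary
#'
#' Cell maps use exactly three morphological classes: cancer cells,
#' lymphocytes and stromal cells (fibroblasts, endothelial cells and other
#' non-lymphoid stroma are collapsed into the stromal class upstream).
#'
#' @return Character vector of the three valid cell-type labels.
#' @export
cell_classes <- function() c("cancer", "lymphocyte", "stromal")

#' Construct a cell map
#'
#' A cell map is the raw input of the method: one row per classified cell,
#' with planar coordinates in micrometres (image convention: origin at the
#' top-left, y increasing downward; only relative positions matter) and a
#' cell class from the three-class vocabulary.
#'
#' @param x,y numeric coordinates in micrometres; finite and non-negative.
#' @param cell_type character or factor; values must be among
#'   [cell_classes()].
#' @param section_id optional per-cell section identifier (e.g. top /
#'   middle / bottom section of the same tumor).
#' @param tumor_id single identifier for the tumor the cells belong to.
#' @return A `data.frame` of class `"cell_map"` with columns `x_um`,
#'   `y_um`, `cell_type` and optionally `section_id`, and a `tumor_id`
#'   attribute.
#' @examples
#' cm <- cell_map(c(1, 2, 3), c(1, 1, 2),
#'                c("cancer", "lymphocyte", "stromal"))
#' nrow(cm)
#' @export
cell_map <- function(x, y, cell_type, section_id = NULL, tumor_id = "tumor") {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || length(cell_type) != n)
    stop_ecodiv("x, y and cell_type must have equal length", "ecodiv_schema_error")
  if (n > 0L) {
    bad <- which(!is.finite(x) | !is.finite(y))
    if (length(bad))
      stop_ecodiv(sprintf("non-finite coordinate at row %d", bad[1L]),
                  "ecodiv_parse_error")
    if (any(x < 0) || any(y < 0))
      stop_ecodiv("coordinates must be non-negative", "ecodiv_parse_error")
  }
  cell_type <- as.character(cell_type)
  unknown <- setdiff(unique(cell_type), cell_classes())
  if (length(unknown))
    stop_ecodiv(sprintf("unknown cell type label(s): %s",
                        paste(unknown, collapse = ", ")),
                "ecodiv_vocabulary_error")
  df <- data.frame(x_um = x, y_um = y,
                   cell_type = factor(cell_type, levels = cell_classes()),
                   stringsAsFactors = FALSE)
  if (!is.null(section_id)) {
    if (length(section_id) != n)
      stop_ecodiv("section_id must match the number of cells", "ecodiv_schema_error")
    df$section_id <- as.character(section_id)
  }
  structure(df, tumor_id = as.character(tumor_id)[1L],
            class = c("cell_map", "data.frame"))
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("Cell map '%s': %d cells", attr(x, "tumor_id"), nrow(x)))
  if (nrow(x)) {
    tab <- table(x$cell_type)
    cat(" (", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Read a cell table from CSV
#'
#' Canonical columns are `x_um`, `y_um`, `cell_type` and the optional
#' `section_id`; other column names can be mapped through `schema`.
#'
#' @param path path to a CSV file.
#' @param schema named character vector mapping canonical names
#'   (`x`, `y`, `cell_type`, `section_id`) to the file's column names.
#' @param tumor_id tumor identifier attached to the result; defaults to the
#'   file name without extension.
#' @return A [cell_map()] object; row order follows the file.
#' @export
read_cell_table <- function(path,
                            schema = c(x = "x_um", y = "y_um",
                                       cell_type = "cell_type",
                                       section_id = "section_id"),
                            tumor_id = NULL) {
  if (!file.exists(path))
    stop_ecodiv(sprintf("file not found: %s", path), "ecodiv_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "cell_type")
  for (f in need) {
    col <- schema[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop_ecodiv(sprintf("missing required column '%s' (mapped from '%s')",
                          if (is.null(col)) f else col, f),
                  "ecodiv_schema_error")
  }
  xs <- raw[[schema[["x"]]]]; ys <- raw[[schema[["y"]]]]
  if (nrow(raw)) {
    xn <- suppressWarnings(as.numeric(xs)); yn <- suppressWarnings(as.numeric(ys))
    bad <- which(is.na(xn) | is.na(yn))
    if (length(bad))
      stop_ecodiv(sprintf("non-numeric coordinate at data row %d", bad[1L]),
                  "ecodiv_parse_error")
    xs <- xn; ys <- yn
  } else xs <- ys <- numeric(0)
  sec_col <- schema[["section_id"]]
  sec <- if (!is.null(sec_col) && !is.na(sec_col) && sec_col %in% names(raw) && nrow(raw))
    raw[[sec_col]] else NULL
  if (is.null(tumor_id))
    tumor_id <- sub("\\.[^.]*$", "", basename(path))
  cell_map(xs, ys,
           if (nrow(raw)) raw[[schema[["cell_type"]]]] else character(0),
           section_id = sec, tumor_id = tumor_id)
}

#' Write a cell table to CSV
#'
#' Inverse of [read_cell_table()]: the written file re-reads to a cell map
#' equal to the input on all fields.
#'
#' @param cellmap a [cell_map()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cellmap, path) {
  stopifnot(inherits(cellmap, "cell_map"))
  df <- as.data.frame(cellmap)
  df$cell_type <- as.character(df$cell_type)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_ecodiv(sprintf("cannot write to '%s'", path), "ecodiv_io_error")
  invisible(path)
}

#' Validate a cohort clinical table
#'
#' Checks the clinical schema and applies administrative censoring at the
#' 10-year endpoint: disease-specific follow-up beyond `cap_months` is
#' truncated to `cap_months` with the event flag cleared. Validation is
#' idempotent.
#'
#' @param table data.frame with columns `survival_months` (> 0), `event`
#'   (0/1) and optionally `grade` (1/2/3), `size_cat` (1/2/3), `node` (0/1),
#'   `er` (0/1), `tp53` ("WT"/"MUT"), `edi_score` (integer 1-5).
#' @param cap_months administrative censoring horizon (default 120 months).
#' @return The validated table with censoring applied.
#' @export
validate_cohort <- function(table, cap_months = 120) {
  stopifnot(is.data.frame(table))
  for (col in c("survival_months", "event"))
    if (!col %in% names(table))
      stop_ecodiv(sprintf("missing cohort column '%s'", col), "ecodiv_schema_error")
  t <- table
  if (any(!is.finite(t$survival_months)) || any(t$survival_months <= 0))
    stop_ecodiv("survival_months must be finite and > 0", "ecodiv_validation_error")
  if (!all(t$event %in% c(0, 1)))
    stop_ecodiv("event must be 0 or 1", "ecodiv_validation_error")
  over <- t$survival_months > cap_months
  t$event[over] <- 0
  t$survival_months[over] <- cap_months
  checks <- list(grade = 1:3, size_cat = 1:3, node = 0:1, er = 0:1,
                 tp53 = c("WT", "MUT"), edi_score = 1:5)
  for (col in names(checks)) {
    if (!col %in% names(t)) next
    v <- t[[col]]
    bad <- !is.na(v) & !v %in% checks[[col]]
    if (any(bad))
      stop_ecodiv(sprintf("invalid value in cohort column '%s': %s",
                          col, v[bad][1L]), "ecodiv_validation_error")
  }
  t
}
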