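#' @title Cell-coordinate and clinical table input/output
#' @name cellmap_io
#' @description
#' Readers and writers for the two flat-file inputs of the pipeline: per-slide
#' cell tables (one row per detected nucleus, with coordinates and a class
#' label in cancer / lymphocyte / stromal) and per-patient clinical tables
#' (overall-survival time and event plus optional covariates). The internal
#' canonical unit is the micrometre; pixel-unit files are converted at read
#' time. Class labels are case-insensitive on input and stored lowercase.
NULL

.CELL_CLASSES <- c("cancer", "lymphocyte", "stromal")

# delimiter sniffing: tab wins if present in the header line
.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Construct a slide cell map from coordinates held in memory
#'
#' @param cells data frame with columns `x`, `y` (micrometres, finite,
#'   non-negative) and `cell_class` (one of `"cancer"`, `"lymphocyte"`,
#'   `"stromal"`; case-insensitive).
#' @param patient_id,section_id identifiers; `(patient_id, section_id)`
#'   should be unique within a cohort.
#' @param resolution_um_per_px metadata only: the scan resolution the
#'   coordinates came from. Default 5 micrometres per pixel.
#' @return An object of class `slide_cell_map`: a list with elements
#'   `patient_id`, `section_id`, `cells` (data frame in micrometres) and
#'   `resolution_um_per_px`.
#' @export
slide_cell_map <- function(cells, patient_id = "P1", section_id = "S1",
                           resolution_um_per_px = 5) {
  stopifnot(is.data.frame(cells))
  need <- c("x", "y", "cell_class")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(cells) == 0L) stop("a slide must contain at least one cell")
  x <- as.numeric(cells$x); y <- as.numeric(cells$y)
  bad <- which(!is.finite(x) | !is.finite(y) | x < 0 | y < 0)
  if (length(bad))
    stop("non-finite or negative coordinate at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cls <- tolower(trimws(as.character(cells$cell_class)))
  unknown <- setdiff(unique(cls), .CELL_CLASSES)
  if (length(unknown))
    stop("unknown cell class label(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(resolution_um_per_px) || resolution_um_per_px <= 0)
    stop("resolution_um_per_px must be a positive number")
  out <- list(
    patient_id = as.character(patient_id),
    section_id = as.character(section_id),
    cells = data.frame(x = x, y = y, cell_class = cls,
                       stringsAsFactors = FALSE),
    resolution_um_per_px = resolution_um_per_px
  )
  class(out) <- "slide_cell_map"
  out
}

#' @export
print.slide_cell_map <- function(x, ...) {
  tab <- table(factor(x$cells$cell_class, levels = .CELL_CLASSES))
  cat(sprintf("<slide_cell_map> patient %s section %s: %d cells (%s)\n",
              x$patient_id, x$section_id, nrow(x$cells),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Bounding box of a slide in micrometres
#'
#' @param map a `slide_cell_map`.
#' @return Named numeric vector `xmin, xmax, ymin, ymax`.
#' @export
slide_bbox <- function(map) {
  stopifnot(inherits(map, "slide_cell_map"))
  c(xmin = min(map$cells$x), xmax = max(map$cells$x),
    ymin = min(map$cells$y), ymax = max(map$cells$y))
}

#' Read a cell-coordinate table from CSV/TSV
#'
#' Columns `x`, `y` and `class` are required (names configurable). If the
#' file is in pixel units, coordinates are multiplied by
#' `resolution_um_per_px` so that the returned object is always in
#' micrometres. Row order is preserved.
#'
#' @param path path to a CSV or TSV file.
#' @param units `"um"` (default) or `"px"`.
#' @param resolution_um_per_px micrometres per pixel used for the `"px"`
#'   conversion; default 5.
#' @param patient_id,section_id identifiers; if `NULL`, taken from
#'   `patient_id` / `section_id` columns when present (which must then be
#'   constant within the file).
#' @param col_x,col_y,col_class column names in the file.
#' @return A [slide_cell_map()].
#' @export
read_cell_map <- function(path, units = c("um", "px"),
                          resolution_um_per_px = 5,
                          patient_id = NULL, section_id = NULL,
                          col_x = "x", col_y = "y", col_class = "class") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in c(col_x, col_y, col_class))
    if (!cc %in% names(df)) stop("missing column in ", path, ": ", cc)
  take_id <- function(given, col, fallback) {
    if (!is.null(given)) return(given)
    if (col %in% names(df)) {
      v <- unique(as.character(df[[col]]))
      if (length(v) != 1L)
        stop("column ", col, " is not constant within ", path)
      return(v)
    }
    fallback
  }
  pid <- take_id(patient_id, "patient_id",
                 sub("\\.[^.]*$", "", basename(path)))
  sid <- take_id(section_id, "section_id", "S1")
  sc <- if (units == "px") resolution_um_per_px else 1
  slide_cell_map(
    data.frame(x = as.numeric(df[[col_x]]) * sc,
               y = as.numeric(df[[col_y]]) * sc,
               cell_class = df[[col_class]],
               stringsAsFactors = FALSE),
    patient_id = pid, section_id = sid,
    resolution_um_per_px = resolution_um_per_px
  )
}

#' Read a per-patient clinical table
#'
#' Requires columns `patient_id`, `os_months` (or `os_time`) and `os_event`.
#' All remaining columns are kept as covariates; missing values are
#' propagated, never imputed. With `five_year = TRUE` (the default, because
#' the downstream survival analyses are five-year overall survival),
#' administrative censoring is applied at 60 months: times beyond 60 are
#' truncated to 60 with the event indicator set to 0.
#'
#' @param path path to a CSV or TSV file.
#' @param five_year logical; apply five-year administrative censoring.
#' @return A data frame of class `clinical_table` with columns
#'   `patient_id`, `os_months`, `os_event`, then covariates.
#' @export
read_clinical <- function(path, five_year = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"os_months" %in% names(df) && "os_time" %in% names(df))
    names(df)[names(df) == "os_time"] <- "os_months"
  miss <- setdiff(c("patient_id", "os_months", "os_event"), names(df))
  if (length(miss))
    stop("missing column in ", path, ": ", paste(miss, collapse = ", "))
  clinical_table(df, five_year = five_year)
}

#' Validate (and optionally five-year-censor) a clinical data frame
#'
#' @param df data frame with `patient_id`, `os_months`, `os_event` and any
#'   covariate columns.
#' @param five_year logical; truncate times beyond 60 months to 60 with
#'   `os_event = 0`.
#' @return The validated data frame with class `clinical_table`.
#' @export
clinical_table <- function(df, five_year = TRUE) {
  stopifnot(is.data.frame(df))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  df$os_months <- as.numeric(df$os_months)
  if (any(!is.finite(df$os_months) | df$os_months <= 0))
    stop("os_months must be finite and > 0")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  df$os_event <- as.integer(df$os_event)
  if (five_year) {
    over <- df$os_months > 60
    df$os_event[over] <- 0L
    df$os_months[over] <- 60
  }
  front <- c("patient_id", "os_months", "os_event")
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a tabular result as TSV
#'
#' UTF-8, tab-separated, header row, no quoting, deterministic column order
#' (as given). Writing an empty collection is an error rather than an empty
#' file, so silently-empty analyses are caught early.
#'
#' @param records non-empty data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("refusing to write an empty table: ", path)
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a slide cell map back to TSV (micrometre units)
#'
#' @param map a `slide_cell_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_map <- function(map, path) {
  stopifnot(inherits(map, "slide_cell_map"))
  df <- data.frame(x = map$cells$x, y = map$cells$y,
                   class = map$cells$cell_class,
                   patient_id = map$patient_id,
                   section_id = map$section_id,
                   stringsAsFactors = FALSE)
  write_table(df, path)
}
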