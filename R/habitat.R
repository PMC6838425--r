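#' @title Habitat grid: quadrat counts and ecological classification
#' @name habitat_grid
#' @description
#' A square grid (default 100 micrometre side) is laid over each tissue
#' section and the cells of each class are counted per square. Every square
#' holding at least one cancer cell is classified into one of four
#' ecological habitats by comparing its stromal ("resource") and lymphocyte
#' ("hazard") counts against thresholds proportional to its cancer-cell
#' count: `th_str = k_str * n_cancer` and `th_lym = k_lym * n_cancer`.
#' "High" means strictly greater than the threshold, so with the default
#' `k_lym = 0.2` a square with fewer than five cancer cells still needs at
#' least one lymphocyte to be high hazard. Squares without cancer cells get
#' no habitat and are excluded from all summaries.
NULL

.HABITATS <- c("RpHp", "RpHm", "RmHp", "RmHm")

#' Grid specification
#'
#' Squares tile the plane as half-open intervals
#' `[x0 + shift + i*s, x0 + shift + (i+1)*s)` (and likewise in y), so a
#' cell sitting exactly on a right or bottom edge belongs to the next
#' square and is never double counted.
#'
#' @param square_size_um square side length in micrometres (default 100).
#' @param shift_x_um,shift_y_um grid-origin displacement in micrometres.
#' @param origin numeric length-2, grid origin `(x0, y0)` before shift.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(square_size_um = 100, shift_x_um = 0, shift_y_um = 0,
                      origin = c(0, 0)) {
  stopifnot(is.numeric(square_size_um), square_size_um > 0,
            length(origin) == 2)
  structure(list(square_size_um = square_size_um,
                 shift_x_um = shift_x_um, shift_y_um = shift_y_um,
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

# half-open square index of coordinates under a grid spec
.square_index <- function(v, origin, shift, size) {
  as.integer(floor((v - origin - shift) / size))
}

#' Count cells of each class per grid square
#'
#' Every cell is assigned to exactly one square by half-open binning after
#' applying the grid shift. Squares containing no cells at all are omitted.
#'
#' @param map a [slide_cell_map()].
#' @param grid a [grid_spec()].
#' @return Data frame with columns `i`, `j`, `n_cancer`, `n_stromal`,
#'   `n_lym`, one row per occupied square, ordered by `(i, j)`.
#' @export
count_cells_per_square <- function(map, grid = grid_spec()) {
  stopifnot(inherits(map, "slide_cell_map"), inherits(grid, "grid_spec"))
  s <- grid$square_size_um
  i <- .square_index(map$cells$x, grid$origin[1], grid$shift_x_um, s)
  j <- .square_index(map$cells$y, grid$origin[2], grid$shift_y_um, s)
  key <- paste(i, j, sep = ":")
  cls <- factor(map$cells$cell_class, levels = .CELL_CLASSES)
  tab <- table(key, cls)
  ij <- do.call(rbind, strsplit(rownames(tab), ":", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    n_cancer = as.integer(tab[, "cancer"]),
                    n_stromal = as.integer(tab[, "stromal"]),
                    n_lym = as.integer(tab[, "lymphocyte"]))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Habitat threshold constants
#'
#' @param k_str stromal (resource) threshold multiplier; default 0.5, which
#'   labels roughly a quarter of cancer-containing squares high resource and
#'   damps noise from reactive stroma at the tumour margin.
#' @param k_lym lymphocyte (hazard) threshold multiplier; default 0.2,
#'   which splits habitats into two roughly equal hazard groups. Lymphocytes
#'   sit a trophic level above cancer cells, so their threshold is the
#'   smaller of the two.
#' @return List of class `habitat_params`.
#' @export
habitat_params <- function(k_str = 0.5, k_lym = 0.2) {
  stopifnot(k_str > 0, k_lym > 0)
  structure(list(k_str = k_str, k_lym = k_lym), class = "habitat_params")
}

#' Classify grid squares into ecological habitats
#'
#' A square with no cancer cells gets habitat `"none"`. Otherwise resource
#' is high iff `n_stromal > k_str * n_cancer` and hazard is high iff
#' `n_lym > k_lym * n_cancer` (strictly greater: boundary counts are low).
#'
#' @param counts data frame as from [count_cells_per_square()] (columns
#'   `n_cancer`, `n_stromal`, `n_lym`).
#' @param params a [habitat_params()].
#' @return Character vector of habitat labels, one per row of `counts`,
#'   in `RpHp`, `RpHm`, `RmHp`, `RmHm`, `none`.
#' @export
classify_squares <- function(counts, params = habitat_params()) {
  stopifnot(inherits(params, "habitat_params"))
  n_c <- counts$n_cancer
  r_hi <- counts$n_stromal > params$k_str * n_c
  h_hi <- counts$n_lym > params$k_lym * n_c
  lab <- ifelse(r_hi,
                ifelse(h_hi, "RpHp", "RpHm"),
                ifelse(h_hi, "RmHp", "RmHm"))
  lab[n_c == 0L] <- "none"
  lab
}

#' Build a classified habitat map for one section
#'
#' @param map a [slide_cell_map()].
#' @param grid a [grid_spec()].
#' @param params a [habitat_params()].
#' @return Object of class `habitat_map`: list with `grid`, `params`,
#'   `squares` (counts plus `habitat` column), `bbox`, and the slide ids.
#' @export
habitat_map <- function(map, grid = grid_spec(), params = habitat_params()) {
  sq <- count_cells_per_square(map, grid)
  sq$habitat <- classify_squares(sq, params)
  structure(list(patient_id = map$patient_id, section_id = map$section_id,
                 grid = grid, params = params, squares = sq,
                 bbox = slide_bbox(map)),
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  tab <- table(factor(x$squares$habitat, levels = c(.HABITATS, "none")))
  cat(sprintf("<habitat_map> patient %s section %s: %d occupied squares (%s)\n",
              x$patient_id, x$section_id, nrow(x$squares),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Summarize a habitat map into habitat counts and fractions
#'
#' Only squares with a habitat (at least one cancer cell) enter the
#' summary; fractions are counts over the number of classified squares.
#'
#' @param hmap a [habitat_map()], or a precomputed habitat label vector.
#' @param id identifier for the summary; defaults to the map's section.
#' @return Object of class `habitat_summary`: list with `id`,
#'   `patient_id`, `counts` (named integer, the four habitats), `total`
#'   and `fractions`.
#' @export
summarize_habitats <- function(hmap, id = NULL) {
  if (inherits(hmap, "habitat_map")) {
    lab <- hmap$squares$habitat
    if (is.null(id)) id <- hmap$section_id
    pid <- hmap$patient_id
  } else {
    lab <- as.character(hmap)
    if (is.null(id)) id <- "S1"
    pid <- id
  }
  lab <- lab[lab != "none"]
  if (length(lab) == 0L)
    stop("no cancer-containing squares: section has no scorable tumour region")
  counts <- as.integer(table(factor(lab, levels = .HABITATS)))
  names(counts) <- .HABITATS
  structure(list(id = id, patient_id = pid, counts = counts,
                 total = sum(counts), fractions = counts / sum(counts)),
            class = "habitat_summary")
}

#' Construct a habitat summary directly from the four counts
#'
#' Convenience for tests and worked examples.
#'
#' @param RpHp,RpHm,RmHp,RmHm habitat square counts.
#' @param patient_id identifier.
#' @return A `habitat_summary`.
#' @export
habitat_summary <- function(RpHp, RpHm, RmHp, RmHm, patient_id = "P1") {
  counts <- c(RpHp = as.integer(RpHp), RpHm = as.integer(RpHm),
              RmHp = as.integer(RmHp), RmHm = as.integer(RmHm))
  stopifnot(all(counts >= 0), sum(counts) > 0)
  structure(list(id = patient_id, patient_id = patient_id, counts = counts,
                 total = sum(counts), fractions = counts / sum(counts)),
            class = "habitat_summary")
}

#' Aggregate section summaries to the patient level
#'
#' Habitat counts are pooled across sections, which is the same as a
#' weighted average of section fractions with weights equal to each
#' section's number of classified squares.
#'
#' @param summaries list of `habitat_summary` objects sharing a patient id
#'   (typically one or two sections).
#' @return A patient-level `habitat_summary`.
#' @export
aggregate_sections <- function(summaries) {
  if (inherits(summaries, "habitat_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 1)
  pids <- unique(vapply(summaries, `[[`, "", "patient_id"))
  if (length(pids) != 1L)
    stop("sections belong to different patients: ",
         paste(pids, collapse = ", "))
  if (length(summaries) > 2L)
    warning("more than two sections for patient ", pids, "; pooling all")
  counts <- Reduce(`+`, lapply(summaries, `[[`, "counts"))
  structure(list(id = pids, patient_id = pids, counts = counts,
                 total = sum(counts), fractions = counts / sum(counts)),
            class = "habitat_summary")
}

#' Tabulate a cohort of habitat summaries
#'
#' @param summaries list of `habitat_summary` objects.
#' @return Data frame: `patient_id`, the four counts, `total`, and the
#'   four fractions (`frac_*`).
#' @export
habitat_table <- function(summaries) {
  if (inherits(summaries, "habitat_summary")) summaries <- list(summaries)
  rows <- lapply(summaries, function(s) {
    data.frame(patient_id = s$patient_id,
               t(s$counts), total = s$total,
               t(stats::setNames(s$fractions, paste0("frac_", .HABITATS))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
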