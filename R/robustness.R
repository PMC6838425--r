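#' @title Spatial robustness sweeps of the EcoScore
#' @name robustness
#' @description
#' The habitat grid is an arbitrary tessellation, so a credible score must
#' not depend on exactly where the grid falls or (within reason) how big
#' its squares are. These sweeps rerun the whole habitat + EcoScore
#' pipeline under displaced grid origins (default 25/50/75 micrometres in
#' both axes at once) and under alternative square sizes (default
#' 50/200/300/500 against the 100 micrometre baseline), re-dichotomize
#' each variant at its own 40th percentile, and report group changes, the
#' relative change of the cohort mean score, and Spearman correlations
#' between variants.
NULL

#' Score a cohort of slides: habitat maps, section pooling, local EcoScore
#'
#' @param slides list of [slide_cell_map()] objects (one or two sections
#'   per patient; pooled by patient id).
#' @param grid a [grid_spec()].
#' @param params a [habitat_params()].
#' @return Data frame `patient_id`, `ecoscore`, ordered by patient id.
#' @export
score_cohort <- function(slides, grid = grid_spec(),
                         params = habitat_params()) {
  if (inherits(slides, "slide_cell_map")) slides <- list(slides)
  pids <- vapply(slides, `[[`, "", "patient_id")
  by_pat <- split(slides, pids)
  rows <- lapply(by_pat, function(secs) {
    summ <- lapply(secs, function(s)
      summarize_habitats(habitat_map(s, grid, params)))
    local_ecoscore(aggregate_sections(summ))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared machinery: score each variant, dichotomize, compare to baseline
.sweep_report <- function(variant_scores, baseline_label, percentile) {
  labels <- names(variant_scores)
  groups <- lapply(variant_scores, dichotomize, percentile = percentile)
  base <- groups[[baseline_label]]
  per_variant <- lapply(labels, function(lb) {
    g <- groups[[lb]]
    stopifnot(identical(g$patient_id, base$patient_id))
    comparable <- g$group != "undefined" & base$group != "undefined"
    finite <- is.finite(g$ecoscore) & is.finite(base$ecoscore)
    mean_change <- if (any(finite))
      abs(mean(g$ecoscore[finite]) - mean(base$ecoscore[finite])) /
        mean(base$ecoscore[finite]) * 100 else NA_real_
    data.frame(variant = lb,
               n_group_changes = sum(g$group[comparable] !=
                                       base$group[comparable]),
               mean_score_change_pct = mean_change,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(cbind, lapply(variant_scores, `[[`, "ecoscore"))
  colnames(scores) <- labels
  rownames(scores) <- base$patient_id
  structure(list(baseline = baseline_label,
                 percentile = percentile,
                 scores = scores,
                 groups = do.call(cbind, lapply(groups, `[[`, "group")),
                 summary = do.call(rbind, per_variant),
                 correlations = variant_correlations(scores)),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> baseline %s, %d variants, %d patients\n",
              x$baseline, ncol(x$scores), nrow(x$scores)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Grid-shift stability sweep
#'
#' Reruns the habitat grid and local EcoScore with the grid origin
#' displaced by each shift in both x and y simultaneously, dichotomizing
#' every variant at its own percentile. A shift equal to the square size
#' reproduces the baseline exactly (tiling periodicity).
#'
#' @param slides list of [slide_cell_map()] objects.
#' @param shifts_um shifts in micrometres; default `c(25, 50, 75)`.
#' @param grid baseline [grid_spec()] (shift 0).
#' @param params a [habitat_params()].
#' @param percentile dichotomization percentile, default 40.
#' @return A `sweep_report`: per-variant scores and groups, group-change
#'   counts and mean relative score change versus baseline, and the
#'   Spearman correlation matrix across variants.
#' @export
grid_shift_sweep <- function(slides, shifts_um = c(25, 50, 75),
                             grid = grid_spec(), params = habitat_params(),
                             percentile = 40) {
  if (any(shifts_um >= grid$square_size_um))
    warning("shift >= square size is equivalent to shift mod square size")
  all_shifts <- c(0, shifts_um)
  labels <- paste0("shift_", all_shifts)
  vs <- stats::setNames(lapply(all_shifts, function(sh) {
    g <- grid_spec(grid$square_size_um,
                   shift_x_um = grid$shift_x_um + sh,
                   shift_y_um = grid$shift_y_um + sh,
                   origin = grid$origin)
    score_cohort(slides, g, params)
  }), labels)
  .sweep_report(vs, "shift_0", percentile)
}

#' Square-size (scale tolerance) sweep
#'
#' Recomputes habitat classification and EcoScore for each square size and
#' dichotomizes each variant at its own percentile. Duplicates of the
#' baseline size are dropped.
#'
#' @param slides list of [slide_cell_map()] objects.
#' @param sizes_um square sizes in micrometres; default
#'   `c(50, 100, 200, 300, 500)` with 100 as baseline.
#' @param baseline_um the baseline square size; default 100.
#' @param params a [habitat_params()].
#' @param percentile dichotomization percentile, default 40.
#' @return A `sweep_report` (see [grid_shift_sweep()]).
#' @export
square_size_sweep <- function(slides, sizes_um = c(50, 100, 200, 300, 500),
                              baseline_um = 100, params = habitat_params(),
                              percentile = 40) {
  sizes <- unique(c(baseline_um, sizes_um))
  labels <- paste0("size_", sizes)
  vs <- stats::setNames(lapply(sizes, function(sz) {
    score_cohort(slides, grid_spec(square_size_um = sz), params)
  }), labels)
  .sweep_report(vs, paste0("size_", baseline_um), percentile)
}

#' Spearman correlations between sweep variants
#'
#' Rank correlations across patients between the score vectors of every
#' pair of variants; infinite scores are handled naturally by the ranks,
#' patients with an undefined score in any variant are dropped.
#'
#' @param scores numeric matrix, patients in rows, variants in columns
#'   (as in a `sweep_report`'s `scores` element), or a `sweep_report`.
#' @return Symmetric correlation matrix.
#' @export
variant_correlations <- function(scores) {
  if (inherits(scores, "sweep_report")) scores <- scores$scores
  stopifnot(is.matrix(scores), ncol(scores) >= 2L)
  ok <- stats::complete.cases(scores)
  if (sum(ok) < 3L) stop("fewer than three patients with defined scores")
  stats::cor(apply(scores[ok, , drop = FALSE], 2, rank),
             method = "spearman")
}
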