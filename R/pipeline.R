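#' @title Cohort pipeline orchestration
#' @name pipeline
#' @description
#' End-to-end drivers tying the stages together: per-sample habitat
#' classification, hotspot detection and global EcoScore; cohort-level
#' scoring, dichotomization, resource and combined groupings, the
#' optimal-percentile survival search, stratified analyses and the
#' robustness sweeps. Every run writes deterministic TSV artifacts plus a
#' JSON manifest recording the configuration, the seed and per-stage
#' counts, so a rerun at the same seed reproduces every output byte.
NULL

#' Default pipeline configuration
#'
#' All defaults are the method's reference values: 100 micrometre squares,
#' habitat thresholds `k_str = 0.5`, `k_lym = 0.2`, EcoScore split at the
#' 40th percentile, mutational-burden split at the 45th, SCNA at 25th/75th,
#' Gi* neighbourhood 100 micrometres with BH correction at 0.05, survival
#' threshold candidates 15-85 step 5 at corrected alpha 0.003.
#'
#' @param ... overrides of individual entries (recorded in the manifest).
#' @return Named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    square_size_um = 100, k_str = 0.5, k_lym = 0.2,
    eco_percentile = 40, mb_percentile = 45, scna_percentiles = c(25, 75),
    hotspot_radius_um = 100, hotspot_alpha = 0.05,
    hotspot_correction = "BH",
    shift_sweep_um = c(25, 50, 75),
    size_sweep_um = c(50, 100, 200, 300, 500),
    threshold_percentiles = seq(15, 85, by = 5),
    alpha_corrected = 0.003,
    five_year = TRUE,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  attr(cfg, "overridden") <- names(over)
  class(cfg) <- "run_config"
  cfg
}

.cfg_grid <- function(cfg) grid_spec(square_size_um = cfg$square_size_um)
.cfg_params <- function(cfg) habitat_params(k_str = cfg$k_str,
                                            k_lym = cfg$k_lym)

#' Run the per-sample stages for one slide
#'
#' Habitat map, habitat summary, hotspot field, nearest-hotspot distances
#' and the global EcoScore; artifacts written as TSV when `out_dir` is
#' given.
#'
#' @param slide a [slide_cell_map()].
#' @param config a [default_config()].
#' @param out_dir optional output directory for TSV artifacts.
#' @return List `habitat_map`, `summary`, `hotspots`, `distances`,
#'   `global_ecoscore`, `log` (named per-stage counts).
#' @export
run_sample <- function(slide, config = default_config(), out_dir = NULL) {
  hm <- habitat_map(slide, .cfg_grid(config), .cfg_params(config))
  summ <- summarize_habitats(hm)
  hf <- hotspot_field(hm, radius_um = config$hotspot_radius_um,
                      alpha = config$hotspot_alpha,
                      correction = config$hotspot_correction)
  dp <- habitat_hotspot_distances(hm, hf)
  ges <- suppressWarnings(global_ecoscore(dp))
  log <- c(n_cells = nrow(slide$cells),
           n_squares = nrow(hm$squares),
           n_habitats = sum(hm$squares$habitat != "none"),
           n_lym_hotspots = sum(hf$squares$hot_lym),
           n_str_hotspots = sum(hf$squares$hot_str))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tag <- sprintf("%s_%s", slide$patient_id, slide$section_id)
    write_table(hm$squares, file.path(out_dir,
                                      sprintf("habitats_%s.tsv", tag)))
    write_table(hf$squares, file.path(out_dir,
                                      sprintf("hotspots_%s.tsv", tag)))
    write_table(dp$squares, file.path(out_dir,
                                      sprintf("distances_%s.tsv", tag)))
  }
  list(habitat_map = hm, summary = summ, hotspots = hf, distances = dp,
       global_ecoscore = ges, log = log)
}

#' Run the full cohort pipeline
#'
#' Scores every slide, pools sections per patient, computes local and
#' global EcoScores, dichotomizes, forms resource and combined groups,
#' runs the threshold search and stratified/subgroup survival analyses
#' (skipped with a warning when the cohort is too small), the robustness
#' sweeps, and writes a manifest.
#'
#' @param slides list of [slide_cell_map()] objects.
#' @param clinical a [clinical_table()] (or `NULL` to skip survival).
#' @param genomic optional data frame with `patient_id`,
#'   `mutational_burden`, `scna_rate`.
#' @param config a [default_config()].
#' @param out_dir optional output directory.
#' @return List of class `cohort_run` with the per-stage results and the
#'   manifest.
#' @export
run_cohort <- function(slides, clinical = NULL, genomic = NULL,
                       config = default_config(), out_dir = NULL) {
  grid <- .cfg_grid(config); params <- .cfg_params(config)
  pids_all <- vapply(slides, `[[`, "", "patient_id")
  by_pat <- split(slides, pids_all)
  summaries <- lapply(by_pat, function(secs)
    aggregate_sections(lapply(secs, function(s)
      summarize_habitats(habitat_map(s, grid, params)))))
  scores <- cohort_ecoscores(summaries)
  eco <- dichotomize(scores, percentile = config$eco_percentile)
  res <- resource_groups(summaries)
  # global EcoScore per patient: pooled distance profiles across sections
  gscores <- vapply(by_pat, function(secs) {
    profs <- lapply(secs, function(s) {
      hm <- habitat_map(s, grid, params)
      hf <- hotspot_field(hm, radius_um = config$hotspot_radius_um,
                          alpha = config$hotspot_alpha,
                          correction = config$hotspot_correction)
      habitat_hotspot_distances(hm, hf)$squares
    })
    suppressWarnings(global_ecoscore(do.call(rbind, profs)))
  }, numeric(1))
  score_tab <- merge(eco, res[, c("patient_id", "resource")],
                     by = "patient_id")
  score_tab$global_ecoscore <- gscores[score_tab$patient_id]
  names(score_tab)[names(score_tab) == "group"] <- "eco_group"
  if (!is.null(genomic)) {
    cg <- combined_eco_mb_group(
      data.frame(patient_id = eco$patient_id, group = eco$group,
                 stringsAsFactors = FALSE),
      genomic, mb_percentile = config$mb_percentile)
    score_tab <- merge(score_tab, cg, by = "patient_id")
  }
  n_pat <- nrow(score_tab)
  survival_res <- NULL
  if (!is.null(clinical) && n_pat >= 10) {
    missing_clin <- setdiff(score_tab$patient_id, clinical$patient_id)
    if (length(missing_clin))
      warning("no clinical record for: ",
              paste(missing_clin, collapse = ", "),
              " (excluded from survival analyses only)")
    eco_named <- data.frame(patient_id = eco$patient_id,
                            group = eco$group, stringsAsFactors = FALSE)
    survival_res <- list(
      km_eco = km_logrank(eco_named, clinical),
      search = threshold_search(scores, clinical,
                                percentiles = config$threshold_percentiles,
                                alpha_corrected = config$alpha_corrected))
    if (!is.null(genomic)) {
      mb <- data.frame(patient_id = genomic$patient_id,
                       value = genomic$mutational_burden,
                       stringsAsFactors = FALSE)
      survival_res$strat_mb <- tryCatch(
        stratified_prognosis(mb, res, clinical,
                             percentiles = config$mb_percentile),
        error = function(e) list(flag = conditionMessage(e)))
      scna <- data.frame(patient_id = genomic$patient_id,
                         value = genomic$scna_rate,
                         stringsAsFactors = FALSE)
      survival_res$strat_scna <- tryCatch(
        stratified_prognosis(scna, res, clinical,
                             percentiles = config$scna_percentiles),
        error = function(e) list(flag = conditionMessage(e)))
    }
    if ("debulking" %in% names(clinical))
      survival_res$debulking_optimal <- tryCatch(
        subgroup_analysis(eco_named, clinical, ~ debulking == "optimal"),
        error = function(e) list(flag = conditionMessage(e)))
  } else if (!is.null(clinical)) {
    warning("cohort of ", n_pat,
            " patients: survival stages skipped (need >= 10)")
  }
  sweeps <- list(
    shift = grid_shift_sweep(slides, shifts_um = config$shift_sweep_um,
                             grid = grid, params = params,
                             percentile = config$eco_percentile),
    size = square_size_sweep(slides, sizes_um = config$size_sweep_um,
                             baseline_um = config$square_size_um,
                             params = params,
                             percentile = config$eco_percentile))
  manifest <- list(
    config = unclass(config),
    overridden = as.list(attr(config, "overridden")),
    seed = config$seed,
    n_patients = n_pat,
    n_sections = length(slides),
    n_cells = sum(vapply(slides, function(s) nrow(s$cells), 0)),
    eco_cutoff = attr(eco, "cutoff"),
    resource_cutoff = attr(res, "cutoff"),
    selected_percentile = if (!is.null(survival_res))
      survival_res$search$selected else NA)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(score_tab, file.path(out_dir, "cohort_scores.tsv"))
    write_table(habitat_table(summaries),
                file.path(out_dir, "habitat_summary.tsv"))
    write_table(sweeps$shift$summary, file.path(out_dir, "sweep_shift.tsv"))
    write_table(sweeps$size$summary, file.path(out_dir, "sweep_size.tsv"))
    if (!is.null(survival_res))
      write_table(survival_res$search$table,
                  file.path(out_dir, "threshold_search.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(summaries = summaries, scores = score_tab,
                 eco_groups = eco, resource = res,
                 survival = survival_res, sweeps = sweeps,
                 manifest = manifest),
            class = "cohort_run")
}
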