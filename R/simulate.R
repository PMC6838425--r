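#' @title Synthetic slides, cohorts and linked clinical tables
#' @name synthetic_data
#' @description
#' Marked point-process simulator producing cell maps with the spatial
#' structure the analysis assumes: cancer cells from a Thomas-type
#' cluster process (Poisson parents, Gaussian offspring) forming tumour
#' nests; stromal cells uniform inside randomly placed circular patches,
#' whose number and size control how "patchy" versus well-distributed the
#' resource field is; lymphocytes from a mixture steered toward (or away
#' from) cancer nests by a co-localization coefficient rho. Positions are
#' wrapped on the torus so realized counts keep their Poisson
#' distributions. Cohort simulation ties survival to the group the real
#' pipeline assigns, so recovery tests exercise the full chain from
#' coordinates to hazard ratios.
NULL

#' Parameters for one simulated tissue section
#'
#' @param extent_um width/height of the section, default `c(2000, 2000)`.
#' @param cancer_parents expected number of tumour-nest centres.
#' @param cancer_per_parent expected offspring (cancer cells) per nest.
#' @param cluster_radius_um Gaussian offspring s.d., default 100.
#' @param stromal_n expected stromal cell count.
#' @param stromal_patches number of circular stromal patches.
#' @param patch_radius_um stromal patch radius, default 300.
#' @param lym_n expected lymphocyte count.
#' @param rho lymphocyte/cancer co-localization in [-1, 1]: fraction
#'   `|rho|` of lymphocytes placed inside (rho > 0) or kept outside
#'   (rho < 0) cancer nests, the rest uniform.
#' @return List of class `slide_sim_params`.
#' @export
slide_sim_params <- function(extent_um = c(2000, 2000),
                             cancer_parents = 10, cancer_per_parent = 120,
                             cluster_radius_um = 100,
                             stromal_n = 800, stromal_patches = 6,
                             patch_radius_um = 300,
                             lym_n = 400, rho = 0) {
  stopifnot(all(extent_um > 0), cancer_parents >= 0, cancer_per_parent >= 0,
            stromal_n >= 0, lym_n >= 0, rho >= -1, rho <= 1,
            cluster_radius_um > 0, patch_radius_um > 0,
            stromal_patches >= 1)
  structure(as.list(environment()), class = "slide_sim_params")
}

# wrap coordinates onto [0, L) torus so counts stay Poisson
.wrap <- function(v, L) ((v %% L) + L) %% L

#' Simulate one tissue section
#'
#' @param params a [slide_sim_params()].
#' @param patient_id,section_id identifiers for the returned map.
#' @param seed optional integer; when given the slide is reproduced
#'   bit-for-bit.
#' @return A [slide_cell_map()].
#' @export
simulate_slide <- function(params = slide_sim_params(),
                           patient_id = "SIM1", section_id = "S1",
                           seed = NULL) {
  stopifnot(inherits(params, "slide_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  W <- params$extent_um[1]; H <- params$extent_um[2]
  if (params$cancer_parents * params$cancer_per_parent <= 0 &&
      params$stromal_n <= 0 && params$lym_n <= 0)
    stop("expected cell count is zero for every class")
  # cancer: Thomas-type cluster process, conditioned on a non-empty tumour
  # (a section without cancer cells has no habitats and is unusable)
  n_par <- stats::rpois(1, params$cancer_parents)
  if (params$cancer_parents > 0 && n_par == 0L) n_par <- 1L
  px <- stats::runif(max(n_par, 1), 0, W)
  py <- stats::runif(max(n_par, 1), 0, H)
  if (n_par > 0) {
    n_off <- stats::rpois(n_par, params$cancer_per_parent)
    if (params$cancer_per_parent > 0 && sum(n_off) == 0L) n_off[1] <- 1L
    cx <- .wrap(rep(px[seq_len(n_par)], n_off) +
                  stats::rnorm(sum(n_off), 0, params$cluster_radius_um), W)
    cy <- .wrap(rep(py[seq_len(n_par)], n_off) +
                  stats::rnorm(sum(n_off), 0, params$cluster_radius_um), H)
  } else cx <- cy <- numeric(0)
  # stroma: uniform within random circular patches
  n_str <- stats::rpois(1, params$stromal_n)
  patch_x <- stats::runif(params$stromal_patches, 0, W)
  patch_y <- stats::runif(params$stromal_patches, 0, H)
  if (n_str > 0) {
    which_patch <- sample.int(params$stromal_patches, n_str, replace = TRUE)
    r <- params$patch_radius_um * sqrt(stats::runif(n_str))
    th <- stats::runif(n_str, 0, 2 * pi)
    sx <- .wrap(patch_x[which_patch] + r * cos(th), W)
    sy <- .wrap(patch_y[which_patch] + r * sin(th), H)
  } else sx <- sy <- numeric(0)
  # lymphocytes: |rho| co-localized with (or excluded from) nests
  n_lym <- stats::rpois(1, params$lym_n)
  lx <- ly <- numeric(0)
  if (n_lym > 0) {
    n_co <- stats::rbinom(1, n_lym, abs(params$rho))
    ux <- stats::runif(n_lym - n_co, 0, W)
    uy <- stats::runif(n_lym - n_co, 0, H)
    if (n_co > 0 && n_par > 0) {
      if (params$rho > 0) {
        par_idx <- sample.int(n_par, n_co, replace = TRUE)
        vx <- .wrap(px[par_idx] + stats::rnorm(n_co, 0, params$cluster_radius_um), W)
        vy <- .wrap(py[par_idx] + stats::rnorm(n_co, 0, params$cluster_radius_um), H)
      } else {
        # rejection-sample points away from every nest centre
        vx <- vy <- numeric(0)
        excl <- 2 * params$cluster_radius_um
        tries <- 0L
        while (length(vx) < n_co && tries < 50L) {
          need <- n_co - length(vx)
          tx <- stats::runif(2 * need, 0, W); ty <- stats::runif(2 * need, 0, H)
          d2 <- outer(tx, px[seq_len(n_par)], "-")^2 +
            outer(ty, py[seq_len(n_par)], "-")^2
          far <- apply(d2, 1, min) > excl^2
          vx <- c(vx, tx[far]); vy <- c(vy, ty[far])
          tries <- tries + 1L
        }
        vx <- vx[seq_len(min(n_co, length(vx)))]
        vy <- vy[seq_len(min(n_co, length(vy)))]
        # fall back to uniform if exclusion is infeasible
        if (length(vx) < n_co) {
          k <- n_co - length(vx)
          vx <- c(vx, stats::runif(k, 0, W))
          vy <- c(vy, stats::runif(k, 0, H))
        }
      }
    } else { vx <- vy <- numeric(0); ux <- c(ux, stats::runif(n_co, 0, W));
             uy <- c(uy, stats::runif(n_co, 0, H)) }
    lx <- c(ux, vx); ly <- c(uy, vy)
  }
  cells <- data.frame(
    x = round(c(cx, sx, lx), 2),
    y = round(c(cy, sy, ly), 2),
    cell_class = c(rep("cancer", length(cx)),
                   rep("stromal", length(sx)),
                   rep("lymphocyte", length(lx))),
    stringsAsFactors = FALSE)
  if (nrow(cells) == 0L) stop("simulated slide has no cells")
  slide_cell_map(cells, patient_id = patient_id, section_id = section_id)
}

#' Parameters for a simulated cohort
#'
#' Patients span a ladder of microenvironment archetypes: stromal patch
#' number and lymphocyte co-localization vary monotonically across the
#' cohort from resource-rich/low-hazard (high EcoScore) to
#' resource-poor/high-hazard (low EcoScore), which yields well-separated
#' scores. Survival is exponential with the hazard multiplied by
#' `exp(beta_eco)` for patients the pipeline itself scores as high
#' EcoScore, and optionally by `exp(beta_mb)` per low-mutational-burden
#' indicator within a resource stratum. Censoring is independent uniform,
#' calibrated to the requested rate.
#'
#' @param n_patients number of patients (>= 2).
#' @param sections_per_patient 1 or 2.
#' @param base_hazard baseline event rate per month, default 0.03
#'   (median survival about 23 months, typical of advanced HGSOC).
#' @param beta_eco log hazard ratio of the high-EcoScore group.
#' @param beta_mb optional log-HR of low mutational burden; applied in
#'   the stratum named by `mb_effect_stratum` (`"both"`, `"high"` or
#'   `"low"` resource) to emulate context-dependent prognosis.
#' @param mb_effect_stratum see `beta_mb`.
#' @param censoring target censoring fraction in [0, 1), default 0.3.
#' @param mb_cor target Spearman-scale correlation between mutational
#'   burden and realized lymphocyte abundance (|r| <= 0.95).
#' @param rho_range,patches_range ladders of lymphocyte co-localization
#'   and stromal patch counts across the cohort.
#' @param gap separation parameter in [0, 0.35]: pushes the archetype
#'   ladder away from its 40th-percentile point, opening a gap in the
#'   score distribution around the dichotomization boundary. 0 (default)
#'   is a uniform ladder; use a positive gap when a stability analysis
#'   needs between-group separation to exceed within-patient grid noise.
#' @param slide extra per-slide parameters (a [slide_sim_params()] used
#'   as the template).
#' @param seed master seed.
#' @return List of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 20, sections_per_patient = 2,
                              base_hazard = 0.03, beta_eco = log(2),
                              beta_mb = 0, mb_effect_stratum = "both",
                              censoring = 0.3, mb_cor = 0.3,
                              rho_range = c(0.7, -0.3),
                              patches_range = c(3L, 12L), gap = 0,
                              slide = slide_sim_params(), seed = 1L) {
  stopifnot(n_patients >= 2, sections_per_patient %in% 1:2,
            censoring >= 0, censoring < 1, gap >= 0, gap <= 0.35)
  if (abs(mb_cor) > 0.95)
    stop("requested mutational-burden correlation is infeasible (|r| > 0.95)")
  structure(as.list(environment()), class = "cohort_sim_params")
}

# uniform-censoring upper bound hitting a target censoring fraction for a
# mix of exponential rates
.censor_bound <- function(rates, target) {
  if (target <= 0) return(Inf)
  f <- function(m) mean((1 - exp(-rates * m)) / (rates * m)) - target
  stats::uniroot(f, c(1e-6, 1e5))$root
}

#' Simulate a cohort: slides, clinical table, genomic table
#'
#' Slides are generated per patient, scored with the real habitat +
#' EcoScore pipeline (default grid and thresholds, 40th-percentile
#' dichotomization, resource split at the median), and survival times are
#' then drawn from an exponential model whose hazard depends on those
#' pipeline-assigned groups.
#'
#' @param params a [cohort_sim_params()].
#' @return List of class `sim_cohort`: `slides` (list of
#'   [slide_cell_map()]), `clinical` (a [clinical_table()], untruncated
#'   times), `genomic` (data frame `patient_id`, `mutational_burden`,
#'   `scna_rate`, `lym_abundance`), `scores`, `eco_groups`,
#'   `resource` and the `params`.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  # archetype ladder over [0, 1]; a positive gap opens a hole around the
  # 40th-percentile point so the score split falls between two separated
  # blocks rather than inside a crowded middle
  u <- seq(0, 1, length.out = n)
  if (params$gap > 0) {
    lo <- u < 0.4
    u[lo] <- u[lo] * (0.4 - params$gap) / 0.4
    u[!lo] <- (0.4 + params$gap) + (u[!lo] - 0.4) * (0.6 - params$gap) / 0.6
  }
  rho <- params$rho_range[1] + u * diff(params$rho_range)
  patches <- round(params$patches_range[1] + u * diff(params$patches_range))
  pids <- sprintf("P%03d", seq_len(n))
  slides <- list()
  for (k in seq_len(n)) {
    sp <- params$slide
    sp$stromal_patches <- patches[k]
    sp$rho <- rho[k]
    for (sec in seq_len(params$sections_per_patient)) {
      slides[[length(slides) + 1L]] <-
        simulate_slide(sp, patient_id = pids[k],
                       section_id = paste0("S", sec))
    }
  }
  # run the real pipeline to get the groups the hazard acts on
  summaries <- lapply(split(slides, vapply(slides, `[[`, "", "patient_id")),
                      function(secs)
                        aggregate_sections(lapply(secs, function(s)
                          summarize_habitats(habitat_map(s)))))
  summaries <- summaries[pids]
  scores <- cohort_ecoscores(summaries)
  eco <- dichotomize(scores, percentile = 40)
  res <- resource_groups(summaries)
  # lymphocyte abundance: fraction of all detected cells that are lymphocytes
  lym_ab <- vapply(split(slides, vapply(slides, `[[`, "", "patient_id")),
                   function(secs) {
                     cls <- unlist(lapply(secs, function(s) s$cells$cell_class))
                     mean(cls == "lymphocyte")
                   }, numeric(1))[pids]
  # genomic measures via a Gaussian copula against lymphocyte abundance
  r <- params$mb_cor
  z_l <- as.vector(scale(lym_ab))
  if (any(!is.finite(z_l))) z_l <- stats::rnorm(n)
  z_mb <- r * z_l + sqrt(1 - r^2) * stats::rnorm(n)
  mb <- stats::qnbinom(stats::pnorm(z_mb), size = 8, mu = 60)
  scna <- stats::qnbinom(stats::pnorm(stats::rnorm(n)), size = 5, mu = 30)
  genomic <- data.frame(patient_id = pids, mutational_burden = mb,
                        scna_rate = scna, lym_abundance = unname(lym_ab),
                        stringsAsFactors = FALSE)
  # survival: exponential hazard tied to pipeline-assigned groups
  hi <- eco$group == "high"
  mb_low <- mb <= quantile_cut(mb, 45)
  in_stratum <- switch(params$mb_effect_stratum,
                       both = rep(TRUE, n),
                       high = res$resource == "high",
                       low = res$resource == "low")
  rates <- params$base_hazard *
    exp(params$beta_eco * hi + params$beta_mb * (mb_low & in_stratum))
  t_ev <- stats::rexp(n, rates)
  cmax <- .censor_bound(rates, params$censoring)
  c_t <- if (is.finite(cmax)) stats::runif(n, 0, cmax) else rep(Inf, n)
  os <- pmax(pmin(t_ev, c_t), 0.01)
  ev <- as.integer(t_ev <= c_t)
  clin <- clinical_table(
    data.frame(patient_id = pids, os_months = round(os, 3), os_event = ev,
               debulking = sample(c("optimal", "suboptimal"), n, TRUE),
               age = round(stats::rnorm(n, 62, 9), 1),
               stage = sample(c("III", "IV"), n, TRUE, prob = c(0.75, 0.25)),
               stringsAsFactors = FALSE),
    five_year = FALSE)
  structure(list(slides = slides, clinical = clin, genomic = genomic,
                 scores = scores, eco_groups = eco, resource = res,
                 summaries = summaries, params = params),
            class = "sim_cohort")
}

#' Write a preset fixture cohort to disk
#'
#' Presets: `tiny` (3 patients, one small section each — the copy checked
#' into the package's extdata), `demo` (20 patients, two sections) and
#' `stress` (200 patients, one section, smaller slides, for the
#' threshold-search simulations). Writes one cell TSV per section, a
#' clinical TSV, a genomic TSV and a JSON manifest holding the generating
#' seed, so the fixture can be regenerated byte-for-byte.
#'
#' @param name `"tiny"`, `"demo"` or `"stress"`.
#' @param dir output directory (created if needed).
#' @param seed master seed, default 20 (recorded in the manifest).
#' @return The manifest as a list, invisibly.
#' @export
make_fixture <- function(name = c("tiny", "demo", "stress"), dir,
                         seed = 20L) {
  name <- match.arg(name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- switch(name,
    tiny = cohort_sim_params(
      n_patients = 3, sections_per_patient = 1, seed = seed,
      slide = slide_sim_params(extent_um = c(1000, 1000),
                               cancer_parents = 5, cancer_per_parent = 60,
                               stromal_n = 250, lym_n = 120)),
    demo = cohort_sim_params(n_patients = 20, sections_per_patient = 2,
                             seed = seed),
    stress = cohort_sim_params(
      n_patients = 200, sections_per_patient = 1, seed = seed,
      slide = slide_sim_params(extent_um = c(1200, 1200),
                               cancer_parents = 6, cancer_per_parent = 80,
                               stromal_n = 350, lym_n = 180)))
  sim <- simulate_cohort(cp)
  for (s in sim$slides)
    write_cell_map(s, file.path(dir, sprintf("cells_%s_%s.tsv",
                                             s$patient_id, s$section_id)))
  write_table(as.data.frame(sim$clinical), file.path(dir, "clinical.tsv"))
  write_table(sim$genomic, file.path(dir, "genomic.tsv"))
  manifest <- list(preset = name, seed = seed,
                   n_patients = cp$n_patients,
                   sections_per_patient = cp$sections_per_patient,
                   n_sections = length(sim$slides),
                   n_cells = sum(vapply(sim$slides,
                                        function(s) nrow(s$cells), 0)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture cohort back from disk
#'
#' @param dir directory written by [make_fixture()].
#' @param five_year apply five-year censoring to the clinical table.
#' @return List `slides`, `clinical`, `genomic`, `manifest`.
#' @export
read_fixture <- function(dir, five_year = TRUE) {
  files <- sort(list.files(dir, pattern = "^cells_.*\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no cell tables found in ", dir)
  slides <- lapply(files, read_cell_map)
  clin <- read_clinical(file.path(dir, "clinical.tsv"),
                        five_year = five_year)
  gen <- utils::read.table(file.path(dir, "genomic.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  list(slides = slides, clinical = clin, genomic = gen, manifest = man)
}
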