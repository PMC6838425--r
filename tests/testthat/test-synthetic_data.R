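test_that("slide simulation is deterministic under a seed", {
  p <- slide_sim_params(extent_um = c(800, 800), cancer_parents = 4,
                        cancer_per_parent = 50, stromal_n = 150, lym_n = 80)
  a <- simulate_slide(p, seed = 42)
  b <- simulate_slide(p, seed = 42)
  expect_identical(a$cells, b$cells)
  c2 <- simulate_slide(p, seed = 43)
  expect_false(identical(a$cells, c2$cells))
})

test_that("zero lymphocyte intensity yields an all-low-hazard section", {
  p <- slide_sim_params(extent_um = c(800, 800), cancer_parents = 5,
                        cancer_per_parent = 60, stromal_n = 200, lym_n = 0)
  sl <- simulate_slide(p, seed = 7)
  expect_false(any(sl$cells$cell_class == "lymphocyte"))
  hm <- habitat_map(sl)
  hab <- hm$squares$habitat[hm$squares$habitat != "none"]
  expect_true(all(hab %in% c("RpHm", "RmHm")))
})

test_that("realized class counts follow their Poisson expectations", {
  p <- slide_sim_params(extent_um = c(600, 600), cancer_parents = 6,
                        cancer_per_parent = 40, stromal_n = 180, lym_n = 90)
  set.seed(99)
  counts <- t(vapply(1:100, function(k) {
    sl <- simulate_slide(p)
    tab <- table(factor(sl$cells$cell_class,
                        levels = c("cancer", "stromal", "lymphocyte")))
    as.numeric(tab)
  }, numeric(3)))
  # mean realized counts within 3 s.e. of the (compound) Poisson means
  mu <- c(6 * 40, 180, 90)
  # cancer is a cluster process: var = E[N_par]*(mu_off + mu_off^2)
  v <- c(6 * (40 + 40^2), 180, 90)
  se <- sqrt(v / 100)
  expect_true(all(abs(colMeans(counts) - mu) < 3 * se))
})

test_that("stromal patchiness drives the high-resource habitat fraction", {
  set.seed(13)
  frac_rp <- vapply(c(2, 6, 14), function(np) {
    mean(vapply(1:4, function(k) {
      sl <- simulate_slide(slide_sim_params(
        extent_um = c(1200, 1200), cancer_parents = 6,
        cancer_per_parent = 80, stromal_n = 500,
        stromal_patches = np, lym_n = 0))
      s <- summarize_habitats(habitat_map(sl))
      s$fractions[["RpHp"]] + s$fractions[["RpHm"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(frac_rp[1] < frac_rp[2] && frac_rp[2] < frac_rp[3])
})

test_that("lymphocyte co-localization, not abundance, drives hazard", {
  set.seed(14)
  frac_hp <- vapply(c(-0.5, 0, 0.8), function(rho) {
    mean(vapply(1:4, function(k) {
      sl <- simulate_slide(slide_sim_params(
        extent_um = c(1200, 1200), cancer_parents = 6,
        cancer_per_parent = 80, stromal_n = 300, lym_n = 250, rho = rho))
      s <- summarize_habitats(habitat_map(sl))
      s$fractions[["RpHp"]] + s$fractions[["RmHp"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(frac_hp[1] < frac_hp[3])
  expect_true(frac_hp[2] < frac_hp[3])
})

test_that("cohort simulation ties survival to pipeline-assigned groups", {
  cp <- cohort_sim_params(n_patients = 12, sections_per_patient = 2,
                          beta_eco = log(2), seed = 5)
  sim <- simulate_cohort(cp)
  expect_equal(length(sim$slides), 24)
  expect_equal(nrow(sim$clinical), 12)
  expect_equal(sort(sim$scores$patient_id), sort(sim$genomic$patient_id))
  # two sections pooled equals patient-level aggregation by construction
  p1 <- sim$slides[vapply(sim$slides, `[[`, "", "patient_id") == "P001"]
  agg <- aggregate_sections(lapply(p1, function(s)
    summarize_habitats(habitat_map(s))))
  expect_equal(agg$counts, sim$summaries[["P001"]]$counts)
  # null effect: confidence interval straddles 1 under beta_eco = 0
  cp0 <- cohort_sim_params(n_patients = 60, sections_per_patient = 1,
                           beta_eco = 0, censoring = 0.2, seed = 6,
                           slide = slide_sim_params(
                             extent_um = c(1000, 1000), cancer_parents = 5,
                             cancer_per_parent = 60, stromal_n = 250,
                             lym_n = 120))
  sim0 <- simulate_cohort(cp0)
  cl0 <- sim0$clinical
  cl0$high <- as.integer(sim0$eco_groups$group[
    match(cl0$patient_id, sim0$eco_groups$patient_id)] == "high")
  cx <- cox_fit(cl0, "high")
  expect_true(cx$ci_lo < 1 && 1 < cx$ci_hi)
})

test_that("infeasible genomic correlation is rejected", {
  expect_error(cohort_sim_params(mb_cor = 0.99), "infeasible")
})

test_that("fixtures regenerate byte-identically from the manifest seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_fixture("tiny", d1, seed = 20)
  make_fixture("tiny", d2, seed = 20)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  fx <- read_fixture(d1)
  expect_equal(length(fx$slides), 3)
  expect_true(all(vapply(fx$slides, function(s) nrow(s$cells), 0) <= 2000))
  expect_equal(fx$manifest$seed, 20)
})

test_that("the shipped tiny fixture matches its generator output", {
  shipped <- system.file("extdata", "tiny", package = "ecohab")
  expect_true(dir.exists(shipped))
  fresh <- withr::local_tempdir()
  make_fixture("tiny", fresh, seed = 20)
  for (f in sort(list.files(shipped)))
    expect_identical(readLines(file.path(shipped, f)),
                     readLines(file.path(fresh, f)))
})
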