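test_that("log-rank on identical groups is zero; hand tally matches", {
  cl <- clinical_table(data.frame(
    patient_id = c("A", "B", "C", "D"),
    os_months = c(5, 9, 5, 9), os_event = c(1, 1, 1, 1),
    stringsAsFactors = FALSE), five_year = FALSE)
  g <- data.frame(patient_id = c("A", "B", "C", "D"),
                  group = c("g1", "g1", "g2", "g2"),
                  stringsAsFactors = FALSE)
  kl <- km_logrank(g, cl)
  expect_equal(kl$chisq, 0, tolerance = 1e-12)
  expect_equal(kl$p, 1)

  # 4-patient example against the risk-set tally oracle
  cl2 <- clinical_table(data.frame(
    patient_id = c("A", "B", "C", "D"),
    os_months = c(1, 2, 3, 4), os_event = c(1, 1, 1, 1),
    stringsAsFactors = FALSE), five_year = FALSE)
  g2 <- data.frame(patient_id = c("A", "B", "C", "D"),
                   group = c("a", "a", "b", "b"), stringsAsFactors = FALSE)
  kl2 <- km_logrank(g2, cl2)
  expect_equal(kl2$chisq,
               oracle_logrank_chisq(c(1, 2, 3, 4), rep(1, 4),
                                    c("a", "a", "b", "b")),
               tolerance = 1e-10)
})

test_that("KM estimate without censoring equals the empirical survivor", {
  set.seed(1)
  n <- 40
  cl <- clinical_table(data.frame(
    patient_id = as.character(1:n), os_months = sample(1:100, n),
    os_event = 1L, group = "all", g2 = rep(c("x", "y"), n / 2),
    stringsAsFactors = FALSE), five_year = FALSE)
  kl <- km_logrank(data.frame(patient_id = cl$patient_id, group = cl$g2),
                   cl)
  sf <- kl$fit
  # pooled check per stratum: S(t) = fraction of that group's times > t
  times_by <- split(cl$os_months, cl$g2)
  st <- summary(sf)
  for (lv in names(times_by)) {
    idx <- st$strata == paste0("g=", lv)
    emp <- vapply(st$time[idx],
                  function(t) mean(times_by[[lv]] > t), numeric(1))
    expect_equal(st$surv[idx], emp)
  }
})

test_that("log-rank equals the Cox score test on ties-free data", {
  set.seed(12)
  cl <- sim_survival_cohort(120, hr = 1.8)
  kl <- km_logrank(data.frame(patient_id = cl$patient_id, group = cl$group),
                   cl)
  fit <- survival::coxph(
    survival::Surv(os_months, os_event) ~ group, data = cl, ties = "efron")
  expect_equal(kl$chisq, unname(summary(fit)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("Cox fit recovers a known hazard ratio and is stable under duplication", {
  set.seed(2)
  cl <- sim_survival_cohort(500, hr = 2)
  cl$high <- as.integer(cl$group == "high")
  cx <- cox_fit(cl, "high")
  expect_gt(cx$hr, 1.4); expect_lt(cx$hr, 2.8)
  expect_true(cx$ci_lo < cx$hr && cx$hr < cx$ci_hi)
  # duplicating every patient leaves the estimate essentially unchanged
  # (duplication creates ties, so the Efron approximation perturbs the
  # partial likelihood slightly; exact invariance holds only ties-free)
  dup <- cl; dup$patient_id <- paste0(dup$patient_id, "_d")
  both <- clinical_table(rbind(as.data.frame(cl), as.data.frame(dup)),
                         five_year = FALSE)
  expect_equal(cox_fit(both, "high")$hr, cx$hr, tolerance = 0.01)
})

test_that("Cox fit validates covariates and warns on few events", {
  cl <- sim_survival_cohort(30)
  cl$const <- 1
  expect_error(cox_fit(cl, "const"), "constant")
  few <- cl[1:8, ]; few$high <- as.integer(few$group == "high")
  class(few) <- c("clinical_table", "data.frame")
  expect_warning(cox_fit(few, "high"), "10 events")
})

test_that("univariate scope fits covariates separately, multivariate jointly", {
  set.seed(31)
  cl <- sim_survival_cohort(200, hr = 2)
  cl$high <- as.integer(cl$group == "high")
  cl$noise <- rnorm(200)
  uni <- cox_fit(cl, c("high", "noise"), "univariate")
  multi <- cox_fit(cl, c("high", "noise"), "multivariate")
  expect_equal(nrow(uni), 2); expect_equal(nrow(multi), 2)
  solo <- cox_fit(cl, "high", "univariate")
  expect_equal(uni$hr[uni$covariate == "high"], solo$hr)
})

test_that("threshold search with one candidate reduces to a single log-rank", {
  set.seed(41)
  cl <- sim_survival_cohort(80, hr = 2.5)
  sc <- data.frame(patient_id = cl$patient_id,
                   ecoscore = rnorm(80) + 2 * (cl$group == "high"),
                   stringsAsFactors = FALSE)
  ts <- threshold_search(sc, cl, percentiles = 40, alpha_corrected = 0.05)
  cutoff <- quantile_cut(sc$ecoscore, 40)
  grp <- data.frame(patient_id = sc$patient_id,
                    group = ifelse(sc$ecoscore <= cutoff, "low", "high"),
                    stringsAsFactors = FALSE)
  kl <- km_logrank(grp, cl)
  expect_equal(ts$table$chisq, kl$chisq, tolerance = 1e-10)
  expect_equal(ts$table$p, kl$p, tolerance = 1e-10)
})

test_that("threshold search skips degenerate splits and selects the min p", {
  set.seed(51)
  cl <- sim_survival_cohort(60, hr = 3, censoring = 0.2)
  sc <- data.frame(patient_id = cl$patient_id,
                   ecoscore = ifelse(cl$group == "high", 2, 1),
                   stringsAsFactors = FALSE)
  # many candidate percentiles give the same attained cutoff; none empty
  expect_warning(ts <- threshold_search(sc, cl), NA)
  tab <- ts$table
  expect_equal(nrow(tab), 15)
  if (any(tab$significant))
    expect_equal(min(tab$p[tab$significant]),
                 tab$p[tab$percentile == ts$selected][1])
  # all-equal scores: every split degenerate, nothing selected
  sc2 <- transform(sc, ecoscore = 1)
  ts2 <- threshold_search(sc2, cl)
  expect_true(all(ts2$table$skipped))
  expect_true(is.na(ts2$selected))
})

test_that("stratified prognosis splits measures within each stratum", {
  set.seed(61)
  n <- 120
  resource <- rep(c("low", "high"), each = n / 2)
  mb <- rnorm(n, 60, 15)
  # MB protective only in the high-resource stratum
  rate <- 0.05 * exp(ifelse(resource == "high" & mb <= quantile(mb, 0.45),
                            log(3), 0))
  cl <- clinical_table(data.frame(
    patient_id = sprintf("S%03d", 1:n),
    os_months = pmax(rexp(n, rate), 0.01), os_event = 1L,
    stringsAsFactors = FALSE), five_year = FALSE)
  sp <- stratified_prognosis(
    data.frame(patient_id = cl$patient_id, value = mb),
    data.frame(patient_id = cl$patient_id, resource = resource),
    cl, percentiles = 45)
  expect_named(sp, c("high", "low"))
  expect_s3_class(sp$high$logrank, "km_logrank")
  expect_lt(sp$high$logrank$p, 0.05)
  # constant measure in a stratum is flagged, not fitted
  sp2 <- suppressWarnings(stratified_prognosis(
    data.frame(patient_id = cl$patient_id,
               value = ifelse(resource == "low", 1, mb)),
    data.frame(patient_id = cl$patient_id, resource = resource),
    cl, percentiles = 45))
  expect_equal(sp2$low$flag, "constant measure in stratum")
})

test_that("three-group percentile split uses 25th/75th boundaries", {
  x <- 1:100
  g <- percentile_groups(x, c(25, 75))
  expect_equal(sum(g == "low"), 25)
  expect_equal(sum(g == "medium"), 50)
  expect_equal(sum(g == "high"), 25)
  expect_true(is.na(percentile_groups(c(x, NA), c(25, 75))[101]))
})

test_that("subgroup analysis restricted to everyone matches the full cohort", {
  set.seed(71)
  cl <- sim_survival_cohort(100, hr = 2)
  cl$debulking <- "optimal"
  g <- data.frame(patient_id = cl$patient_id, group = cl$group,
                  stringsAsFactors = FALSE)
  full <- km_logrank(g, cl)
  sub <- subgroup_analysis(g, cl, ~ debulking == "optimal")
  expect_equal(sub$logrank$chisq, full$chisq)
  expect_error(subgroup_analysis(g, cl, ~ debulking == "none"), "every")
})

test_that("Jonckheere statistic and exact p match full enumeration", {
  x <- c(1, 2, 3, 4, 5, 6)
  g <- c("a", "a", "b", "b", "c", "c")
  jt <- jonckheere_test(x, g)
  expect_equal(jt$statistic, oracle_jt_stat(x, g))
  expect_equal(jt$p, oracle_jt_exact_p(x, g))
  # a tied configuration
  x2 <- c(2, 2, 3, 3, 5, 1)
  jt2 <- jonckheere_test(x2, g)
  expect_equal(jt2$statistic, oracle_jt_stat(x2, g))
  expect_equal(jt2$p, oracle_jt_exact_p(x2, g))
  expect_error(jonckheere_test(x, rep("a", 6)), "2 groups")
})

test_that("large-sample Jonckheere uses the tie-corrected normal tail", {
  set.seed(81)
  x <- c(rnorm(15, 0), rnorm(15, 0.8), rnorm(15, 1.6))
  g <- rep(c("g1", "g2", "g3"), each = 15)
  jt <- jonckheere_test(x, g)
  expect_match(jt$method, "normal")
  expect_lt(jt$p, 0.05)
  # no trend: p should be comfortably nonsignificant on average
  x0 <- rnorm(45)
  jt0 <- jonckheere_test(x0, g)
  expect_gt(jt0$p, 0.001)
})

test_that("wilcoxon and spearman wrappers give the standard two-sided answers", {
  expect_equal(association_tests(c(1, 2, 3, 1, 2, 3),
                                 rep(c("u", "v"), each = 3),
                                 kind = "wilcoxon")$p, 1)
  sp <- association_tests(1:10, (1:10)^2, kind = "spearman")
  expect_equal(sp$statistic, 1)
})
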