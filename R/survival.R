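#' @title Survival machinery: KM/log-rank/Cox, threshold search, strata
#' @name survival_stats
#' @description
#' Standard survival analysis (Kaplan-Meier curves, k-group log-rank
#' tests, Cox proportional-hazards fits with Efron tie handling, via the
#' survival package) plus the cohort procedures specific to this
#' pipeline: the Bonferroni-corrected optimal-percentile threshold search
#' (candidates every 5th percentile from 15 to 85, significance at
#' p < 0.003), resource-stratified prognosis of genomic measures
#' (mutational burden split at the 45th percentile; SCNA at the 25th/75th
#' into three groups), subgroup analyses such as restriction to optimally
#' debulked patients, and the rank/trend association tests (Jonckheere,
#' Wilcoxon, Spearman).
NULL

.merge_groups <- function(groups, clinical, group_col = "group") {
  stopifnot(inherits(clinical, "clinical_table") || is.data.frame(clinical))
  cl <- as.data.frame(clinical)
  cl <- cl[, setdiff(names(cl), group_col), drop = FALSE]
  m <- merge(groups[, c("patient_id", group_col)], cl, by = "patient_id")
  m <- m[!is.na(m[[group_col]]) & m[[group_col]] != "undefined", ,
         drop = FALSE]
  m
}

#' Kaplan-Meier curves and log-rank test between patient groups
#'
#' @param groups data frame with `patient_id` and a group column.
#' @param clinical a [clinical_table()].
#' @param group_col name of the group column, default `"group"`.
#' @return List of class `km_logrank`: `fit` (a `survfit`), `chisq`, `df`,
#'   `p`, per-group table `groups` (n, events), and `zero_event_groups`.
#' @export
km_logrank <- function(groups, clinical, group_col = "group") {
  m <- .merge_groups(groups, clinical, group_col)
  g <- factor(m[[group_col]])
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  if (any(m$os_months <= 0)) stop("survival times must be positive")
  sv <- survival::Surv(m$os_months, m$os_event)
  sd <- survival::survdiff(sv ~ g)
  chisq <- unname(sd$chisq)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  tab <- data.frame(group = levels(g),
                    n = as.vector(table(g)),
                    events = as.vector(tapply(m$os_event, g, sum)))
  zero <- tab$group[tab$events == 0]
  if (length(zero))
    warning("group(s) with zero events: ", paste(zero, collapse = ", "))
  structure(list(fit = survival::survfit(sv ~ g), chisq = chisq, df = df,
                 p = p, groups = tab, zero_event_groups = zero,
                 n = nrow(m)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> %d patients, chisq = %.3f on %d df, p = %.4g\n",
              x$n, x$chisq, x$df, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood estimation with Efron handling of ties. Univariate
#' scope fits each covariate in its own model; multivariate fits them
#' jointly. Constant covariates are an error; fewer than ten events per
#' fitted covariate draws a warning.
#'
#' @param clinical a [clinical_table()] whose columns include the
#'   covariates (merge scores/groups in beforehand).
#' @param covariates character vector of column names.
#' @param scope `"univariate"` or `"multivariate"`.
#' @return Data frame of class `cox_result`: one row per covariate level
#'   with `covariate`, `hr`, `ci_lo`, `ci_hi`, `p`, `scope`, plus
#'   attribute `fits` (the underlying `coxph` objects).
#' @export
cox_fit <- function(clinical, covariates,
                    scope = c("univariate", "multivariate")) {
  scope <- match.arg(scope)
  df <- as.data.frame(clinical)
  stopifnot(all(covariates %in% names(df)))
  for (cv in covariates) {
    v <- df[[cv]][!is.na(df[[cv]])]
    if (length(unique(v)) < 2L)
      stop("constant covariate: ", cv)
  }
  n_events <- sum(df$os_event)
  fit_one <- function(vars) {
    if (n_events < 10 * length(vars))
      warning("fewer than 10 events per covariate (",
              n_events, " events, ", length(vars), " covariate(s))")
    fm <- stats::as.formula(paste(
      "survival::Surv(os_months, os_event) ~",
      paste(sprintf("`%s`", vars), collapse = " + ")))
    fit <- survival::coxph(fm, data = df, ties = "efron")
    if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
      stop("Cox model did not converge for: ", paste(vars, collapse = ", "))
    s <- summary(fit)
    co <- s$coefficients; ci <- s$conf.int
    res <- data.frame(covariate = rownames(co),
                      hr = unname(co[, "exp(coef)"]),
                      ci_lo = unname(ci[, "lower .95"]),
                      ci_hi = unname(ci[, "upper .95"]),
                      p = unname(co[, "Pr(>|z|)"]),
                      scope = scope, stringsAsFactors = FALSE)
    # flag likely separation: coefficient running away
    res$flag <- ifelse(abs(co[, "coef"]) > 15, "possible separation", "")
    list(res = res, fit = fit)
  }
  if (scope == "univariate") {
    parts <- lapply(covariates, function(cv) fit_one(cv))
    out <- do.call(rbind, lapply(parts, `[[`, "res"))
    fits <- lapply(parts, `[[`, "fit")
  } else {
    one <- fit_one(covariates)
    out <- one$res
    fits <- list(one$fit)
  }
  rownames(out) <- NULL
  class(out) <- c("cox_result", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' Bonferroni-corrected optimal-percentile threshold search
#'
#' Every 5th percentile from 15 to 85 of the score is tried as a
#' dichotomizing cutoff (inverse-ECDF, boundary to the low group); each
#' split is tested by two-group log-rank. Candidates with p < 0.003 (the
#' 0.05 level Bonferroni-corrected for the 15 candidates, applied at the
#' printed precision) are significant, and the one with the smallest p is
#' selected; if none passes, nothing is selected. Candidates whose split
#' leaves a group empty are skipped and recorded.
#'
#' @param scores data frame `patient_id`, `ecoscore` (column configurable).
#' @param clinical a [clinical_table()].
#' @param percentiles candidate percentiles, default `seq(15, 85, by = 5)`.
#' @param alpha_corrected significance threshold on the log-rank p,
#'   default 0.003.
#' @param score_col score column name.
#' @return List of class `threshold_search`: `table` (per-candidate
#'   percentile, cutoff, group sizes, chisq, p, significant, skipped),
#'   `selected` (percentile or `NA`), `alpha_corrected`.
#' @export
threshold_search <- function(scores, clinical,
                             percentiles = seq(15, 85, by = 5),
                             alpha_corrected = 0.003,
                             score_col = "ecoscore") {
  m <- merge(scores, as.data.frame(clinical), by = "patient_id")
  m <- m[!is.na(m[[score_col]]), , drop = FALSE]
  if (nrow(m) < 30)
    warning("threshold search on fewer than 30 patients")
  sv <- survival::Surv(m$os_months, m$os_event)
  rows <- lapply(percentiles, function(p) {
    cutoff <- quantile_cut(m[[score_col]], p)
    grp <- ifelse(m[[score_col]] <= cutoff, "low", "high")
    if (length(unique(grp)) < 2L)
      return(data.frame(percentile = p, cutoff = cutoff, n_low = sum(grp == "low"),
                        n_high = sum(grp == "high"), chisq = NA_real_,
                        p = NA_real_, skipped = TRUE))
    sd <- survival::survdiff(sv ~ grp)
    chisq <- unname(sd$chisq)
    data.frame(percentile = p, cutoff = cutoff, n_low = sum(grp == "low"),
               n_high = sum(grp == "high"), chisq = chisq,
               p = stats::pchisq(chisq, 1, lower.tail = FALSE),
               skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- !tab$skipped & tab$p < alpha_corrected
  sel <- if (any(tab$significant))
    tab$percentile[which.min(ifelse(tab$significant, tab$p, Inf))]
  else NA_real_
  structure(list(table = tab, selected = sel,
                 alpha_corrected = alpha_corrected, n = nrow(m)),
            class = "threshold_search")
}

#' @export
print.threshold_search <- function(x, ...) {
  cat(sprintf("<threshold_search> %d patients, %d candidates, alpha %.4g\n",
              x$n, nrow(x$table), x$alpha_corrected))
  cat(if (is.na(x$selected)) "no significant percentile\n"
      else sprintf("selected percentile: %g\n", x$selected))
  invisible(x)
}

#' Percentile grouping of a continuous measure
#'
#' One percentile gives two groups (`low`/`high`, boundary low); two give
#' three (`low`/`medium`/`high`), as used for the SCNA tertile-style split
#' at the 25th and 75th percentiles.
#'
#' @param x numeric values (`NA` kept as `NA` group).
#' @param percentiles one or two percentiles in (0, 100).
#' @return Character vector of group labels.
#' @export
percentile_groups <- function(x, percentiles) {
  stopifnot(length(percentiles) %in% 1:2)
  ok <- !is.na(x)
  out <- rep(NA_character_, length(x))
  cuts <- sort(vapply(percentiles, function(p) quantile_cut(x[ok], p),
                      numeric(1)))
  if (length(cuts) == 1L) {
    out[ok] <- ifelse(x[ok] <= cuts, "low", "high")
  } else {
    out[ok] <- ifelse(x[ok] <= cuts[1], "low",
                      ifelse(x[ok] <= cuts[2], "medium", "high"))
  }
  out
}

#' Resource-stratified prognosis of a genomic measure
#'
#' Within each resource stratum the measure is grouped by the given
#' percentile rule (mutational burden: 45th percentile, two groups; SCNA:
#' 25th/75th, three groups — percentiles are recomputed within each
#' stratum) and tested by log-rank plus a univariate Cox fit on the
#' continuous measure. A measure constant within a stratum is flagged and
#' not fitted; an empty stratum is an error.
#'
#' @param measure data frame `patient_id`, `value`.
#' @param strata data frame `patient_id`, `resource` (from
#'   [resource_groups()]).
#' @param clinical a [clinical_table()].
#' @param percentiles grouping percentiles (e.g. `45` or `c(25, 75)`).
#' @return List of class `stratified_prognosis`, one element per stratum:
#'   `logrank` (a `km_logrank`), `cox` (a `cox_result`) or a `flag`.
#' @export
stratified_prognosis <- function(measure, strata, clinical,
                                 percentiles = 45) {
  m <- merge(measure, strata[, c("patient_id", "resource")],
             by = "patient_id")
  m <- m[!is.na(m$value), , drop = FALSE]
  out <- lapply(split(m, m$resource), function(d) {
    if (nrow(d) == 0L) stop("empty resource stratum")
    if (nrow(d) < 20)
      warning("fewer than 20 patients with the measure in a stratum")
    if (length(unique(d$value)) < 2L)
      return(list(flag = "constant measure in stratum", n = nrow(d)))
    grp <- percentile_groups(d$value, percentiles)
    lr <- km_logrank(data.frame(patient_id = d$patient_id, group = grp,
                                stringsAsFactors = FALSE), clinical)
    cl <- merge(as.data.frame(clinical),
                d[, c("patient_id", "value")], by = "patient_id")
    class(cl) <- c("clinical_table", "data.frame")
    list(logrank = lr, cox = cox_fit(cl, "value", "univariate"),
         n = nrow(d))
  })
  if (length(out) < 2L) stop("need both resource strata")
  structure(out, class = "stratified_prognosis")
}

#' Subgroup (filtered) survival analysis
#'
#' Restricts the cohort to a clinical filter (for example optimally
#' debulked patients) and reruns log-rank and a univariate Cox fit on the
#' group indicator within the subgroup.
#'
#' @param groups data frame `patient_id`, `group`.
#' @param clinical a [clinical_table()].
#' @param filter logical vector over `clinical` rows, or a one-sided
#'   formula evaluated in the clinical table (e.g. `~ debulking ==
#'   "optimal"`).
#' @return List: `logrank`, `cox`, `n`; `flag` set when the filtered
#'   subgroup has no events.
#' @export
subgroup_analysis <- function(groups, clinical, filter) {
  df <- as.data.frame(clinical)
  keep <- if (inherits(filter, "formula"))
    eval(filter[[2]], envir = df) else filter
  keep[is.na(keep)] <- FALSE
  sub <- df[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("filter removes every patient")
  class(sub) <- c("clinical_table", "data.frame")
  flag <- if (sum(sub$os_event) == 0) "no events in subgroup" else ""
  lr <- km_logrank(groups, sub)
  gm <- .merge_groups(groups, sub)
  gm$group_high <- as.integer(gm$group == "high")
  class(gm) <- c("clinical_table", "data.frame")
  cx <- cox_fit(gm, "group_high", "univariate")
  list(logrank = lr, cox = cx, n = nrow(sub), flag = flag)
}

#' Rank and trend association tests
#'
#' `kind = "jonckheere"`: two-sided Jonckheere-Terpstra trend test of a
#' continuous variable against an ordered grouping — the statistic is the
#' sum of pairwise Mann-Whitney counts over ordered group pairs (ties
#' counted half), with an exact permutation p-value when the total n is at
#' most 10 and a tie-corrected normal approximation otherwise.
#' `kind = "wilcoxon"` and `kind = "spearman"` delegate to the standard
#' two-sided tests.
#'
#' @param x numeric values.
#' @param y for Jonckheere/Wilcoxon: group labels (ordered factor or
#'   coercible; Jonckheere needs >= 2 groups in their given order); for
#'   Spearman: a second numeric vector.
#' @param kind one of `"jonckheere"`, `"wilcoxon"`, `"spearman"`.
#' @return List `statistic`, `p`, `method`.
#' @export
association_tests <- function(x, y,
                              kind = c("jonckheere", "wilcoxon", "spearman")) {
  kind <- match.arg(kind)
  ok <- switch(kind,
               spearman = !is.na(x) & !is.na(y),
               !is.na(x) & !is.na(y))
  x <- x[ok]; y <- if (kind == "spearman") as.numeric(y)[ok] else y[ok]
  if (length(x) < 3L) stop("need at least three observations")
  switch(kind,
    jonckheere = jonckheere_test(x, y),
    wilcoxon = {
      g <- factor(y)
      if (nlevels(g) != 2L) stop("Wilcoxon test needs exactly two groups")
      wt <- stats::wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                               alternative = "two.sided", exact = FALSE,
                               correct = TRUE)
      list(statistic = unname(wt$statistic), p = wt$p.value,
           method = "two-sided Wilcoxon rank sum")
    },
    spearman = {
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman",
                        alternative = "two.sided", exact = FALSE))
      list(statistic = unname(ct$estimate), p = ct$p.value,
           method = "Spearman rank correlation")
    })
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs k < l of
# #(x_k < x_l) + 0.5 #(x_k = x_l)
.jt_statistic <- function(x, g_int) {
  ks <- sort(unique(g_int))
  j <- 0
  for (a in seq_along(ks)[-length(ks)]) for (b in (a + 1):length(ks)) {
    xa <- x[g_int == ks[a]]; xb <- x[g_int == ks[b]]
    cmp <- outer(xa, xb, "<")
    ties <- outer(xa, xb, "==")
    j <- j + sum(cmp) + 0.5 * sum(ties)
  }
  j
}

#' Two-sided Jonckheere-Terpstra trend test
#'
#' @param x numeric values.
#' @param g group labels whose level order encodes the trend (ordered
#'   factor, or factor/character taken in its level/sort order).
#' @param exact_n_max use the exact permutation distribution when the
#'   total sample size is at most this (default 10); otherwise the
#'   tie-corrected normal approximation.
#' @return List `statistic`, `p`, `method`.
#' @export
jonckheere_test <- function(x, g, exact_n_max = 10) {
  g <- if (is.factor(g)) g else factor(g)
  if (nlevels(droplevels(g)) < 2L) stop("trend test needs >= 2 groups")
  g <- droplevels(g)
  g_int <- as.integer(g)
  n <- length(x)
  j <- .jt_statistic(x, g_int)
  nk <- as.vector(table(g_int))
  e_j <- (n^2 - sum(nk^2)) / 4
  if (n <= exact_n_max) {
    perms <- .multiset_perms(g_int)
    stats_all <- vapply(perms, function(gp) .jt_statistic(x, gp), numeric(1))
    dev <- abs(stats_all - e_j)
    p <- mean(dev >= abs(j - e_j) - 1e-12)
    return(list(statistic = j, p = p,
                method = "Jonckheere-Terpstra (exact permutation)"))
  }
  # tie-corrected normal approximation
  tu <- as.vector(table(x))
  v1 <- (n * (n - 1) * (2 * n + 5) -
           sum(nk * (nk - 1) * (2 * nk + 5)) -
           sum(tu * (tu - 1) * (2 * tu + 5))) / 72
  v2 <- sum(nk * (nk - 1) * (nk - 2)) * sum(tu * (tu - 1) * (tu - 2)) /
    (36 * n * (n - 1) * (n - 2))
  v3 <- sum(nk * (nk - 1)) * sum(tu * (tu - 1)) / (8 * n * (n - 1))
  v <- v1 + v2 + v3
  z <- (j - e_j) / sqrt(v)
  list(statistic = j, p = 2 * stats::pnorm(-abs(z)),
       method = "Jonckheere-Terpstra (normal approximation)")
}

# all distinct permutations of a small multiset of group labels
.multiset_perms <- function(g) {
  n <- length(g)
  out <- list()
  rec <- function(remaining, acc) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (v in unique(remaining)) {
      idx <- which(remaining == v)[1]
      rec(remaining[-idx], c(acc, v))
    }
  }
  rec(g, integer(0))
  out
}
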