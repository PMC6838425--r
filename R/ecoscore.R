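#' @title Local EcoScore and cohort groupings
#' @name ecoscore
#' @description
#' The local EcoScore condenses the four habitat counts into one balance of
#' cancer-favouring against cancer-inhibiting conditions:
#' `EcoScore = (RpHp + RpHm) / RmHp`. High-resource habitats (with or
#' without hazard) are taken as pro-tumour, the low-resource/high-hazard
#' habitat as tumour-inhibiting, and the low-resource/low-hazard habitat —
#' mostly squares deep inside tumour nests with few non-tumour cells —
#' never enters the score. Cohorts are dichotomized at a percentile of the
#' score (40th by default) using the inverse-ECDF quantile so the cutoff is
#' always an attained score, with the boundary going to the low group.
NULL

#' Inverse-ECDF (type 1) quantile
#'
#' The smallest observed value whose empirical CDF reaches `p/100`. Used
#' for every percentile split in the package so that cutoffs are attained
#' values and behave sensibly with infinite scores.
#'
#' @param x numeric values (`NA` dropped; `Inf` allowed).
#' @param p percentile in (0, 100).
#' @return The cutoff value.
#' @export
quantile_cut <- function(x, p) {
  stopifnot(p > 0, p < 100)
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no defined values to take a quantile of")
  unname(stats::quantile(x, p / 100, type = 1, names = FALSE))
}

#' Compute the local EcoScore of one habitat summary
#'
#' `score = (count(RpHp) + count(RpHm)) / count(RmHp)`. A zero denominator
#' with a positive numerator yields `Inf` (ranked above every finite score
#' by the percentile split); 0/0 is undefined (`NA`) with a warning.
#'
#' @param summary a [habitat_summary()] (or anything with a `counts`
#'   element naming the four habitats).
#' @return Data frame with `patient_id`, `ecoscore`.
#' @export
local_ecoscore <- function(summary) {
  cnt <- summary$counts
  num <- cnt[["RpHp"]] + cnt[["RpHm"]]
  den <- cnt[["RmHp"]]
  score <- if (den > 0) num / den
           else if (num > 0) Inf
           else { warning("EcoScore undefined (0/0) for patient ",
                          summary$patient_id); NA_real_ }
  data.frame(patient_id = summary$patient_id, ecoscore = score,
             stringsAsFactors = FALSE)
}

#' EcoScores for a cohort of habitat summaries
#'
#' @param summaries list of `habitat_summary` objects (patient level).
#' @return Data frame `patient_id`, `ecoscore`.
#' @export
cohort_ecoscores <- function(summaries) {
  if (inherits(summaries, "habitat_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, local_ecoscore))
}

#' Dichotomize cohort scores at a percentile
#'
#' Cutoff is the inverse-ECDF quantile of the defined scores; `score <=
#' cutoff` is low, above is high. Infinite scores are defined and always
#' high (unless every score is infinite); undefined (`NA`) scores stay
#' `"undefined"` and take no part in the cutoff.
#'
#' @param scores data frame with `patient_id` and `ecoscore` (or a bare
#'   numeric vector).
#' @param percentile split percentile, default 40.
#' @param score_col name of the score column.
#' @return The input with a `group` column in `low` / `high` / `undefined`,
#'   plus attribute `cutoff`.
#' @export
dichotomize <- function(scores, percentile = 40, score_col = "ecoscore") {
  if (is.numeric(scores))
    scores <- data.frame(patient_id = as.character(seq_along(scores)),
                         ecoscore = scores, stringsAsFactors = FALSE)
  x <- scores[[score_col]]
  def <- !is.na(x)
  if (sum(def) < 2L) stop("need at least two defined scores to dichotomize")
  cutoff <- quantile_cut(x[def], percentile)
  grp <- rep("undefined", length(x))
  grp[def] <- ifelse(x[def] <= cutoff, "low", "high")
  if (all(grp[def] == grp[def][1]))
    warning("degenerate split: all defined scores fall in one group")
  scores$group <- grp
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Split a cohort into low/high resource groups
#'
#' High-resource abundance is the fraction of classified squares that are
#' high resource (`frac(RpHp) + frac(RpHm)`); the cohort is split at its
#' median (inverse-ECDF 50th percentile), boundary to low. Low resource
#' corresponds to absent or patchy stroma around the cancer.
#'
#' @param summaries list of patient-level `habitat_summary` objects.
#' @return Data frame `patient_id`, `high_resource_abundance`, `resource`
#'   (`low`/`high`), with attribute `cutoff`.
#' @export
resource_groups <- function(summaries) {
  if (inherits(summaries, "habitat_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) >= 2L)
  ab <- vapply(summaries, function(s)
    s$fractions[["RpHp"]] + s$fractions[["RpHm"]], numeric(1))
  pid <- vapply(summaries, `[[`, "", "patient_id")
  cutoff <- quantile_cut(ab, 50)
  grp <- ifelse(ab <= cutoff, "low", "high")
  if (all(grp == grp[1]))
    warning("degenerate resource split: all patients in one group")
  out <- data.frame(patient_id = pid, high_resource_abundance = ab,
                    resource = grp, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Combined EcoScore-by-mutational-burden grouping
#'
#' The aggressive subgroup is high EcoScore together with low mutational
#' burden (at or below the cohort's 45th-percentile cutoff); all other
#' patients with both measures are "other"; patients missing either
#' measure are excluded (`NA`).
#'
#' @param eco_groups data frame with `patient_id` and `group` (from
#'   [dichotomize()]).
#' @param mb data frame with `patient_id` and `mutational_burden`.
#' @param mb_percentile mutational-burden cut percentile, default 45.
#' @return Data frame `patient_id`, `combined_group` in
#'   `aggressive` / `other` / `NA`, with attribute `mb_cutoff`.
#' @export
combined_eco_mb_group <- function(eco_groups, mb, mb_percentile = 45) {
  m <- merge(eco_groups[, c("patient_id", "group")],
             mb[, c("patient_id", "mutational_burden")],
             by = "patient_id", all.x = TRUE)
  ok <- !is.na(m$mutational_burden) & m$group %in% c("low", "high")
  if (!any(ok)) stop("no patient has both EcoScore group and mutational burden")
  cutoff <- quantile_cut(m$mutational_burden[ok], mb_percentile)
  grp <- rep(NA_character_, nrow(m))
  grp[ok] <- ifelse(m$group[ok] == "high" & m$mutational_burden[ok] <= cutoff,
                    "aggressive", "other")
  out <- data.frame(patient_id = m$patient_id, combined_group = grp,
                    stringsAsFactors = FALSE)
  attr(out, "mb_cutoff") <- cutoff
  out
}
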