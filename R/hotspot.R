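#' @title Hotspot detection and the global EcoScore
#' @name hotspot_global
#' @description
#' Spatial clusters ("hotspots") of lymphocytes and of stromal cells are
#' detected on the same grid used for habitat classification, with the
#' Getis-Ord Gi* local statistic computed over per-square counts on the
#' full rectangular grid covering the section (empty squares count zero —
#' a cluster is elevated relative to the whole section, including its
#' empty parts). One-sided upper-tail normal p-values are corrected across
#' squares by Benjamini-Hochberg; corrected p below alpha flags a hotspot.
#' The global EcoScore is then the ratio of summed centre-to-centre
#' distances from every habitat square to its nearest lymphocyte hotspot,
#' over the same to the nearest stromal hotspot — higher values mean the
#' tumour's habitats sit closer to resources than to hazards.
NULL

# full rectangular grid of per-class counts covering the occupied index range
.full_grid_counts <- function(squares) {
  ir <- range(squares$i); jr <- range(squares$j)
  full <- expand.grid(i = ir[1]:ir[2], j = jr[1]:jr[2])
  m <- merge(full, squares, by = c("i", "j"), all.x = TRUE)
  for (cc in c("n_cancer", "n_stromal", "n_lym"))
    m[[cc]][is.na(m[[cc]])] <- 0L
  m[order(m$i, m$j), c("i", "j", "n_cancer", "n_stromal", "n_lym")]
}

#' Getis-Ord Gi* z-scores over gridded counts
#'
#' For square `i` with neighbourhood `N(i)` = squares whose centres lie
#' within `radius_um` (inclusive of the square itself):
#' \deqn{G^*_i = \frac{\sum_{j \in N(i)} x_j - \bar X |N(i)|}
#'   {S \sqrt{(n |N(i)| - |N(i)|^2) / (n - 1)}}}
#' with `X̄` and `S` the mean and population standard deviation of the
#' counts over all `n` squares. If all counts are equal (`S = 0`) every
#' z-score is defined as 0, so a featureless field has no hotspots.
#'
#' @param counts data frame with columns `i`, `j` (square indices) and `x`
#'   (the count of one cell class per square).
#' @param square_size_um grid square side, to place square centres.
#' @param radius_um neighbourhood radius in micrometres; default 100
#'   (self plus rook neighbours at the default square size). Must be at
#'   least the square size.
#' @return Numeric vector of z-scores, one per row of `counts`.
#' @export
gi_star <- function(counts, square_size_um = 100, radius_um = 100) {
  stopifnot(all(c("i", "j", "x") %in% names(counts)))
  n <- nrow(counts)
  if (n < 2L) stop("need at least two squares")
  if (radius_um < square_size_um)
    stop("neighbourhood radius must be at least the square size")
  x <- as.numeric(counts$x)
  xbar <- mean(x)
  s2 <- mean(x^2) - xbar^2
  if (s2 <= 0) return(rep(0, n))
  s <- sqrt(s2)
  cx <- (counts$i + 0.5) * square_size_um
  cy <- (counts$j + 0.5) * square_size_um
  # binary weights: centre-to-centre distance <= radius (inclusive of self)
  d2 <- outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2
  w <- d2 <= radius_um^2 + 1e-9
  wn <- rowSums(w)
  num <- as.vector(w %*% x) - xbar * wn
  den <- s * sqrt((n * wn - wn^2) / (n - 1))
  z <- ifelse(den > 0, num / den, 0)
  z
}

#' Flag hotspot squares from Gi* z-scores
#'
#' One-sided upper-tail p-values from the standard normal, corrected for
#' the number of squares (Benjamini-Hochberg by default); flagged where
#' the corrected p is below `alpha`.
#'
#' @param z numeric z-scores.
#' @param alpha significance level, default 0.05.
#' @param correction a `p.adjust` method, default `"BH"`.
#' @return Logical vector of hotspot flags, with attribute `p_adj`.
#' @export
detect_hotspots <- function(z, alpha = 0.05, correction = "BH") {
  stopifnot(all(is.finite(z)))
  p <- stats::pnorm(z, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = correction)
  structure(p_adj < alpha, p_adj = p_adj)
}

#' Hotspot field for both cell classes on a habitat map's grid
#'
#' @param hmap a [habitat_map()].
#' @param radius_um Gi* neighbourhood radius; default 100.
#' @param alpha significance level after correction; default 0.05.
#' @param correction multiplicity correction; default `"BH"`.
#' @return Object of class `hotspot_field`: list with `squares` (data
#'   frame `i, j, z_lym, p_lym, hot_lym, z_str, p_str, hot_str` on the full
#'   rectangular grid), plus the grid and settings.
#' @export
hotspot_field <- function(hmap, radius_um = 100, alpha = 0.05,
                          correction = "BH") {
  stopifnot(inherits(hmap, "habitat_map"))
  g <- .full_grid_counts(hmap$squares)
  s <- hmap$grid$square_size_um
  out <- g[, c("i", "j")]
  for (cls in c("lym", "str")) {
    x <- if (cls == "lym") g$n_lym else g$n_stromal
    z <- gi_star(data.frame(i = g$i, j = g$j, x = x),
                 square_size_um = s, radius_um = radius_um)
    hot <- detect_hotspots(z, alpha = alpha, correction = correction)
    out[[paste0("z_", cls)]] <- z
    out[[paste0("p_", cls)]] <- attr(hot, "p_adj")
    out[[paste0("hot_", cls)]] <- as.logical(hot)
  }
  structure(list(patient_id = hmap$patient_id, section_id = hmap$section_id,
                 grid = hmap$grid, bbox = hmap$bbox, squares = out,
                 radius_um = radius_um, alpha = alpha,
                 correction = correction),
            class = "hotspot_field")
}

#' Nearest-hotspot distances for every habitat square
#'
#' Euclidean centre-to-centre distance (micrometres) from each classified
#' (cancer-containing) square to the nearest flagged hotspot of each
#' class. A square that is itself a hotspot has distance 0. When a class
#' has no hotspot anywhere on the section, all its distances are set to
#' the section bounding-box diagonal and the profile is flagged as capped
#' for that class, so the global score stays defined.
#'
#' @param hmap a [habitat_map()].
#' @param hotspots a [hotspot_field()] on the same grid.
#' @return Object of class `distance_profile`: data-frame element
#'   `squares` (`i, j, habitat, d_lym, d_str`) plus logical flags
#'   `capped_lym`, `capped_str`.
#' @export
habitat_hotspot_distances <- function(hmap, hotspots) {
  stopifnot(inherits(hmap, "habitat_map"), inherits(hotspots, "hotspot_field"))
  if (!identical(hmap$grid, hotspots$grid))
    stop("habitat map and hotspot field use different grids")
  s <- hmap$grid$square_size_um
  hab <- hmap$squares[hmap$squares$habitat != "none", , drop = FALSE]
  if (nrow(hab) == 0L) stop("no classified habitat squares")
  diag_um <- sqrt(diff(hmap$bbox[c("xmin", "xmax")])^2 +
                  diff(hmap$bbox[c("ymin", "ymax")])^2)
  nearest <- function(hot_sq) {
    if (nrow(hot_sq) == 0L) return(rep(unname(diag_um), nrow(hab)))
    d2 <- outer(hab$i, hot_sq$i, "-")^2 + outer(hab$j, hot_sq$j, "-")^2
    s * sqrt(apply(d2, 1, min))
  }
  hs <- hotspots$squares
  lym_hot <- hs[hs$hot_lym, c("i", "j"), drop = FALSE]
  str_hot <- hs[hs$hot_str, c("i", "j"), drop = FALSE]
  out <- data.frame(i = hab$i, j = hab$j, habitat = hab$habitat,
                    d_lym = nearest(lym_hot), d_str = nearest(str_hot),
                    stringsAsFactors = FALSE)
  structure(list(patient_id = hmap$patient_id, section_id = hmap$section_id,
                 squares = out,
                 capped_lym = nrow(lym_hot) == 0L,
                 capped_str = nrow(str_hot) == 0L),
            class = "distance_profile")
}

#' Global EcoScore from a distance profile
#'
#' `score = sum(d_lym) / sum(d_str)` over the habitat squares: the ratio
#' of mean distance to the nearest lymphocyte hotspot over mean distance
#' to the nearest stromal hotspot. If every habitat square is itself a
#' stromal hotspot the denominator is zero and the score is `Inf` with a
#' warning.
#'
#' @param profile a `distance_profile` from [habitat_hotspot_distances()],
#'   or a data frame with columns `d_lym`, `d_str`.
#' @return Non-negative number (possibly `Inf`).
#' @export
global_ecoscore <- function(profile) {
  sq <- if (inherits(profile, "distance_profile")) profile$squares else profile
  stopifnot(all(c("d_lym", "d_str") %in% names(sq)), nrow(sq) >= 1L)
  den <- sum(sq$d_str)
  if (den == 0) {
    warning("all habitat squares are stromal hotspots; global EcoScore is Inf")
    return(Inf)
  }
  sum(sq$d_lym) / den
}
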