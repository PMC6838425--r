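# Independent brute-force oracles, deliberately written with plain loops
# and none of the package's binning/matrix machinery.

# Per-cell binning + per-square threshold evaluation: returns a data frame
# i, j, n_cancer, n_stromal, n_lym, habitat for every occupied square.
oracle_habitats <- function(map, square_size = 100, shift_x = 0, shift_y = 0,
                            origin = c(0, 0), k_str = 0.5, k_lym = 0.2) {
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(map$cells))) {
    i <- floor((map$cells$x[r] - origin[1] - shift_x) / square_size)
    j <- floor((map$cells$y[r] - origin[2] - shift_y) / square_size)
    key <- paste(i, j)
    cur <- if (is.null(acc[[key]])) c(cancer = 0, stromal = 0, lymphocyte = 0)
           else acc[[key]]
    cur[[map$cells$cell_class[r]]] <- cur[[map$cells$cell_class[r]]] + 1
    acc[[key]] <- cur
  }
  keys <- ls(acc)
  rows <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    ij <- as.integer(strsplit(keys[k], " ")[[1]])
    cnt <- acc[[keys[k]]]
    hab <- if (cnt[["cancer"]] == 0) "none" else {
      r_hi <- cnt[["stromal"]] > k_str * cnt[["cancer"]]
      h_hi <- cnt[["lymphocyte"]] > k_lym * cnt[["cancer"]]
      if (r_hi && h_hi) "RpHp" else if (r_hi) "RpHm"
      else if (h_hi) "RmHp" else "RmHm"
    }
    rows[[k]] <- data.frame(i = ij[1], j = ij[2],
                            n_cancer = unname(cnt[["cancer"]]),
                            n_stromal = unname(cnt[["stromal"]]),
                            n_lym = unname(cnt[["lymphocyte"]]),
                            habitat = hab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$i, out$j), , drop = FALSE]
}

# Direct evaluation of the Gi* formula square by square.
oracle_gi_star <- function(counts, square_size = 100, radius = 100) {
  n <- nrow(counts)
  x <- counts$x
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  if (s == 0) return(z)
  for (a in seq_len(n)) {
    wsum <- 0; wn <- 0
    for (b in seq_len(n)) {
      dx <- (counts$i[a] - counts$i[b]) * square_size
      dy <- (counts$j[a] - counts$j[b]) * square_size
      if (sqrt(dx^2 + dy^2) <= radius + 1e-9) {
        wsum <- wsum + x[b]; wn <- wn + 1
      }
    }
    den <- s * sqrt((n * wn - wn^2) / (n - 1))
    z[a] <- if (den > 0) (wsum - xbar * wn) / den else 0
  }
  z
}

# Exhaustive Jonckheere-Terpstra statistic: every pair of observations in
# every ordered pair of groups, ties counted half. Group order is the
# sorted label order and stays fixed under label permutation.
oracle_jt_stat <- function(x, g) {
  g <- as.integer(factor(g))
  j <- 0
  n <- length(x)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (g[a] < g[b]) {
      if (x[a] < x[b]) j <- j + 1
      else if (x[a] == x[b]) j <- j + 0.5
    }
  }
  j
}

# Exact permutation p for the JT test via full enumeration of all n!
# orderings (deduplicated), two-sided around the null mean.
oracle_jt_exact_p <- function(x, g) {
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms_of(v[-k]))
        out[[length(out) + 1]] <- c(v[k], rest)
    out
  }
  g <- as.integer(factor(g))
  nk <- table(g)
  e_j <- (length(x)^2 - sum(nk^2)) / 4
  obs <- oracle_jt_stat(x, g)
  all_g <- unique(perms_of(g))
  devs <- vapply(all_g, function(gp) abs(oracle_jt_stat(x, gp) - e_j),
                 numeric(1))
  mean(devs >= abs(obs - e_j) - 1e-12)
}

# Hand risk-set tally for the two-group log-rank chi-square.
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group)) # 1 or 2
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Small deterministic slide for grid tests: explicit coordinates.
toy_slide <- function() {
  slide_cell_map(data.frame(
    x = c(50, 60, 70, 150, 160, 250, 55, 65, 155, 52, 250),
    y = c(50, 55, 60, 50, 55, 50, 52, 58, 52, 57, 55),
    cell_class = c(rep("cancer", 6), rep("stromal", 3),
                   rep("lymphocyte", 2)),
    stringsAsFactors = FALSE), patient_id = "T1", section_id = "S1")
}

# Random slide with mixed classes on a given extent.
random_slide <- function(n = 500, extent = 1000, pid = "R1") {
  cls <- sample(c("cancer", "stromal", "lymphocyte"), n, replace = TRUE,
                prob = c(0.5, 0.3, 0.2))
  slide_cell_map(data.frame(
    x = runif(n, 0, extent), y = runif(n, 0, extent), cell_class = cls,
    stringsAsFactors = FALSE), patient_id = pid)
}

# Direct exponential survival cohort (no slides) for the survival oracles.
sim_survival_cohort <- function(n, hr = 2, censoring = 0.3,
                                base_rate = 0.05) {
  grp <- rep(c("low", "high"), length.out = n)
  rate <- base_rate * ifelse(grp == "high", hr, 1)
  t_ev <- rexp(n, rate)
  f <- function(m) mean((1 - exp(-rate * m)) / (rate * m)) - censoring
  cmax <- if (censoring > 0) uniroot(f, c(1e-6, 1e5))$root else Inf
  ct <- if (is.finite(cmax)) runif(n, 0, cmax) else rep(Inf, n)
  clinical_table(data.frame(
    patient_id = sprintf("Q%04d", seq_len(n)),
    os_months = pmax(pmin(t_ev, ct), 0.001),
    os_event = as.integer(t_ev <= ct),
    group = grp, stringsAsFactors = FALSE), five_year = FALSE)
}
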