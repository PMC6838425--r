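test_that("Gi* matches the brute-force formula on random grids", {
  set.seed(101)
  for (side in c(5, 7, 10)) {
    g <- expand.grid(i = 0:(side - 1), j = 0:(side - 1))
    g$x <- rpois(nrow(g), 3)
    for (radius in c(100, 150, 250)) {
      z <- gi_star(g, square_size_um = 100, radius_um = radius)
      expect_lt(max(abs(z - oracle_gi_star(g, 100, radius))), 1e-10)
    }
  }
})

test_that("Gi* on a single nonzero centre square matches the oracle exactly", {
  g <- expand.grid(i = 0:4, j = 0:4)
  g$x <- ifelse(g$i == 2 & g$j == 2, 25, 0)
  z <- gi_star(g, 100, 100)
  expect_lt(max(abs(z - oracle_gi_star(g, 100, 100))), 1e-10)
  expect_gt(z[g$i == 2 & g$j == 2], 0)
})

test_that("uniform count fields have all-zero z and no hotspots", {
  g <- expand.grid(i = 0:4, j = 0:4)
  g$x <- 7
  z <- gi_star(g, 100, 100)
  expect_equal(z, rep(0, 25))
  expect_false(any(detect_hotspots(z)))
})

test_that("Gi* is equivariant under permutation of square order", {
  set.seed(7)
  g <- expand.grid(i = 0:5, j = 0:5)
  g$x <- rpois(36, 2)
  z <- gi_star(g, 100, 100)
  perm <- sample(36)
  expect_equal(gi_star(g[perm, ], 100, 100), z[perm])
})

test_that("Gi* rejects invalid neighbourhoods", {
  g <- data.frame(i = 0:3, j = 0, x = 1:4)
  expect_error(gi_star(g, 100, 50), "radius")
  expect_error(gi_star(g[1, ], 100, 100), "two squares")
})

test_that("hotspot flags follow one-sided BH-corrected normal p-values", {
  z <- c(6, rep(0, 24))
  flags <- detect_hotspots(z, alpha = 0.05)
  expect_true(flags[1])
  expect_false(any(flags[-1]))
  # monotone in alpha
  z2 <- c(3, 2.5, 1, rep(0, 22))
  f01 <- detect_hotspots(z2, alpha = 0.01)
  f05 <- detect_hotspots(z2, alpha = 0.05)
  expect_true(all(which(f01) %in% which(f05)))
})

test_that("habitat-to-hotspot distances are centre-to-centre with caps", {
  cells <- data.frame(
    x = c(rep(seq(25, 975, by = 50), each = 2)),
    y = c(rep(c(25, 975), times = 20)),
    cell_class = "cancer", stringsAsFactors = FALSE)
  # dense lymphocyte block in one corner square, stroma in another
  cells <- rbind(cells,
                 data.frame(x = runif(60, 0, 100), y = runif(60, 0, 100),
                            cell_class = "lymphocyte"),
                 data.frame(x = runif(60, 200, 300), y = runif(60, 0, 100),
                            cell_class = "stromal"))
  m <- slide_cell_map(cells)
  hm <- habitat_map(m)
  hf <- hotspot_field(hm)
  dp <- habitat_hotspot_distances(hm, hf)
  expect_true(all(dp$squares$d_lym >= 0))
  # a square that is itself a hotspot has distance zero
  hs <- hf$squares
  if (any(hs$hot_lym)) {
    hot_keys <- paste(hs$i[hs$hot_lym], hs$j[hs$hot_lym])
    self_hot <- paste(dp$squares$i, dp$squares$j) %in% hot_keys
    if (any(self_hot)) expect_true(all(dp$squares$d_lym[self_hot] == 0))
  }
})

test_that("adjacent hotspot distance equals one square size", {
  hm <- list(patient_id = "P", section_id = "S", grid = grid_spec(100),
             params = habitat_params(),
             squares = data.frame(i = 0L, j = 0L, n_cancer = 5L,
                                  n_stromal = 0L, n_lym = 0L,
                                  habitat = "RmHm"),
             bbox = c(xmin = 0, xmax = 1000, ymin = 0, ymax = 1000))
  class(hm) <- "habitat_map"
  hf <- list(grid = grid_spec(100),
             squares = data.frame(i = c(0L, 1L), j = c(0L, 0L),
                                  hot_lym = c(FALSE, TRUE),
                                  hot_str = c(FALSE, FALSE)))
  class(hf) <- "hotspot_field"
  dp <- habitat_hotspot_distances(hm, hf)
  expect_equal(dp$squares$d_lym, 100)
  # no stromal hotspots anywhere: capped at the bounding-box diagonal
  expect_equal(dp$squares$d_str, sqrt(2) * 1000)
  expect_true(dp$capped_str)
  expect_false(dp$capped_lym)
})

test_that("global EcoScore is the distance-sum ratio with the stated edge cases", {
  expect_equal(global_ecoscore(data.frame(d_lym = c(10, 20),
                                          d_str = c(5, 10))), 2)
  expect_equal(global_ecoscore(data.frame(d_lym = c(7, 3),
                                          d_str = c(7, 3))), 1)
  # invariant under uniform scaling of the distance geometry
  set.seed(3)
  d <- data.frame(d_lym = runif(10, 0, 500), d_str = runif(10, 1, 500))
  expect_equal(global_ecoscore(transform(d, d_lym = d_lym * 3,
                                         d_str = d_str * 3)),
               global_ecoscore(d))
  expect_warning(g <- global_ecoscore(data.frame(d_lym = c(1, 2),
                                                 d_str = c(0, 0))),
                 "Inf")
  expect_equal(g, Inf)
})

test_that("adding lymphocyte hotspots never increases the distance sum", {
  hab <- expand.grid(i = 0:9, j = 0:9)
  set.seed(17)
  nearest_sum <- function(hot) {
    d2 <- outer(hab$i, hot$i, "-")^2 + outer(hab$j, hot$j, "-")^2
    sum(100 * sqrt(apply(d2, 1, min)))
  }
  hot <- data.frame(i = c(2L, 7L), j = c(3L, 8L))
  bigger <- rbind(hot, data.frame(i = 5L, j = 5L))
  expect_lte(nearest_sum(bigger), nearest_sum(hot))
})
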