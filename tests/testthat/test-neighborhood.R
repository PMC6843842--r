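test_that("mean grid distance matches hand computations", {
  # destination on the single cell centre
  expect_equal(mean_grid_distance(rbind(c(50, 50)), rbind(c(50, 50))), 0)
  # 1x2 strip, destination at the first centre: (0 + 100) / 2
  expect_equal(mean_grid_distance(rbind(c(50, 50), c(150, 50)),
                                  rbind(c(50, 50))), 50)
  expect_error(mean_grid_distance(matrix(0, 0, 2), rbind(c(0, 0))),
               "no urbanized cells")
  expect_error(mean_grid_distance(rbind(c(0, 0)), matrix(0, 0, 2)),
               "no destinations")
})

test_that("mean grid distance equals the brute-force all-pairs loop", {
  set.seed(61)
  for (k in 1:5) {
    cells <- cbind(runif(30, 0, 3000), runif(30, 0, 3000))
    dest <- cbind(runif(5, 0, 3000), runif(5, 0, 3000))
    brute <- mean(vapply(seq_len(30), function(i)
      min(vapply(seq_len(5), function(j)
        sqrt(sum((cells[i, ] - dest[j, ])^2)), 0)), 0))
    expect_equal(mean_grid_distance(cells, dest), brute, tolerance = 1e-9)
  }
})

test_that("grid distance is invariant to translation and 90-degree rotation", {
  set.seed(62)
  cells <- cbind(runif(12, 0, 1000), runif(12, 0, 1000))
  dest <- cbind(runif(3, 0, 1000), runif(3, 0, 1000))
  d0 <- mean_grid_distance(cells, dest)
  shift <- c(137, -250)
  expect_equal(mean_grid_distance(sweep(cells, 2, shift, `+`),
                                  sweep(dest, 2, shift, `+`)), d0,
               tolerance = 1e-9)
  rot <- function(m) cbind(-m[, 2], m[, 1])
  expect_equal(mean_grid_distance(rot(cells), rot(dest)), d0,
               tolerance = 1e-9)
})

test_that("adding a destination never increases the mean distance", {
  set.seed(63)
  cells <- cbind(runif(20, 0, 2000), runif(20, 0, 2000))
  dest <- cbind(runif(4, 0, 2000), runif(4, 0, 2000))
  d0 <- mean_grid_distance(cells, dest)
  for (k in 1:10) {
    extra <- rbind(dest, c(runif(1, 0, 2000), runif(1, 0, 2000)))
    expect_lte(mean_grid_distance(cells, extra), d0 + 1e-12)
  }
})

test_that("densities divide counts by urbanized area", {
  expect_equal(density_per_km2(100, 2), 50)
  expect_equal(density_per_km2(0, 5), 0)
  expect_error(density_per_km2(10, 0), "positive")
  expect_error(density_per_km2(-1, 1), "non-negative")
})

test_that("land-use-mix entropy hits its exact reference points", {
  expect_equal(land_use_mix(c(1, 1, 1)), 1)
  expect_equal(land_use_mix(c(7, 0, 0)), 0)
  expect_equal(land_use_mix(c(0.5, 0.5, 0)), log(2) / log(3))
  expect_error(land_use_mix(c(0, 0, 0)), "undefined")
  expect_error(land_use_mix(c(1, 1)), "three")
})

test_that("LUM is permutation invariant and uniquely maximal at equality", {
  set.seed(64)
  for (k in 1:20) {
    fa <- rgamma(3, 1)
    base <- land_use_mix(fa)
    for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
      expect_equal(land_use_mix(fa[p]), base, tolerance = 1e-12)
    if (max(fa) / min(fa) > 1.01) expect_lt(base, 1)
  }
})

test_that("tertiles cut 1..9 into equal thirds with ties to the lower group", {
  t9 <- tertile_categorize(1:9)
  expect_equal(as.character(t9), rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(unname(table(t9)), array(c(3L, 3L, 3L)), ignore_attr = TRUE)

  # a value exactly at the cut goes to the lower tertile
  v <- c(1, 2, 3, 3, 5, 6)
  cuts <- attr(tertile_categorize(v), "cuts")
  lab <- tertile_categorize(v)
  expect_true(all(as.character(lab)[v == cuts[1]] == "T1"))

  expect_error(tertile_categorize(c(1, 1, 2, 2)), "distinct")
})

test_that("tertile labels are rank invariant and balanced for distinct values", {
  set.seed(65)
  for (k in 1:10) {
    v <- runif(3 * sample(5:30, 1L))
    lab <- tertile_categorize(v)
    sizes <- table(lab)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(as.character(tertile_categorize(exp(2 * v))),
                     as.character(lab))
  }
})

test_that("person-weighted cuts balance individuals rather than areas", {
  # equal weights reduce to the area-weighted quantile grid
  v <- c(4, 1, 9, 2, 6, 5, 8, 3, 7)
  expect_identical(as.character(tertile_categorize(v, weights = rep(2, 9))),
                   as.character(tertile_categorize(v)))
  # half the population in the lowest-value area pulls both cuts down:
  # areas 2 and 3 move into the upper tertiles
  v2 <- 1:6
  w2 <- c(5, 1, 1, 1, 1, 1)
  lab <- as.character(tertile_categorize(v2, weights = w2))
  expect_identical(lab, c("T1", "T2", "T2", "T3", "T3", "T3"))
})

test_that("landscape metrics table integrates the individual measures", {
  ls <- simulate_landscape(n_areas = 20L, seed = 66L)
  mt <- landscape_metrics(ls)
  expect_equal(nrow(mt), 20L)
  expect_true(all(mt$dist_pa_m >= 0))
  expect_true(all(mt$lum >= 0 & mt$lum <= 1))
  expect_true(all(mt$pop_density >= 0))
  expect_true(all(mt$dist_pa_m_tertile %in% c("T1", "T2", "T3")))
  # recompute one area by hand through the public pieces
  a <- ls$areas[[7L]]
  expect_equal(mt$dist_park_m[7L],
               mean_grid_distance(a$cell_centers, ls$destinations$park))
  expect_equal(mt$lum[7L], land_use_mix(a$floor_areas))
})

test_that("saturating destination intensity drives distances to the floor", {
  sparse <- landscape_metrics(simulate_landscape(
    n_areas = 12L, dest_per_tile = c(pa_facility = 1, park = 1, transit = 1),
    seed = 67L), tertiles = FALSE)
  dense <- landscape_metrics(simulate_landscape(
    n_areas = 12L, dest_per_tile = c(pa_facility = 2000, park = 2000,
                                     transit = 2000),
    seed = 67L), tertiles = FALSE)
  expect_lt(mean(dense$dist_pa_m), mean(sparse$dist_pa_m))
  # ~2000 points per 3 km tile ~ one per 67 m cell: nearest within ~100 m
  expect_lt(mean(dense$dist_pa_m), 150)
})

test_that("large Dirichlet concentration pushes LUM towards 1", {
  lo <- landscape_metrics(simulate_landscape(n_areas = 15L,
                                             floor_concentration = 0.3,
                                             seed = 68L), tertiles = FALSE)
  hi <- landscape_metrics(simulate_landscape(n_areas = 15L,
                                             floor_concentration = 400,
                                             seed = 68L), tertiles = FALSE)
  expect_gt(mean(hi$lum), 0.99)
  expect_gt(mean(hi$lum), mean(lo$lum))
})

test_that("default landscape brackets the published tertile medians", {
  # published per-metric tertile medians: PA distance 511.9/1020.6/2406.7 m,
  # park 119.7/247.8/1530.5 m, transit 126.8/219.9/413.7 m, population
  # density 15/189/395 per km^2, LUM 0.61/0.77/0.90
  mt <- landscape_metrics(simulate_landscape(n_areas = 100L, seed = 69L),
                          tertiles = FALSE)
  expect_lt(min(mt$dist_pa_m), 511.9)
  expect_gt(max(mt$dist_pa_m), 2406.7)
  expect_lt(min(mt$dist_transit_m), 126.8)
  expect_gt(max(mt$dist_transit_m), 413.7)
  expect_lt(min(mt$pop_density), 15)
  expect_gt(max(mt$pop_density), 395)
  expect_lt(min(mt$lum), 0.61)
  expect_gt(max(mt$lum), 0.90)
})
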