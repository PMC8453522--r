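test_that("tree basal area is the circle area of the DBH", {
  expect_equal(tree_basal_area(10), 78.53982, tolerance = 1e-6)
  expect_equal(tree_basal_area(0), 0)
  expect_equal(tree_basal_area(20), 4 * tree_basal_area(10))
})

test_that("inventory DBH interpolates linearly with constant extrapolation", {
  expect_equal(interpolate_dbh(c(1980, 1985), c(20, 25), 1982), 22)
  expect_equal(interpolate_dbh(1985, 30, 1980:1990), rep(30, 11))
  # brute-force per-year linear formula oracle
  iy <- c(1980, 1985, 1990); id <- c(20, 24, 31)
  got <- interpolate_dbh(iy, id, 1978:1992)
  oracle <- sapply(1978:1992, function(y) {
    if (y <= 1980) return(20)
    if (y >= 1990) return(31)
    k <- max(which(iy <= y))
    id[k] + (id[k + 1] - id[k]) * (y - iy[k]) / (iy[k + 1] - iy[k])
  })
  expect_equal(got, oracle)
  expect_warning(interpolate_dbh(c(1980, 1985), c(25, 24), 1982),
                 "decreasing")
})

test_that("the competition index matches its hand-computed definition", {
  trees <- data.frame(
    tree_id = c("f", "n1", "n2", "far"),
    species = c("fir", "fir", "spruce", "fir"),
    x = c(0, 2, 5, 10.5), y = c(0, 0, 0, 0),
    dbh = c(30, 2 * sqrt(100 / pi), 2 * sqrt(200 / pi), 50))
  ni <- neighborhood_index("f", trees, radius = 10)
  expect_equal(ni$ni, 100 / 2 + 200 / 5) # = 90 cm2/m; tree at 10.5 m ignored
  expect_equal(ni$ratio_fir, 50 / 90)
  expect_equal(ni$ratio_spruce, 40 / 90)
  expect_equal(ni$ratio_other, 0)
  # all-fir neighborhood
  trees2 <- trees; trees2$species <- "fir"
  expect_equal(neighborhood_index("f", trees2)$ratio_fir, 1)
  # coincident positions are a data error naming both trees
  trees3 <- trees; trees3$x[2] <- 0
  expect_error(neighborhood_index("f", trees3), "f.*n1|n1.*f")
})

test_that("vectorised NI equals the brute-force double loop exactly", {
  set.seed(12)
  n <- 50
  trees <- data.frame(tree_id = sprintf("t%02d", 1:n),
                      species = sample(c("fir", "spruce", "other"), n, TRUE),
                      x = runif(n, 0, 50), y = runif(n, 0, 50),
                      dbh = runif(n, 5, 60))
  fast <- neighborhood_all(trees, radius = 10, plot_bounds = c(50, 50))
  for (i in seq_len(n)) {
    ni <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((trees$x[i] - trees$x[j])^2 + (trees$y[i] - trees$y[j])^2)
      if (d <= 10) ni <- ni + tree_basal_area(trees$dbh[j]) / d
    }
    expect_equal(fast$ni[i], ni)
    one <- neighborhood_index(trees$tree_id[i], trees, 10, c(50, 50))
    expect_equal(one$ni, ni)
  }
  # ratio partition: NI_fir + NI_spruce + NI_other = NI
  with_ni <- fast[fast$ni > 0, ]
  expect_equal(with_ni$ratio_fir + with_ni$ratio_spruce + with_ni$ratio_other,
               rep(1, nrow(with_ni)))
  # monotone in a neighbor's basal area
  trees_big <- trees; trees_big$dbh[2] <- trees_big$dbh[2] + 10
  grew <- neighborhood_all(trees_big, radius = 10)
  expect_true(all(grew$ni >= neighborhood_all(trees, radius = 10)$ni))
})

test_that("radius selection maximizes R2 with a parsimonious tie-break", {
  set.seed(2)
  n <- 120
  trees <- data.frame(tree_id = sprintf("t%03d", 1:n), species = "fir",
                      x = runif(n, 0, 50), y = runif(n, 0, 50),
                      dbh = runif(n, 10, 50))
  # growth independent of NI: flat profile, smallest candidate wins
  bai <- rnorm(n, 20, 1e-6)
  flat <- optimize_radius(c(6, 8, 10), bai, trees)
  expect_true(all(flat$r2 >= 0 & flat$r2 <= 1))
  bai2 <- rep(20, n) # exactly constant: R2 identical (0), tie -> smallest
  expect_equal(suppressWarnings(optimize_radius(c(6, 8, 10), bai2,
                                                trees))$radius, 6)
})

test_that("generative competition radius is recovered within 2 m", {
  hits <- 0L
  for (i in 1:20) {
    set.seed(500 + i)
    n <- 300
    trees <- data.frame(tree_id = sprintf("t%03d", 1:n), species = "fir",
                        x = runif(n, 0, 70), y = runif(n, 0, 70),
                        dbh = rlnorm(n, log(25), 0.3))
    ni8 <- neighborhood_all(trees, radius = 8)$ni
    # periodic annual BAI: the mean over a 5-yr inventory period, so the
    # per-year growth noise is averaged down by sqrt(5)
    bai <- rowMeans(replicate(5, exp(3 - 3e-4 * ni8 + rnorm(n, 0, 0.22))))
    sel <- optimize_radius(4:14, bai, trees, plot_bounds = c(70, 70))
    if (abs(sel$radius - 8) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.8)
})

test_that("Shannon diversity behaves over basal-area shares", {
  expect_equal(shannon_index(1), 0)
  expect_equal(shannon_index(c(0.5, 0.5)), log(2))
  expect_equal(shannon_index(c(1, 1, 1) / 3), log(3))
  expect_gt(shannon_index(c(1, 1, 1) / 3), shannon_index(c(0.6, 0.3, 0.1)))
})

test_that("stand attributes aggregate live trees per hectare", {
  trees <- data.frame(species = "fir", dbh = 10)
  sa <- stand_attributes(trees, 0.25)
  expect_equal(sa$ba, tree_basal_area(10) / 1e4 / 0.25)
  expect_equal(sa$density, 4)
  trees2 <- data.frame(species = c("fir", "spruce", "other"),
                       dbh = c(30, 25, 20))
  sa2 <- stand_attributes(trees2, 0.25)
  expect_equal(sa2$prop_fir + sa2$prop_spruce + sa2$prop_other, 1)
  sa3 <- stand_attributes(trees2[-1, ], 0.25)
  expect_equal(sa2$ba - sa3$ba, tree_basal_area(30) / 1e4 / 0.25)
})

test_that("management covariates summarise the thinning history", {
  sch <- data.frame(year = c(1985, 1990), ba_removed = c(5, 4))
  mg <- management_covariates(sch, 1991, residual_ba = 30)
  expect_equal(mg$years_since_thinning, 1)
  expect_equal(mg$n_interventions, 2)
  expect_equal(mg$ba_removed_total, 9)
  expect_equal(mg$ba_removed_last, 4)
  none <- management_covariates(sch[0, ], 1991, 30, start_year = 1980)
  expect_equal(none$years_since_thinning, 11)
  expect_true(none$no_prior_thinning)
})

test_that("edge filtering uses a strict buffer rule", {
  expect_true(edge_filter(5, 5, c(50, 50), 10))
  expect_false(edge_filter(25, 25, c(50, 50), 10))
  expect_false(edge_filter(10, 25, c(50, 50), 10)) # exactly at 10 m: kept
})

test_that("residual BA at drought equals the stand attribute cross-module", {
  cfg <- small_config(seed = 4)
  sim <- simulate_plot(cfg, "P1", "medium")
  ev <- 2011
  mem <- sim$membership
  alive <- mem[is.na(mem$removal_year) | mem$removal_year > ev, ]
  inv <- sim$inventory[sim$inventory$year == ev &
                         sim$inventory$tree_id %in% alive$tree_id, ]
  sa <- stand_attributes(inv, 0.16)
  mg <- management_covariates(sim$schedule, ev, sa$ba, start_year = 1999)
  expect_equal(mg$residual_ba, sa$ba)
  expect_gte(mg$years_since_thinning, 0)
})
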