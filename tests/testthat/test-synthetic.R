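test_that("degenerate climate parameters give a constant mean temperature", {
  cfg <- small_config(climate = list(amplitude = 0, temp_sd = 0, ar1 = 0))
  cl <- gen_climate(cfg, "S1")
  expect_equal(var(cl$tmean), 0)
  expect_true(all(cl$tmin <= cl$tmean & cl$tmean <= cl$tmax))
  expect_true(all(cl$prcp >= 0))
})

test_that("drought multiplier scales March-July precipitation as configured", {
  mults <- numeric(200)
  base <- numeric(200)
  for (i in 1:200) {
    cfg <- synth_config(years = c(1980, 2010),
                        drought_years = c("2003" = 0.4), seed = i)
    cl <- gen_climate(cfg, "S1")
    mj <- cl$month %in% 3:7
    mults[i] <- sum(cl$prcp[mj & cl$year == 2003])
    base[i] <- mean(tapply(cl$prcp[mj & cl$year != 2003],
                           cl$year[mj & cl$year != 2003], sum))
  }
  expect_equal(mean(mults) / mean(base), 0.4, tolerance = 0.05)
})

test_that("climate generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  expect_identical(gen_climate(cfg, "S1"), gen_climate(cfg, "S1"))
  expect_false(identical(gen_climate(cfg, "S1"), gen_climate(cfg, "S2")))
})

test_that("climate validation rejects short spans and bad AR1", {
  expect_error(synth_config(years = c(2000, 2016)), "30")
  expect_error(synth_config(climate = list(ar1 = 1)), "AR1")
  expect_error(synth_config(drought_years = c("2003" = 0)), "multipliers")
})

test_that("stand generation matches its Poisson/truncation contract", {
  n <- vapply(1:500, function(i) {
    nrow(gen_stand(synth_config(stem_density = 500, plot_side = 50,
                                seed = i)))
  }, numeric(1))
  expect_equal(mean(n), 125, tolerance = 0.03)
  cfg <- synth_config(species_probs = c(fir = 1, spruce = 0, other = 0))
  st <- gen_stand(cfg, "P1")
  expect_true(all(st$species == "fir"))
  expect_true(all(st$dbh >= 4))
  expect_false(anyDuplicated(st$tree_id) > 0)
  expect_true(all(st$x >= 0 & st$x <= 50 & st$y >= 0 & st$y <= 50))
})

test_that("thinning regimes order residual basal area as constructed", {
  cfg <- small_config(seed = 5)
  stand_ba <- function(sim) {
    yrs <- sort(unique(sim$inventory$year))
    vapply(yrs, function(y) {
      a <- sim$inventory[sim$inventory$year == y & !is.na(sim$inventory$dbh), ]
      sum(tree_basal_area(a$dbh)) / 1e4 / (40^2 / 1e4)
    }, numeric(1))
  }
  cl <- gen_climate(cfg, "S1")
  ctrl <- simulate_plot(cfg, "P1", "control", cl)
  slow <- simulate_plot(cfg, "P1", "slow", cl)
  med <- simulate_plot(cfg, "P1", "medium", cl)
  expect_true(all(diff(stand_ba(ctrl)) >= 0)) # growth only
  expect_true(all(stand_ba(med) <= stand_ba(slow) + 1e-9))
  # removed fraction per event matches configuration
  yrs <- sort(unique(med$inventory$year))
  ba_m <- stand_ba(med)
  for (k in seq_len(nrow(med$schedule))) {
    y <- med$schedule$year[k]
    pre_ba <- ba_m[match(y - 1, yrs)] # removal happens before growth of y
    if (is.na(pre_ba)) next # intervention in the first simulated year
    frac <- med$schedule$ba_removed[k] / pre_ba
    expect_gt(frac, 0.17); expect_lt(frac, 0.30) # configured 0.22 +- 1 tree
  }
  expect_true(all(!is.na(med$membership$removal_year) ==
                    (med$membership$tree_id %in%
                       med$inventory$tree_id[med$inventory$status ==
                                               "harvested"])))
})

test_that("degenerate growth parameters give constant BAI = exp(a_sp)", {
  cfg <- small_config(
    species_probs = c(fir = 1, spruce = 0, other = 0),
    growth = list(a = c(fir = 2, spruce = 2, other = 2), b = 0, c = 0,
                  d = c(fir = 0, spruce = 0, other = 0), e = 0, sd = 0,
                  plot_sd = 0))
  sim <- simulate_plot(cfg, "P1", "control")
  rwl <- sim$rwl
  yrs <- as.integer(rownames(rwl))
  for (id in head(colnames(rwl), 10)) {
    inv <- sim$inventory[sim$inventory$tree_id == id, ]
    d_ib0 <- inv$dbh[inv$year == min(yrs)] * 0.9 - 2 * rwl[1, id] / 10
    r <- d_ib0 / 2 + cumsum(rwl[[id]] / 10)
    bai <- bai_from_rings(r, r0 = d_ib0 / 2)
    expect_equal(bai, rep(exp(2), length(bai)), tolerance = 1e-9)
  }
})

test_that("the more drought-sensitive species loses more resistance", {
  # under log BAI = ... + d_sp * SPEI, a larger d_sp means a larger loss in
  # a negative-SPEI year, so the species with smaller d is more resistant
  cfg <- small_config(seed = 11, stem_density = 850, plot_side = 50,
                      growth = list(d = c(fir = 0.05, spruce = 0.45,
                                          other = 0.2)))
  sim <- simulate_plot(cfg, "P1", "control")
  bai <- sim$rwl
  yrs <- as.integer(rownames(bai))
  # compare ring widths directly around the severe 2003 event
  rel <- function(id) {
    w <- bai[[id]]
    w[yrs == 2003] / mean(w[yrs %in% 2001:2002])
  }
  mem <- sim$membership
  rt <- vapply(colnames(bai), rel, numeric(1))
  expect_gt(length(rt), 200)
  expect_gt(mean(rt[mem$species == "fir"]),
            mean(rt[mem$species == "spruce"]))
})

test_that("the whole simulation is reproducible and writable", {
  cfg <- small_config(seed = 9)
  a <- simulate_plot(cfg, "P1", "slow")
  b <- simulate_plot(cfg, "P1", "slow")
  expect_identical(a$rwl, b$rwl)
  expect_identical(a$schedule, b$schedule)
  d1 <- file.path(tempdir(), "simout1")
  sim <- simulate_experiment(small_config(seed = 2), regimes = "control")
  write_simulation(sim, d1)
  expect_true(file.exists(file.path(d1, "S1_control.rwl")))
  expect_true(file.exists(file.path(d1, "truth.json")))
  back <- read_rwl(file.path(d1, "S1_control.rwl"))
  orig <- sim$rwl$S1_control
  colnames(orig) <- sub(".*_(T[0-9]+)$", "\\1", colnames(orig))
  expect_setequal(colnames(back), colnames(orig))
  expect_equal(as.matrix(back[colnames(orig)]),
               round(as.matrix(orig), 2),
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(d1, recursive = TRUE)
})
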