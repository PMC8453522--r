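# shared fixtures: a small, fast experiment configuration used across tests

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(years = c(1957, 2016), growth_years = c(1999, 2016),
         plot_side = 40, stem_density = 550,
         drought_years = c("2003" = 0.45, "2011" = 0.55), seed = seed),
    list(...))
  do.call(synth_config, args)
}

# a deterministic ring-width table: 3 series over different spans
fixture_rwl <- function() {
  set.seed(404)
  yrs <- 1980:1999
  rwl <- data.frame(
    A1 = c(rep(NA, 5), round(runif(15, 0.5, 3), 2)),
    A2 = round(runif(20, 0.5, 3), 2),
    B1 = c(round(runif(18, 0.5, 3), 2), NA, NA),
    row.names = yrs, check.names = FALSE)
  rwl
}
species_recovery_rep <- function(seed, d_fir = 0.12, d_spruce = 0.30) {
  cfg <- synth_config(years = c(1957, 2016), growth_years = c(1999, 2016),
                      plot_side = 50, stem_density = 850,
                      species_probs = c(fir = 0.5, spruce = 0.5, other = 0),
                      drought_years = c("2003" = 0.45, "2011" = 0.55),
                      growth = list(d = c(fir = d_fir, spruce = d_spruce,
                                          other = 0.2)),
                      seed = seed)
  cl <- gen_climate(cfg, "S1")
  events <- c(2003, 2011)
  rows <- list()
  spei_of <- NULL
  for (pid in c("P1", "P2")) {
    sim <- simulate_plot(cfg, pid, "control", cl)
    spei_of <- setNames(sim$spei$spei, sim$spei$year)
    bm <- fit_bark_model(sim$bark_obs$dbh, sim$bark_obs$bark)
    rwl <- sim$rwl; yrs <- as.integer(rownames(rwl))
    bai_wide <- rwl
    for (id in colnames(rwl)) {
      inv_t <- sim$inventory[sim$inventory$tree_id == id &
                               sim$inventory$year == 2016, ]
      bai_wide[[id]] <- tree_bai(inv_t$dbh, bm, rwl[[id]], yrs)$bai
    }
    idx <- resilience_table(bai_wide, events)
    for (ev in events) {
      pos <- sim$stand
      trees <- data.frame(tree_id = pos$tree_id, species = pos$species,
                          x = pos$x, y = pos$y,
                          dbh = sim$inventory$dbh[sim$inventory$year == ev])
      ni <- neighborhood_all(trees, 10, c(50, 50))
      sa <- stand_attributes(trees, 0.25)
      r <- merge(idx[idx$event == ev, ], ni, by.x = "owner_id",
                 by.y = "tree_id")
      r$plot_id <- pid; r$spei <- spei_of[as.character(ev)]
      r$residual_ba <- sa$ba
      r$species <- pos$species[match(r$owner_id, pos$tree_id)]
      rows[[length(rows) + 1]] <- r[!r$edge, ]
    }
  }
  d <- do.call(rbind, rows)
  d <- d[d$species %in% c("fir", "spruce"), ]
  d$species <- factor(d$species, levels = c("spruce", "fir"))
  d$.y <- log(d$resistance)
  d <- standardize(d, c("spei", "ratio_fir", "residual_ba"))
  sel <- all_subsets_aicc(d, ".y", c("species", "spei", "ratio_fir",
                                     "residual_ba"), group = "plot_id")
  cf <- sel$best$coefficients
  i <- match("speciesfir", cf$term)
  # construction-implied fir-vs-spruce contrast on the log-resistance scale:
  # d_sp * SPEI in the drought year minus the log of the 2-yr mean of the
  # exponentiated pre-drought SPEI responses
  lme <- function(d0, pre) log(mean(exp(d0 * pre)))
  expected <- mean(vapply(events, function(ev) {
    pre <- spei_of[as.character(ev - 1:2)]
    (d_fir - d_spruce) * spei_of[as.character(ev)] -
      (lme(d_fir, pre) - lme(d_spruce, pre))
  }, numeric(1)))
  c(selected = !is.na(i), est = if (!is.na(i)) cf$estimate[i] else NA_real_,
    se = if (!is.na(i)) cf$se[i] else NA_real_, expected = expected,
    n = nrow(d))
}
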