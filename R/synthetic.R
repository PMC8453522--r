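# Synthetic mixed fir/spruce stands with known ground-truth drought
# responses.
#
# The generator emulates a long-term thinning experiment: ~0.25 ha mapped
# plots, mixed fir/spruce(/beech) composition, 5-yearly thinning regimes,
# monthly climate with embedded mild and severe drought years, and ring
# series whose growth follows a log-linear model
#
#   log BAI_it = a_sp + b*log(DBH_it) - c*NI_it + d_sp*SPEI_t
#                - e*BA_stand_t + plot_effect + eps_it
#
# so that Lloret ratios have analytically predictable expectations and every
# configured coefficient can be recovered by the downstream models. Drought
# enters generation through the same SPEI the analysis pipeline computes.
# Note that d_sp scales the SPEI term: a *larger* d_sp means a larger growth
# loss in a negative-SPEI year, i.e. a more drought-sensitive (less
# resistant) species.

#' Configuration for the synthetic experiment
#'
#' All defaults describe one plausible central-European mixed mountain-forest
#' experiment; pass replacements for any subset of fields.
#'
#' @param n_sites Number of sites (each gets its own climate series).
#' @param years Climate year range (inclusive); must span >= 30 years for
#'   SPEI calibration.
#' @param growth_years Year range over which ring growth is simulated.
#' @param plot_side Plot side length (m); default 50 m (0.25 ha).
#' @param stem_density Stems per hectare at establishment.
#' @param species_probs Named proportions over fir, spruce, other (sum to 1).
#' @param dbh_lognormal `c(meanlog, sdlog)` of the establishment DBH (cm),
#'   truncated below at 4 cm.
#' @param climate List: `mat` (mean annual temperature, degC), `amplitude`
#'   (seasonal half-amplitude, degC), `diurnal` (diurnal range, degC),
#'   `prcp_shape`/`prcp_scale` (monthly precipitation gamma, mm), `ar1`
#'   (monthly AR(1) coefficient in [0,1)), `temp_sd` (stationary SD of the
#'   temperature noise, degC), `latitude` (deg).
#' @param drought_years Named numeric: year -> March-July precipitation
#'   multiplier in (0, 1].
#' @param growth List: species intercepts `a`, size exponent `b`, competition
#'   coefficient `c`, per-species drought sensitivity `d`, stand-BA
#'   coefficient `e`, residual lognormal SD `sd`, plot-intercept SD
#'   `plot_sd`, `bark_k` (bark thickness as fraction of over-bark DBH),
#'   `min_width` (ring-width floor, mm), `spei_month`/`spei_scale` (the SPEI
#'   window driving growth), `ni_radius` (m).
#' @param thinning List: `interval` (yr), `start` (first intervention year),
#'   `frac` (named removal fractions of current basal area per regime).
#' @param seed Master seed; identical seeds give identical output.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_sites = 1,
                         years = c(1950, 2016),
                         growth_years = c(1980, 2016),
                         plot_side = 50,
                         stem_density = 600,
                         species_probs = c(fir = 0.5, spruce = 0.35,
                                           other = 0.15),
                         dbh_lognormal = c(meanlog = log(27), sdlog = 0.35),
                         climate = list(),
                         drought_years = c("1984" = 0.75, "1991" = 0.78,
                                           "2003" = 0.45, "2011" = 0.55),
                         growth = list(),
                         thinning = list(),
                         seed = 1) {
  cl <- utils::modifyList(list(mat = 7, amplitude = 8.5, diurnal = 8,
                               prcp_shape = 4, prcp_scale = 30, ar1 = 0.3,
                               temp_sd = 1.2, latitude = 48), climate)
  gr <- utils::modifyList(list(a = c(fir = 1.1, spruce = 1.0, other = 0.9),
                               b = 0.55, c = 5e-5,
                               d = c(fir = 0.12, spruce = 0.30, other = 0.20),
                               e = 0.006, sd = 0.20, plot_sd = 0.08,
                               bark_k = 0.05, min_width = 0.01,
                               spei_month = 7, spei_scale = 5,
                               ni_radius = 10), growth)
  th <- utils::modifyList(list(interval = 5, start = 1984,
                               frac = c(control = 0, slow = 0.12,
                                        medium = 0.22)), thinning)
  # tolerate list-valued fields from YAML configs
  species_probs <- unlist(species_probs)
  dbh_lognormal <- unlist(dbh_lognormal)
  drought_years <- unlist(drought_years)
  years <- unlist(years); growth_years <- unlist(growth_years)
  cfg <- list(n_sites = n_sites, years = years, growth_years = growth_years,
              plot_side = plot_side, stem_density = stem_density,
              species_probs = species_probs, dbh_lognormal = dbh_lognormal,
              climate = cl, drought_years = drought_years, growth = gr,
              thinning = th, seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$species_probs) - 1) > 1e-9)
    stopf("species_probs must sum to 1")
  if (diff(cfg$years) + 1 < 30)
    stopf("climate span %d < 30 years: too short for SPEI calibration",
          diff(cfg$years) + 1)
  if (cfg$climate$ar1 < 0 || cfg$climate$ar1 >= 1)
    stopf("AR1 coefficient must be in [0, 1)")
  if (length(cfg$drought_years) &&
      (any(cfg$drought_years <= 0) || any(cfg$drought_years > 1)))
    stopf("drought multipliers must lie in (0, 1]")
  if (any(cfg$thinning$frac < 0) || any(cfg$thinning$frac >= 1))
    stopf("thinning removal fractions must lie in [0, 1)")
  if (any(c(cfg$growth$sd, cfg$growth$plot_sd, cfg$climate$temp_sd) < 0))
    stopf("variance parameters must be >= 0")
  if (cfg$plot_side <= 0) stopf("plot_side must be > 0")
  invisible(cfg)
}

#' Generate a monthly climate series for a site
#'
#' Mean temperature is an annual-mean plus seasonal sinusoid (peaking in
#' July) plus AR(1) noise; tmax/tmin sit half a diurnal range above/below;
#' monthly precipitation is gamma-distributed, multiplied by the configured
#' drought factor in March-July of drought years.
#'
#' @param config A [synth_config()].
#' @param site_id Site identifier (also seeds the site's random stream).
#' @return Data frame `site`, `latitude`, `year`, `month`, `tmin`, `tmean`,
#'   `tmax`, `prcp`.
#' @export
gen_climate <- function(config, site_id = "S1") {
  validate_synth_config(config)
  cl <- config$climate
  set.seed(derive_seed(config$seed, paste0("climate_", site_id)))
  yrs <- config$years[1]:config$years[2]
  n <- 12 * length(yrs)
  year <- rep(yrs, each = 12)
  month <- rep(1:12, length(yrs))
  innov_sd <- cl$temp_sd * sqrt(1 - cl$ar1^2)
  e <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), cl$ar1,
                                method = "recursive"))
  tmean <- cl$mat + cl$amplitude * sin(2 * pi * (month - 4) / 12) + e
  half <- cl$diurnal / 2
  prcp <- rgamma(n, shape = cl$prcp_shape, scale = cl$prcp_scale)
  for (dy in names(config$drought_years)) {
    hit <- year == as.integer(dy) & month %in% 3:7
    prcp[hit] <- prcp[hit] * config$drought_years[[dy]]
  }
  data.frame(site = site_id, latitude = cl$latitude, year = year,
             month = month, tmin = tmean - half, tmean = tmean,
             tmax = tmean + half, prcp = prcp)
}

#' Generate a mapped stand
#'
#' Tree count is Poisson in plot area, positions uniform in the square,
#' species i.i.d. from `species_probs` and DBH lognormal truncated below at
#' 4 cm.
#'
#' @param config A [synth_config()].
#' @param plot_id Plot identifier (also seeds the plot's random stream).
#' @return Data frame `tree_id`, `plot_id`, `species`, `x`, `y`, `dbh`
#'   (over-bark, cm).
#' @export
gen_stand <- function(config, plot_id = "P1") {
  validate_synth_config(config)
  set.seed(derive_seed(config$seed, paste0("stand_", plot_id)))
  area_ha <- config$plot_side^2 / 1e4
  n <- rpois(1, config$stem_density * area_ha)
  dbh <- rlnorm(n, config$dbh_lognormal[1], config$dbh_lognormal[2])
  while (any(dbh < 4))
    dbh[dbh < 4] <- rlnorm(sum(dbh < 4), config$dbh_lognormal[1],
                           config$dbh_lognormal[2])
  data.frame(tree_id = sprintf("%s_T%03d", plot_id, seq_len(n)),
             plot_id = plot_id,
             species = sample(names(config$species_probs), n, replace = TRUE,
                              prob = config$species_probs),
             x = runif(n, 0, config$plot_side),
             y = runif(n, 0, config$plot_side),
             dbh = dbh)
}

# greedy DBH-weighted selection of trees to remove, until the removed basal
# area reaches `frac` of the current total
thin_select <- function(dbh, frac) {
  ba <- tree_basal_area(dbh)
  target <- frac * sum(ba)
  ord <- sample(seq_along(dbh), prob = dbh)
  cum <- cumsum(ba[ord])
  ord[seq_len(sum(cum < target) + 1L)]
}

#' Simulate one plot through the experiment
#'
#' Runs the annual growth loop: SPEI is computed from the supplied climate
#' with the analysis pipeline's own routine, competition and stand basal
#' area are updated every year, thinning removes a DBH-weighted random
#' selection of trees in intervention years (winter, before growth), and
#' each live tree draws its BAI from the log-linear growth model.
#'
#' @param config A [synth_config()].
#' @param plot_id Plot identifier.
#' @param regime Thinning regime, one of the names of
#'   `config$thinning$frac` (default regimes: control, slow, medium).
#' @param climate Site climate from [gen_climate()]; generated on the fly
#'   when `NULL`.
#' @return List: `rwl` (ring widths, years x trees, mm), `inventory` (annual
#'   `tree_id`, `plot_id`, `species`, `x`, `y`, `year`, `dbh`, `status`),
#'   `membership` (`tree_id`, `plot_id`, `removal_year`), `schedule`
#'   (`plot_id`, `year`, `ba_removed` m2/ha), `apar` (a size-correlated
#'   light-absorption proxy per tree-year, GJ/tree/yr), `spei` (the SPEI
#'   series used), `truth` (the generating coefficients and plot effect),
#'   `floored` (count of ring widths floored at the minimum).
#' @export
simulate_plot <- function(config, plot_id = "P1", regime = "control",
                          climate = NULL) {
  validate_synth_config(config)
  gr <- config$growth
  th <- config$thinning
  if (!regime %in% names(th$frac))
    stopf("unknown thinning regime '%s'", regime)
  if (is.null(climate)) climate <- gen_climate(config, "S1")
  wb <- water_balance(climate)
  sp <- spei(wb, scale = gr$spei_scale, month = gr$spei_month)
  spei_of <- setNames(sp$spei, sp$year)

  stand <- gen_stand(config, plot_id)
  n <- nrow(stand)
  area_ha <- config$plot_side^2 / 1e4
  yrs <- config$growth_years[1]:config$growth_years[2]
  thin_years <- if (th$frac[[regime]] > 0)
    seq(th$start, max(yrs), by = th$interval) else integer()

  set.seed(derive_seed(config$seed, paste0("growth_", plot_id)))
  plot_eff <- rnorm(1, 0, gr$plot_sd)

  # inverse-distance weights within the competition radius, fixed positions
  d <- sqrt(outer(stand$x, stand$x, "-")^2 + outer(stand$y, stand$y, "-")^2)
  w <- ifelse(d > 0 & d <= gr$ni_radius, 1 / d, 0)

  dbh_ib <- stand$dbh * (1 - 2 * gr$bark_k)
  alive <- rep(TRUE, n)
  removal_year <- rep(NA_integer_, n)
  widths <- matrix(NA_real_, length(yrs), n,
                   dimnames = list(yrs, stand$tree_id))
  dbh_annual <- matrix(NA_real_, length(yrs), n,
                       dimnames = list(yrs, stand$tree_id))
  apar <- matrix(NA_real_, length(yrs), n,
                 dimnames = list(yrs, stand$tree_id))
  schedule <- data.frame(plot_id = character(), year = integer(),
                         ba_removed = numeric())
  floored <- 0L
  a_sp <- gr$a[stand$species]
  d_sp <- gr$d[stand$species]
  for (t in seq_along(yrs)) {
    y <- yrs[t]
    if (y %in% thin_years && sum(alive) > 2) {
      dbh_ob <- dbh_ib[alive] / (1 - 2 * gr$bark_k)
      rm_local <- thin_select(dbh_ob, th$frac[[regime]])
      rm_idx <- which(alive)[rm_local]
      schedule <- rbind(schedule, data.frame(
        plot_id = plot_id, year = y,
        ba_removed = sum(tree_basal_area(dbh_ob[rm_local])) / 1e4 / area_ha))
      alive[rm_idx] <- FALSE
      removal_year[rm_idx] <- y
    }
    ba_ob <- tree_basal_area(dbh_ib / (1 - 2 * gr$bark_k)) * alive
    ni <- as.vector(w %*% ba_ob)
    ba_stand <- sum(ba_ob) / 1e4 / area_ha
    idx <- which(alive)
    eps <- rnorm(length(idx), 0, gr$sd)
    log_bai <- a_sp[idx] + gr$b * log(dbh_ib[idx]) - gr$c * ni[idx] +
      d_sp[idx] * spei_of[as.character(y)] - gr$e * ba_stand +
      plot_eff + eps
    bai <- exp(log_bai)
    r_old <- dbh_ib[idx] / 2
    r_new <- sqrt(r_old^2 + bai / pi)
    wmm <- 10 * (r_new - r_old)
    low <- wmm < gr$min_width
    if (any(low)) {
      floored <- floored + sum(low)
      wmm[low] <- gr$min_width
      r_new[low] <- r_old[low] + gr$min_width / 10
    }
    widths[t, idx] <- wmm
    dbh_ib[idx] <- 2 * r_new
    dbh_annual[t, ] <- ifelse(alive, dbh_ib / (1 - 2 * gr$bark_k), NA)
    apar[t, idx] <- 5e-3 * ba_ob[idx]^0.9 * exp(rnorm(length(idx), 0, 0.15))
  }
  # bark measurements on harvested trees (at removal) and on trees standing
  # at the end: thickness = bark_k * DBH with 5% lognormal measurement noise
  bark_idx <- c(which(!is.na(removal_year)), which(alive))
  bark_year <- ifelse(is.na(removal_year[bark_idx]), max(yrs),
                      removal_year[bark_idx] - 1L)
  bark_dbh <- dbh_annual[cbind(match(bark_year, yrs), bark_idx)]
  bark_obs <- data.frame(
    tree_id = stand$tree_id[bark_idx], species = stand$species[bark_idx],
    dbh = bark_dbh,
    bark = gr$bark_k * bark_dbh * exp(rnorm(length(bark_idx), 0, 0.05)))
  bark_obs <- bark_obs[!is.na(bark_obs$dbh), ]
  inv <- data.frame(
    tree_id = rep(stand$tree_id, each = length(yrs)),
    plot_id = plot_id,
    species = rep(stand$species, each = length(yrs)),
    x = rep(stand$x, each = length(yrs)),
    y = rep(stand$y, each = length(yrs)),
    year = rep(yrs, n),
    dbh = as.vector(dbh_annual),
    status = ifelse(is.na(as.vector(dbh_annual)), "harvested", "live"))
  rwl <- as.data.frame(widths, check.names = FALSE)
  rwl <- rwl[, colSums(!is.na(rwl)) > 0, drop = FALSE]
  apar_long <- data.frame(tree_id = rep(stand$tree_id, each = length(yrs)),
                          year = rep(yrs, n), apar = as.vector(apar))
  apar_long <- apar_long[!is.na(apar_long$apar), ]
  list(rwl = rwl,
       inventory = inv[!is.na(inv$dbh) | inv$status == "harvested", ],
       membership = data.frame(tree_id = stand$tree_id, plot_id = plot_id,
                               species = stand$species,
                               removal_year = removal_year),
       stand = stand, schedule = schedule, apar = apar_long, spei = sp,
       bark_obs = bark_obs,
       truth = list(coefficients = gr[c("a", "b", "c", "d", "e", "sd",
                                        "plot_sd")],
                    plot_effect = plot_eff, regime = regime),
       floored = floored)
}

#' Thinning schedule and per-tree removal years for a plot
#'
#' Convenience wrapper around [simulate_plot()] exposing the management side
#' of the simulation.
#'
#' @inheritParams simulate_plot
#' @return List `schedule` (year, basal area removed in m2/ha) and `status`
#'   (`tree_id`, `removal_year`, NA while never removed).
#' @export
gen_thinning <- function(config, plot_id = "P1", regime = "slow",
                         climate = NULL) {
  sim <- simulate_plot(config, plot_id, regime, climate)
  list(schedule = sim$schedule,
       status = sim$membership[c("tree_id", "removal_year")])
}

#' Ring-width series with known generating coefficients
#'
#' Convenience wrapper around [simulate_plot()] exposing the dendro side of
#' the simulation.
#'
#' @inheritParams simulate_plot
#' @return List `rwl` (ring widths, mm), `truth` (generating coefficients),
#'   `spei` (the SPEI series that drove growth).
#' @export
gen_ring_widths <- function(config, plot_id = "P1", regime = "control",
                            climate = NULL) {
  sim <- simulate_plot(config, plot_id, regime, climate)
  sim[c("rwl", "truth", "spei")]
}

#' Simulate the full multi-site experiment
#'
#' One climate series per site and one plot per (site, regime) combination.
#'
#' @param config A [synth_config()].
#' @param regimes Thinning regimes instantiated at every site.
#' @return List with combined `inventory`, `membership`, `schedule`, `apar`,
#'   per-plot `rwl` list, per-site `climate` and `spei` lists, and `truth`.
#' @export
simulate_experiment <- function(config,
                                regimes = c("control", "slow", "medium")) {
  validate_synth_config(config)
  sites <- sprintf("S%d", seq_len(config$n_sites))
  plots <- list(); climates <- list(); speis <- list()
  inv <- list(); mem <- list(); sch <- list(); apar <- list(); truth <- list()
  bark <- list()
  for (s in sites) {
    climates[[s]] <- gen_climate(config, s)
    for (rg in regimes) {
      pid <- paste0(s, "_", rg)
      sim <- simulate_plot(config, pid, rg, climates[[s]])
      plots[[pid]] <- sim$rwl
      inv[[pid]] <- sim$inventory
      mem[[pid]] <- sim$membership
      if (nrow(sim$schedule)) sch[[pid]] <- sim$schedule
      apar[[pid]] <- sim$apar
      bark[[pid]] <- sim$bark_obs
      speis[[s]] <- sim$spei
      truth[[pid]] <- sim$truth
    }
  }
  list(rwl = plots,
       inventory = do.call(rbind, unname(inv)),
       membership = do.call(rbind, unname(mem)),
       schedule = if (length(sch)) do.call(rbind, unname(sch)) else
         data.frame(plot_id = character(), year = integer(),
                    ba_removed = numeric()),
       apar = do.call(rbind, unname(apar)),
       bark_obs = do.call(rbind, unname(bark)),
       climate = climates, spei = speis, truth = truth,
       plot_area_ha = config$plot_side^2 / 1e4)
}

#' Write a simulated experiment to plain-text files
#'
#' Ring widths go to one Tucson RWL file per plot; the inventory, climate,
#' thinning schedule and APAR tables to tab-delimited files; the generating
#' coefficients to a JSON ground-truth file.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(sim$rwl)) {
    rwl <- sim$rwl[[pid]]
    # one file per plot; series ids are the within-plot tree numbers so they
    # fit the 8-character Tucson id field
    colnames(rwl) <- sub(".*_(T[0-9]+)$", "\\1", colnames(rwl))
    write_rwl(rwl, file.path(dir, paste0(pid, ".rwl")))
  }
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  tsv(sim$inventory, "inventory.tsv")
  tsv(sim$membership, "membership.tsv")
  tsv(sim$schedule, "thinning.tsv")
  tsv(sim$apar, "apar.tsv")
  tsv(sim$bark_obs, "bark.tsv")
  tsv(do.call(rbind, unname(sim$climate)), "climate.tsv")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
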