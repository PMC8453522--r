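# End-to-end orchestration: simulate -> bai -> spei -> droughts ->
# covariates -> resilience -> fit, from one configuration list (or YAML
# file), with a machine-readable run manifest. Every stage is an exported
# function of this package; run_pipeline() only wires them together, so a
# composed run equals stage-by-stage invocation on the same intermediates.

#' Assemble a pipeline configuration
#'
#' @param synthetic List of [synth_config()] arguments for the simulated
#'   experiment.
#' @param analysis List of analysis parameters; defaults:
#'   `window = 2` (Lloret pre/post window, years), `ni_radius = 10` (m),
#'   `spei_month = 7`, `spei_scale = 5`, `select_window = FALSE` (set `TRUE`
#'   to pick the SPEI window by chronology correlation), `drought_periods`
#'   (year ranges for rank-based event selection; default first/second half
#'   of the growth years), `n_per_period = 2`, `edge_exclude = TRUE` (drop
#'   trees within `ni_radius` of the plot boundary from model fitting),
#'   `log_response = TRUE` (model indices on the natural-log scale),
#'   `tree_terms`, `stand_terms` (candidate model terms).
#' @param regimes Thinning regimes instantiated per site.
#' @param seed Master seed (overrides `synthetic$seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), analysis = list(),
                            regimes = c("control", "slow", "medium"),
                            seed = 1) {
  synthetic$seed <- seed
  ana <- utils::modifyList(
    list(window = 2, ni_radius = 10, spei_month = 7, spei_scale = 5,
         select_window = FALSE, drought_periods = NULL, n_per_period = 2,
         edge_exclude = TRUE, log_response = TRUE,
         tree_terms = c("species", "ratio_fir", "ratio_other",
                        "residual_ba", "spei", "apar"),
         stand_terms = c("shannon", "prop_spruce", "years_since_thinning",
                         "residual_ba")),
    analysis)
  structure(list(synthetic = synthetic, analysis = ana, regimes = regimes,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with optional blocks `synthetic`, `analysis`,
#'   `regimes`, `seed`.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  y <- yaml::read_yaml(path)
  pipeline_config(synthetic = y$synthetic %||% list(),
                  analysis = y$analysis %||% list(),
                  regimes = unlist(y$regimes %||%
                                     c("control", "slow", "medium")),
                  seed = y$seed %||% 1)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

signif_stars <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "°", ""))
}

# tree-level BAI for every measured tree of a simulated experiment
pipeline_bai <- function(sim, config) {
  bark_models <- lapply(split(sim$bark_obs, sim$bark_obs$species),
                        function(b) fit_bark_model(b$dbh, b$bark,
                                                   b$species[1]))
  bai_long <- list(); bai_wide <- list()
  for (pid in names(sim$rwl)) {
    rwl <- sim$rwl[[pid]]
    years <- as.integer(rownames(rwl))
    mem <- sim$membership[sim$membership$plot_id == pid, ]
    wide <- rwl
    for (id in colnames(rwl)) {
      ok <- !is.na(rwl[[id]])
      yr_last <- max(years[ok])
      inv_t <- sim$inventory[sim$inventory$tree_id == id &
                               sim$inventory$year == yr_last, ]
      bm <- bark_models[[mem$species[mem$tree_id == id]]]
      tb <- tree_bai(inv_t$dbh, bm, rwl[[id]][ok], years[ok], tree_id = id)
      wide[ok, id] <- tb$bai
      bai_long[[length(bai_long) + 1L]] <-
        cbind(tree_id = id, plot_id = pid, tb)
    }
    bai_wide[[pid]] <- wide
  }
  bai_long <- do.call(rbind, bai_long)
  list(tree = bai_long, wide = bai_wide,
       stand = stand_bai(bai_long[c("tree_id", "year", "bai")],
                         sim$membership))
}

# annual over-bark DBH from the 5-yearly inventory, per tree
dbh_at_year <- function(inv5, tree_ids, year) {
  vapply(tree_ids, function(id) {
    r <- inv5[inv5$tree_id == id & !is.na(inv5$dbh), ]
    interpolate_dbh(r$year, r$dbh, year)
  }, numeric(1))
}

# tree and stand covariates at one drought year
pipeline_covariates <- function(sim, events, config) {
  ana <- config$analysis
  gy <- range(sim$inventory$year)
  inv_years <- unique(c(seq(gy[1], gy[2], by = 5), gy[2]))
  inv5 <- sim$inventory[sim$inventory$year %in% inv_years, ]
  side <- sqrt(sim$plot_area_ha * 1e4)
  tree_rows <- list(); stand_rows <- list()
  for (k in seq_len(nrow(events))) {
    ev <- events$year[k]
    for (pid in unique(sim$membership$plot_id)) {
      mem <- sim$membership[sim$membership$plot_id == pid, ]
      alive <- mem[is.na(mem$removal_year) | mem$removal_year > ev, ]
      pos <- sim$inventory[match(alive$tree_id, sim$inventory$tree_id),
                           c("x", "y")]
      trees <- data.frame(tree_id = alive$tree_id, species = alive$species,
                          x = pos$x, y = pos$y,
                          dbh = dbh_at_year(inv5, alive$tree_id, ev))
      ni <- neighborhood_all(trees, radius = ana$ni_radius,
                             plot_bounds = c(side, side))
      sa <- stand_attributes(trees, sim$plot_area_ha)
      sch <- sim$schedule[sim$schedule$plot_id == pid, , drop = FALSE]
      mg <- management_covariates(
        if (nrow(sch)) sch else
          data.frame(year = integer(), ba_removed = numeric()),
        ev, sa$ba, start_year = gy[1])
      apar_pre <- sim$apar[sim$apar$year %in% (ev - 1:2) &
                             sim$apar$tree_id %in% alive$tree_id, ]
      apar_mu <- tapply(apar_pre$apar, apar_pre$tree_id, mean)
      tree_rows[[length(tree_rows) + 1L]] <- data.frame(
        tree_id = trees$tree_id, plot_id = pid, event = ev,
        class = events$class[k], species = trees$species,
        ni = ni$ni, ratio_fir = ni$ratio_fir,
        ratio_spruce = ni$ratio_spruce, ratio_other = ni$ratio_other,
        edge = ni$edge, residual_ba = sa$ba, shannon = sa$shannon,
        prop_spruce = sa$prop_spruce, spei = events$spei[k],
        apar = as.numeric(apar_mu[trees$tree_id]),
        years_since_thinning = mg$years_since_thinning)
      stand_rows[[length(stand_rows) + 1L]] <- cbind(
        data.frame(plot_id = pid, event = ev, class = events$class[k],
                   spei = events$spei[k],
                   apar = mean(apar_pre$apar)),
        sa[c("ba", "prop_fir", "prop_spruce", "prop_other", "shannon")],
        mg[c("ba_removed_total", "n_interventions", "years_since_thinning")])
    }
  }
  stand_cov <- do.call(rbind, stand_rows)
  names(stand_cov)[names(stand_cov) == "ba"] <- "residual_ba"
  list(tree = do.call(rbind, tree_rows), stand = stand_cov)
}

# model frames, screening and all-subsets selection for one drought class
fit_class_models <- function(frame, terms, responses, group, config) {
  ana <- config$analysis
  out <- list()
  for (resp in responses) {
    dat <- frame
    dat$.y <- if (ana$log_response) log(dat[[resp]]) else dat[[resp]]
    num_terms <- setdiff(terms, "species")
    num_terms <- num_terms[vapply(num_terms, function(tm)
      sd(dat[[tm]]) > 0, logical(1))]
    dat <- standardize(dat, num_terms)
    kept <- screen_predictors(dat, num_terms, ".y")
    cand <- c(intersect(terms, "species"), kept)
    out[[resp]] <- tryCatch(
      all_subsets_aicc(dat, ".y", cand, group = group),
      error = function(e) {
        message("model for '", resp, "' skipped: ", conditionMessage(e))
        list(best = NULL, ranking = NULL, log = conditionMessage(e))
      })
  }
  out
}

#' Run the full drought-response pipeline
#'
#' Simulates the experiment, converts rings to BAI, computes SPEI and
#' drought events, derives competition/stand/management covariates,
#' calculates Lloret indices, and fits the tree- and stand-level model
#' protocol. When `out_dir` is given, all intermediates are persisted as
#' plain delimited tables together with a JSON run manifest.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Optional output directory.
#' @return List: `sim`, `bai`, `spei` (per site), `events`, `covariates`,
#'   `indices` (tree/detrended/stand), `comparisons` (Kruskal-Wallis),
#'   `models` (per level x class x response), `tables` (report tables),
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  ana <- config$analysis

  sim <- run_stage("simulate", {
    cfg <- do.call(synth_config, config$synthetic)
    simulate_experiment(cfg, regimes = config$regimes)
  })
  bai <- run_stage("bai", pipeline_bai(sim, config))

  spei_site <- run_stage("spei", {
    lapply(sim$climate, function(cl) {
      wb <- water_balance(cl)
      if (isTRUE(ana$select_window)) {
        long <- lapply(names(bai$wide), function(pid) {
          w <- sim$rwl[[pid]]
          w[, colSums(!is.na(w)) >= 10, drop = FALSE]
        })
        idx <- detrend_rwl(do.call(cbind, long))
        win <- select_spei_window(wb, build_chronology(idx))
        spei(wb, scale = win$scale, month = win$month)
      } else {
        spei(wb, scale = ana$spei_scale, month = ana$spei_month)
      }
    })
  })

  events <- run_stage("droughts", {
    gy <- range(sim$inventory$year)
    periods <- ana$drought_periods %||%
      list(c(gy[1], gy[1] + floor(diff(gy) / 2)),
           c(gy[1] + floor(diff(gy) / 2) + 1, gy[2]))
    w <- ana$window
    ev <- identify_drought_events(spei_site, mode = "rank",
                                  periods = periods,
                                  n_per_period = ana$n_per_period)
    # keep events whose pre/post windows fit the growth record and do not
    # overlap one another
    ev <- ev[ev$year - w >= gy[1] & ev$year + w <= gy[2], ]
    while (nrow(ev) > 1 && any(diff(ev$year) <= 2 * w))
      ev <- ev[-(which(diff(ev$year) <= 2 * w)[1] + 1), ]
    ev
  })
  if (nrow(events) == 0) stopf("pipeline stage 'droughts': no usable event")

  cov <- run_stage("covariates", pipeline_covariates(sim, events, config))

  indices <- run_stage("resilience", {
    tree_idx <- list()
    for (pid in names(bai$wide))
      tree_idx[[pid]] <- resilience_table(bai$wide[[pid]], events$year,
                                          window = ana$window)
    tree_idx <- do.call(rbind, tree_idx)
    det_idx <- list()
    for (pid in names(sim$rwl)) {
      w <- sim$rwl[[pid]]
      w <- w[, colSums(!is.na(w)) >= 10, drop = FALSE]
      if (ncol(w))
        det_idx[[pid]] <- resilience_table(detrend_rwl(w), events$year,
                                           window = ana$window,
                                           basis = "detrended_index")
    }
    st <- do.call(rbind, lapply(events$year, function(ev)
      stand_indices(bai$stand, ev, window = ana$window)))
    list(tree = tree_idx, detrended = do.call(rbind, det_idx), stand = st)
  })

  comparisons <- run_stage("resilience", {
    ti <- merge(indices$tree,
                unique(cov$tree[c("tree_id", "event", "class", "species")]),
                by.x = c("owner_id", "event"),
                by.y = c("tree_id", "event"))
    lapply(setNames(c("resistance", "recovery", "resilience"),
                    c("resistance", "recovery", "resilience")),
           function(v) {
             if (length(unique(ti$class)) < 2) {
               message("only one drought class realised; ",
                       "class comparison skipped")
               return(NULL)
             }
             compare_groups(ti[[v]], ti$class)
           })
  })

  models <- run_stage("fit", {
    ti <- merge(indices$tree, cov$tree,
                by.x = c("owner_id", "event"),
                by.y = c("tree_id", "event"))
    ti <- ti[ti$species %in% c("fir", "spruce"), ]
    if (isTRUE(ana$edge_exclude)) ti <- ti[!ti$edge, ]
    ti$species <- factor(ti$species, levels = c("spruce", "fir"))
    si <- merge(indices$stand, cov$stand,
                by.x = c("owner_id", "event"),
                by.y = c("plot_id", "event"))
    responses <- c("resistance", "recovery", "resilience")
    out <- list()
    for (cls in unique(events$class)) {
      out[[paste0("tree_", cls)]] <-
        fit_class_models(ti[ti$class == cls, ], ana$tree_terms, responses,
                         group = "plot_id", config)
      scls <- si[si$class == cls, ]
      out[[paste0("stand_", cls)]] <- lapply(
        setNames(responses, responses), function(resp) {
          dat <- scls
          dat$.y <- if (ana$log_response) log(dat[[resp]]) else dat[[resp]]
          terms <- ana$stand_terms[vapply(ana$stand_terms, function(tm)
            sd(dat[[tm]]) > 0, logical(1))]
          dat <- standardize(dat, terms)
          tryCatch(fit_stand_models(dat, ".y", terms),
                   error = function(e) {
                     message("stand model for '", resp, "' (", cls,
                             ") skipped: ", conditionMessage(e))
                     list(best = NULL, ranking = NULL,
                          log = conditionMessage(e))
                   })
        })
    }
    out
  })

  tables <- pipeline_tables(models)
  manifest <- list(
    package = "standres",
    version = as.character(utils::packageVersion("standres")),
    seed = config$seed,
    parameters = config[c("synthetic", "analysis", "regimes")],
    n_trees = length(unique(sim$membership$tree_id)),
    n_plots = length(unique(sim$membership$plot_id)),
    events = events)

  res <- list(sim = sim, bai = bai, spei = spei_site, events = events,
              covariates = cov, indices = indices,
              comparisons = comparisons, models = models, tables = tables,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

# report tables: best-model coefficients per level/class/response, and the
# per-predictor effect-size table
pipeline_tables <- function(models) {
  coefs <- list(); effects <- list()
  for (nm in names(models)) {
    lv <- sub("_.*", "", nm); cls <- sub(".*_", "", nm)
    for (resp in names(models[[nm]])) {
      best <- models[[nm]][[resp]]$best
      if (is.null(best)) next
      cf <- best$coefficients
      p <- 2 * pnorm(-abs(cf$estimate / cf$se))
      coefs[[length(coefs) + 1L]] <- data.frame(
        level = lv, class = cls, response = resp, term = cf$term,
        estimate = cf$estimate, se = cf$se, stars = signif_stars(p),
        r2m = best$r2m, r2c = best$r2c,
        r2adj = best$r2adj %||% NA_real_)
      es <- effect_sizes(best)
      if (length(es))
        effects[[length(effects) + 1L]] <- data.frame(
          level = lv, class = cls, response = resp, term = names(es),
          effect_size = unname(es))
    }
  }
  list(coefficients = if (length(coefs)) do.call(rbind, coefs) else
         data.frame(),
       effect_sizes = if (length(effects)) do.call(rbind, effects) else
         data.frame())
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_simulation(res$sim, file.path(out_dir, "sim"))
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    row.names = FALSE, quote = FALSE)
  tsv(res$bai$tree, "bai_tree.tsv")
  tsv(res$bai$stand, "bai_stand.tsv")
  tsv(do.call(rbind, lapply(names(res$spei), function(s)
    cbind(site = s, res$spei[[s]]))), "spei.tsv")
  tsv(res$events, "drought_events.tsv")
  tsv(res$covariates$tree, "covariates_tree.tsv")
  tsv(res$covariates$stand, "covariates_stand.tsv")
  tsv(res$indices$tree, "indices_tree.tsv")
  tsv(res$indices$stand, "indices_stand.tsv")
  tsv(res$tables$coefficients, "model_coefficients.tsv")
  tsv(res$tables$effect_sizes, "effect_sizes.tsv")
  rel <- list.files(out_dir, recursive = TRUE)
  rel <- rel[!grepl("manifest", rel)]
  dig <- tools::md5sum(file.path(out_dir, rel))
  res$manifest$input_digests <- as.list(setNames(unname(dig), rel))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
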