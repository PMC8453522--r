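# Mapped-stand covariates: distance-dependent competition, composition,
# diversity and management descriptors.

#' Tree basal area from DBH
#'
#' @param dbh Diameter at breast height (cm).
#' @return Basal area in cm2, `pi * (dbh/2)^2`.
#' @export
tree_basal_area <- function(dbh) pi * (dbh / 2)^2

#' Interpolate periodic inventory DBH to annual values
#'
#' Linear interpolation between inventories, constant extrapolation before
#' the first and after the last measurement.
#'
#' @param inv_years Inventory years.
#' @param inv_dbh DBH (cm) at those years.
#' @param years Target years.
#' @return DBH (cm) at every target year.
#' @export
interpolate_dbh <- function(inv_years, inv_dbh, years) {
  o <- order(inv_years)
  inv_years <- inv_years[o]; inv_dbh <- inv_dbh[o]
  if (any(diff(inv_dbh) < 0))
    warnf("decreasing DBH between inventories; kept as measured")
  if (length(inv_years) == 1) return(rep(inv_dbh, length(years)))
  approx(inv_years, inv_dbh, xout = years, rule = 2)$y
}

#' Distance-dependent neighborhood competition index
#'
#' For a focal tree, `NI = sum(BA_i / distance_i)` over live neighbors with
#' `0 < distance <= radius`, plus per-species-group ratios `NI_sp / NI`.
#'
#' @param focal_id Tree id of the focal tree.
#' @param trees Data frame `tree_id`, `species`, `x`, `y`, `dbh` (cm) of all
#'   live trees in the focal year (the focal tree included).
#' @param radius Neighborhood radius (m), default 10.
#' @param plot_bounds Optional `c(xmax, ymax)` (plot assumed `[0, xmax] x
#'   [0, ymax]`) used to flag edge trees via [edge_filter()].
#' @return One-row data frame `tree_id`, `ni` (cm2/m), `ratio_fir`,
#'   `ratio_spruce`, `ratio_other` (NA when `ni = 0`), `edge` (logical or NA
#'   when no bounds given).
#' @export
neighborhood_index <- function(focal_id, trees, radius = 10,
                               plot_bounds = NULL) {
  f <- trees[trees$tree_id == focal_id, ]
  if (nrow(f) != 1) stopf("focal tree '%s' not found exactly once", focal_id)
  d <- sqrt((trees$x - f$x)^2 + (trees$y - f$y)^2)
  if (any(d == 0 & trees$tree_id != focal_id)) {
    other <- trees$tree_id[d == 0 & trees$tree_id != focal_id][1]
    stopf("trees '%s' and '%s' have coincident positions", focal_id, other)
  }
  nb <- d > 0 & d <= radius
  ba_d <- tree_basal_area(trees$dbh[nb]) / d[nb]
  ni <- sum(ba_d)
  grp <- function(sp) sum(ba_d[trees$species[nb] == sp])
  if (ni > 0) {
    ratios <- c(grp("fir"), grp("spruce"), grp("other")) / ni
  } else {
    ratios <- rep(NA_real_, 3)
  }
  edge <- if (is.null(plot_bounds)) NA else
    edge_filter(f$x, f$y, plot_bounds, radius)
  data.frame(tree_id = focal_id, ni = ni, ratio_fir = ratios[1],
             ratio_spruce = ratios[2], ratio_other = ratios[3], edge = edge)
}

#' Competition index for every live tree of a plot-year
#'
#' Vectorised [neighborhood_index()] over all live trees, using a shared
#' distance matrix.
#'
#' @inheritParams neighborhood_index
#' @return Data frame with one row per tree, as in [neighborhood_index()].
#' @export
neighborhood_all <- function(trees, radius = 10, plot_bounds = NULL) {
  n <- nrow(trees)
  dx <- outer(trees$x, trees$x, "-")
  dy <- outer(trees$y, trees$y, "-")
  d <- sqrt(dx^2 + dy^2)
  off <- d[upper.tri(d)]
  if (any(off == 0)) stopf("coincident tree positions in plot")
  w <- ifelse(d > 0 & d <= radius, 1 / d, 0)
  ba <- tree_basal_area(trees$dbh)
  ni <- as.vector(w %*% ba)
  ni_sp <- vapply(c("fir", "spruce", "other"), function(sp)
    as.vector(w %*% (ba * (trees$species == sp))), numeric(n))
  ratios <- ni_sp / ifelse(ni > 0, ni, NA)
  edge <- if (is.null(plot_bounds)) NA else
    edge_filter(trees$x, trees$y, plot_bounds, radius)
  data.frame(tree_id = trees$tree_id, ni = ni,
             ratio_fir = ratios[, 1], ratio_spruce = ratios[, 2],
             ratio_other = ratios[, 3], edge = edge)
}

#' Choose the competition radius by predictive power
#'
#' For each candidate radius, regresses periodic annual BAI on NI and records
#' the R-squared; returns the radius with the highest R-squared (ties go to
#' the smallest radius).
#'
#' @param radii Candidate radii (m).
#' @param bai Periodic annual BAI (cm2/yr), one value per tree in `trees`.
#' @param trees Data frame as in [neighborhood_all()] (live trees, one year).
#' @param plot_bounds Optional bounds; edge trees are dropped from the
#'   regression.
#' @return List `radius`, `r2` (named vector over candidates).
#' @export
optimize_radius <- function(radii, bai, trees, plot_bounds = NULL) {
  r2 <- vapply(radii, function(r) {
    ni <- neighborhood_all(trees, radius = r, plot_bounds = plot_bounds)
    keep <- if (is.null(plot_bounds)) rep(TRUE, nrow(ni)) else !ni$edge
    summary(lm(bai[keep] ~ ni$ni[keep]))$r.squared
  }, numeric(1))
  names(r2) <- radii
  list(radius = radii[which.max(r2)], r2 = r2)
}

#' Shannon diversity of species basal-area shares
#'
#' `H = -sum(p_i * log(p_i))` over species with positive share, computed with
#' the standard community-ecology routine.
#'
#' @param p Basal-area proportions (or abundances) by species.
#' @return Shannon index (natural log).
#' @export
shannon_index <- function(p) {
  unname(vegan::diversity(matrix(p, nrow = 1), index = "shannon"))
}

#' Stand-level structure attributes for one year
#'
#' @param trees Data frame `species`, `dbh` (cm) of live trees in the year.
#' @param area_ha Plot area in hectares.
#' @return One-row data frame: `ba` (m2/ha), `prop_fir`, `prop_spruce`,
#'   `prop_other` (shares of basal area), `shannon`, `density` (stems/ha).
#' @export
stand_attributes <- function(trees, area_ha) {
  ba_cm2 <- tree_basal_area(trees$dbh)
  tot <- sum(ba_cm2)
  p <- vapply(c("fir", "spruce", "other"), function(sp)
    sum(ba_cm2[trees$species == sp]) / tot, numeric(1))
  data.frame(ba = tot / 1e4 / area_ha, prop_fir = p[1], prop_spruce = p[2],
             prop_other = p[3], shannon = shannon_index(p[p > 0]),
             density = nrow(trees) / area_ha)
}

#' Management covariates at a drought year
#'
#' @param schedule Data frame `year`, `ba_removed` (m2/ha) of thinning
#'   events for one plot (zero-removal rows are ignored).
#' @param drought_year Drought year.
#' @param residual_ba Residual stand basal area (m2/ha) at the drought year,
#'   e.g. from [stand_attributes()].
#' @param start_year First year of the experiment, used (with a flag) when no
#'   intervention precedes the drought.
#' @return One-row data frame: `residual_ba`, `ba_removed_total`,
#'   `ba_removed_last`, `n_interventions`, `years_since_thinning`,
#'   `no_prior_thinning`.
#' @export
management_covariates <- function(schedule, drought_year, residual_ba,
                                  start_year = NULL) {
  sch <- schedule[schedule$ba_removed > 0 & schedule$year < drought_year, ]
  none <- nrow(sch) == 0
  if (none && is.null(start_year))
    stopf("no intervention before %d and no start_year given", drought_year)
  data.frame(
    residual_ba = residual_ba,
    ba_removed_total = if (none) 0 else sum(sch$ba_removed),
    ba_removed_last = if (none) 0 else sch$ba_removed[which.max(sch$year)],
    n_interventions = nrow(sch),
    years_since_thinning = drought_year -
      (if (none) start_year else max(sch$year)),
    no_prior_thinning = none)
}

#' Edge exclusion for boundary trees
#'
#' A tree closer than `radius` to any plot edge has an incomplete
#' neighborhood; `TRUE` means exclude. A tree at exactly `radius` is kept
#' (strict inequality).
#'
#' @param x,y Tree coordinates (m), plot assumed `[0, xmax] x [0, ymax]`.
#' @param plot_bounds `c(xmax, ymax)` in m.
#' @param radius Buffer width (m).
#' @return Logical vector, `TRUE` = within the edge buffer.
#' @export
edge_filter <- function(x, y, plot_bounds, radius = 10) {
  pmin(x, plot_bounds[1] - x, y, plot_bounds[2] - y) < radius
}
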