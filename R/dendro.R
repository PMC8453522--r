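# Ring widths to basal area increment.
#
# Calendar convention: the ring of year t is the growth of calendar year t
# (discs sampled after the growing season). Radii are averaged on ring widths
# before any BAI conversion, giving one reconstruction per tree.

#' Average measurement radii into per-tree series
#'
#' Computes the per-year arithmetic mean over all radii measured on the same
#' tree, using whichever radii cover a given year.
#'
#' @param rwl Ring-width data frame (years x series, mm), e.g. from
#'   [read_rwl()].
#' @param tree_of Either a named character vector mapping series id to tree
#'   id, or `NULL` to derive the tree id by stripping a single trailing
#'   letter from the series id (`"T001A"`, `"T001B"` -> `"T001"`).
#' @return Ring-width data frame with one column per tree.
#' @export
average_radii <- function(rwl, tree_of = NULL) {
  ids <- colnames(rwl)
  if (is.null(tree_of)) {
    tree_of <- setNames(sub("(?<=.)[A-Za-z]$", "", ids, perl = TRUE), ids)
  }
  trees <- unique(unname(tree_of[ids]))
  out <- as.data.frame(matrix(NA_real_, nrow(rwl), length(trees),
                              dimnames = list(rownames(rwl), trees)),
                       check.names = FALSE)
  for (tr in trees) {
    cols <- ids[tree_of[ids] == tr]
    m <- as.matrix(rwl[, cols, drop = FALSE])
    mu <- rowMeans(m, na.rm = TRUE)
    mu[!is.finite(mu)] <- NA_real_
    out[[tr]] <- mu
  }
  out
}

#' Fit a species-specific bark thickness model
#'
#' Least-squares fit of bark thickness as a function of over-bark DBH. The
#' default form is linear; a square-root form is available for species whose
#' bark allometry saturates.
#'
#' @param dbh Over-bark DBH (cm).
#' @param bark Single bark thickness (cm) at the same stems.
#' @param species Species label stored with the model.
#' @param form `"linear"` (`bark = a + b * dbh`) or `"sqrt"`
#'   (`bark = a + b * sqrt(dbh)`).
#' @return An object of class `bark_model` with coefficients and residual SD.
#' @export
fit_bark_model <- function(dbh, bark, species = "all", form = c("linear", "sqrt")) {
  form <- match.arg(form)
  if (length(dbh) < 3) stopf("need >= 3 (dbh, bark) pairs per species")
  x <- if (form == "sqrt") sqrt(dbh) else dbh
  fit <- lm(bark ~ x)
  structure(list(species = species, form = form,
                 coefficients = unname(coef(fit)), sigma = sigma(fit)),
            class = "bark_model")
}

#' Predict bark thickness from a bark model
#'
#' @param model A [fit_bark_model()] object, or `NULL` for zero bark.
#' @param dbh Over-bark DBH (cm).
#' @return Bark thickness (cm), clamped at zero; errors if the predicted
#'   double bark thickness reaches the stem diameter.
#' @export
bark_thickness <- function(model, dbh) {
  if (is.null(model)) return(rep(0, length(dbh)))
  x <- if (model$form == "sqrt") sqrt(dbh) else dbh
  bt <- pmax(model$coefficients[1] + model$coefficients[2] * x, 0)
  if (any(2 * bt >= dbh & dbh > 0))
    stopf("bark model predicts 2*bark >= DBH within the observed range")
  bt
}

#' Backwards reconstruction of inside-bark DBH
#'
#' Subtracts modelled bark thickness from the over-bark DBH at sampling, then
#' steps backwards through the ring series:
#' `DBH_ib(t - 1) = DBH_ib(t) - 2 * width(t)`.
#'
#' When twice the cumulated ring widths exceeds the inside-bark DBH at
#' sampling by at most 5% the widths are rescaled proportionally (with a
#' warning and a `rescaled` attribute) so the pith radius is exactly zero;
#' a larger excess is a reconstruction error.
#'
#' @param dbh_ob Over-bark DBH (cm) at the sampling date.
#' @param bark_model A [fit_bark_model()] object or `NULL` (no bark).
#' @param widths Ring widths (mm), oldest first.
#' @param years Calendar years of the rings (defaults to positions).
#' @param tree_id Label used in diagnostics.
#' @return Data frame `year`, `dbh_ib` (cm, at the end of each growth year),
#'   with attribute `dbh_ib0` (before the first ring) and `rescaled`.
#' @export
reconstruct_dbh_inside_bark <- function(dbh_ob, bark_model, widths,
                                        years = seq_along(widths),
                                        tree_id = "tree") {
  w_cm <- widths / 10
  dbh_ib <- dbh_ob - 2 * bark_thickness(bark_model, dbh_ob)
  rescaled <- FALSE
  tot <- 2 * sum(w_cm)
  if (tot > dbh_ib) {
    if (tot > 1.05 * dbh_ib)
      stopf("tree '%s': cumulated ring widths exceed inside-bark DBH by %.1f%%",
            tree_id, 100 * (tot / dbh_ib - 1))
    warnf("tree '%s': ring widths rescaled by %.3f to fit inside-bark DBH",
          tree_id, dbh_ib / tot)
    w_cm <- w_cm * dbh_ib / tot
    rescaled <- TRUE
  }
  d <- dbh_ib - 2 * rev(cumsum(rev(c(w_cm[-1], 0))))
  d0 <- d[1] - 2 * w_cm[1]
  if (any(c(d0, d) < -1e-9))
    stopf("tree '%s': negative reconstructed DBH", tree_id)
  out <- data.frame(year = years, dbh_ib = d)
  attr(out, "dbh_ib0") <- max(d0, 0)
  attr(out, "rescaled") <- rescaled
  out
}

#' Basal area increment from an annual radius series
#'
#' `BAI(t) = pi * (r(t)^2 - r(t-1)^2)` in cm2.
#'
#' @param radius Annual stem radius series (cm), non-decreasing.
#' @param r0 Radius before the first year (cm), default 0 (pith).
#' @return Numeric vector of BAI (cm2/yr), same length as `radius`.
#' @export
bai_from_rings <- function(radius, r0 = 0) {
  r <- c(r0, radius)
  if (any(diff(r) < -1e-12)) stopf("radius series must be non-decreasing")
  pi * diff(r^2)
}

#' Tree-level BAI from ring widths and sampling DBH
#'
#' Convenience wrapper: backwards DBH reconstruction followed by BAI
#' conversion.
#'
#' @inheritParams reconstruct_dbh_inside_bark
#' @return Data frame `year`, `bai` (cm2/yr).
#' @export
tree_bai <- function(dbh_ob, bark_model, widths, years = seq_along(widths),
                     tree_id = "tree") {
  rec <- reconstruct_dbh_inside_bark(dbh_ob, bark_model, widths, years, tree_id)
  r0 <- attr(rec, "dbh_ib0") / 2
  data.frame(year = rec$year, bai = bai_from_rings(rec$dbh_ib / 2, r0 = r0))
}

#' Mean ring-width index chronology
#'
#' Per-year arithmetic mean of detrended ring-width indices across trees,
#' with the number of contributing series (sample depth) per year.
#'
#' @param index Data frame of index series (years x trees), e.g. from
#'   [detrend_rwl()].
#' @return Data frame `year`, `index`, `depth`.
#' @export
build_chronology <- function(index) {
  m <- as.matrix(index)
  depth <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  mu[depth == 0] <- NA_real_
  out <- data.frame(year = as.integer(rownames(index)), index = mu,
                    depth = depth)
  rownames(out) <- NULL
  out[out$depth >= 1, ]
}

#' Stand-level BAI
#'
#' Sums tree-level BAI per stand and year over trees that are still standing:
#' removal occurs in the winter before the growing season, so a tree removed
#' in year y contributes nothing from y onwards.
#'
#' @param bai Long data frame `tree_id`, `year`, `bai` (cm2/yr).
#' @param membership Data frame `tree_id`, `plot_id` and optional
#'   `removal_year` (NA when never removed).
#' @return Data frame `plot_id`, `year`, `bai` (cm2/yr) covering every
#'   plot x year in the range of `bai`; empty stand-years are 0 with a
#'   warning.
#' @export
stand_bai <- function(bai, membership) {
  if (!"removal_year" %in% names(membership)) membership$removal_year <- NA
  m <- merge(bai, membership, by = "tree_id")
  m <- m[is.na(m$removal_year) | m$year < m$removal_year, ]
  grid <- expand.grid(plot_id = unique(membership$plot_id),
                      year = seq(min(bai$year), max(bai$year)),
                      stringsAsFactors = FALSE)
  agg <- aggregate(bai ~ plot_id + year, m, sum)
  out <- merge(grid, agg, by = c("plot_id", "year"), all.x = TRUE)
  if (anyNA(out$bai)) {
    warnf("%d stand-years with no live measured tree; BAI set to 0",
          sum(is.na(out$bai)))
    out$bai[is.na(out$bai)] <- 0
  }
  out[order(out$plot_id, out$year), ]
}
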