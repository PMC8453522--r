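# Lloret resistance / recovery / resilience around single drought years.
#
# Resistance  Rt = BAI_drought / mean(BAI of the `window` years before)
# Recovery    Rc = mean(BAI of the `window` years after) / BAI_drought
# Resilience  Rs = mean(after) / mean(before) = Rt * Rc
#
# The default window of 2 years keeps the indices inside the span of growth
# legacies while limiting confounding by unrelated good or bad years.

#' Lloret indices for one series and one event
#'
#' @param values Annual growth values (BAI in cm2/yr, or a detrended index).
#' @param years Calendar years of `values`.
#' @param event Drought year.
#' @param window Years before/after the event to average (default 2).
#' @param basis Label stored with the result (`"bai"` or `"detrended_index"`).
#' @param owner_id Identifier stored with the result.
#' @return One-row data frame `owner_id`, `event`, `resistance`, `recovery`,
#'   `resilience`, `window`, `basis`.
#' @export
lloret_indices <- function(values, years = seq_along(values), event,
                           window = 2, basis = "bai", owner_id = "series") {
  if (window < 1) stopf("window must be >= 1")
  need <- (event - window):(event + window)
  if (!all(need %in% years[!is.na(values)]))
    stopf("series '%s' does not fully cover %d-%d around event %d",
          owner_id, min(need), max(need), event)
  v <- values[match(need, years)]
  pre <- mean(v[seq_len(window)])
  dr <- v[window + 1]
  post <- mean(v[window + 1 + seq_len(window)])
  if (dr == 0 || pre == 0)
    stopf("series '%s': zero growth in pre/drought window, index undefined",
          owner_id)
  data.frame(owner_id = owner_id, event = event, resistance = dr / pre,
             recovery = post / dr, resilience = post / pre,
             window = window, basis = basis)
}

#' Lloret indices on a spline-detrended series
#'
#' Identical arithmetic applied to the detrended ring-width index; used to
#' verify that the raw-BAI indices are not driven by age/size trends.
#'
#' @param widths Ring widths or BAI values to detrend (see
#'   [spline_detrend()]).
#' @inheritParams lloret_indices
#' @inheritParams spline_detrend
#' @export
lloret_on_detrended <- function(widths, years = seq_along(widths), event,
                                window = 2, wavelength = NULL,
                                owner_id = "series") {
  idx <- spline_detrend(widths, wavelength, tree_id = owner_id)
  lloret_indices(as.numeric(idx), years, event, window,
                 basis = "detrended_index", owner_id = owner_id)
}

#' Lloret indices for every tree and event
#'
#' Applies [lloret_indices()] to each column of a wide BAI table. Trees whose
#' series do not fully cover an event window (e.g. harvested within the
#' post-drought years) are excluded with a message. Events whose pre/post
#' windows overlap another selected event are rejected.
#'
#' @param bai_wide Data frame (years as rownames, one column per tree) of
#'   BAI values.
#' @param events Integer vector of drought years.
#' @param window Window length (years).
#' @param basis Basis label.
#' @return Data frame of indices, one row per tree x event.
#' @export
resilience_table <- function(bai_wide, events, window = 2, basis = "bai") {
  events <- sort(events)
  if (length(events) > 1 && any(diff(events) <= 2 * window))
    stopf("event windows overlap: events %s are closer than %d years",
          paste(events, collapse = ", "), 2 * window + 1)
  years <- as.integer(rownames(bai_wide))
  out <- list()
  skipped <- 0L
  for (ev in events) {
    for (id in colnames(bai_wide)) {
      res <- tryCatch(
        lloret_indices(bai_wide[[id]], years, ev, window, basis, id),
        error = function(e) NULL)
      if (is.null(res)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- res
    }
  }
  if (skipped > 0)
    message(skipped, " tree-event series excluded (incomplete window coverage)")
  do.call(rbind, out)
}

#' Stand-level Lloret indices
#'
#' Applies the Lloret arithmetic to the summed stand BAI series (the sum of
#' the trees measured in each year), not to the mean of tree-level ratios:
#' large trees therefore weigh in proportionally to their growth.
#'
#' @param stand_bai Data frame `plot_id`, `year`, `bai` from [stand_bai()].
#' @param event Drought year.
#' @param window Window length (years).
#' @return Data frame with one row per plot.
#' @export
stand_indices <- function(stand_bai, event, window = 2) {
  do.call(rbind, lapply(split(stand_bai, stand_bai$plot_id), function(s) {
    lloret_indices(s$bai, s$year, event, window, basis = "bai",
                   owner_id = s$plot_id[1])
  }))
}

#' Kruskal-Wallis comparison of index values across groups
#'
#' Rank-based Kruskal-Wallis test with tie correction, for comparing drought
#' classes, forest components (fir / spruce / whole stand) or treatments.
#'
#' @param values Index values.
#' @param groups Group labels, same length.
#' @return List `H`, `df`, `p`.
#' @export
compare_groups <- function(values, groups) {
  n <- table(groups)
  if (any(n < 2)) stopf("every group needs n >= 2 (smallest has %d)", min(n))
  k <- kruskal.test(values, factor(groups))
  list(H = unname(k$statistic), df = unname(k$parameter), p = k$p.value)
}
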