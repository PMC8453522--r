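# Standardized Precipitation-Evapotranspiration Index.
#
# The k-month water-balance sum ending at a target month is transformed to a
# standard normal deviate through a three-parameter log-logistic distribution
# fitted by unbiased probability-weighted moments (PWM), one fit per target
# month so that seasonality is removed from the standardized index.

# unbiased PWM estimators b0, b1, b2 (Landwehr plotting-position free form)
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  c(mean(x),
    sum((i - 1) / (n - 1) * x) / n,
    sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n)
}

# Three-parameter (shifted) log-logistic distribution in its generalized-
# logistic parameterization (location xi, scale a, shape k), fitted from the
# first three L-moments (Hosking): k = -t3, a = l2 * sin(k*pi) / (k*pi),
# xi = l1 - a * (1/k - pi/sin(k*pi)). This handles water-balance samples of
# either skew; k -> 0 recovers the plain logistic.
fit_loglogistic <- function(x) {
  if (length(unique(x)) < 3 || sd(x) < sqrt(.Machine$double.eps))
    stopf("degenerate water-balance sample: cannot fit distribution")
  b <- pwm_unbiased(x)
  l1 <- b[1]
  l2 <- 2 * b[2] - b[1]
  t3 <- (6 * b[3] - 6 * b[2] + b[1]) / l2
  if (!is.finite(t3) || abs(t3) >= 1)
    stopf("log-logistic fit failed (L-skewness %.3f)", t3)
  k <- -t3
  if (abs(k) < 1e-8) {
    a <- l2
    xi <- l1
  } else {
    a <- l2 * sin(k * pi) / (k * pi)
    xi <- l1 - a * (1 / k - pi / sin(k * pi))
  }
  c(xi = xi, a = a, k = k)
}

ploglogistic <- function(x, par) {
  xi <- par[["xi"]]; a <- par[["a"]]; k <- par[["k"]]
  if (abs(k) < 1e-8) {
    y <- (x - xi) / a
  } else {
    arg <- 1 - k * (x - xi) / a
    y <- ifelse(arg > 0, -log(arg) / k,
                ifelse(k < 0, -Inf, Inf)) # beyond the finite support bound
  }
  pmin(pmax(1 / (1 + exp(-y)), 1e-6), 1 - 1e-6)
}

#' Multiscalar SPEI at a target month
#'
#' For each year, the water balance is summed over the `scale` months ending
#' at `month`; a three-parameter log-logistic distribution is fitted to the
#' calibration-period sums by unbiased probability-weighted moments and each
#' sum is mapped to `qnorm(F(D))`. Non-exceedance probabilities are clipped to
#' `[1e-6, 1 - 1e-6]`.
#'
#' @param wb A data frame with columns `year`, `month`, `wb` (from
#'   [water_balance()]).
#' @param scale Aggregation scale in months (k-month sum ending at `month`).
#' @param month Target calendar month.
#' @param calibration Optional `c(first, last)` year range used to fit the
#'   distribution; defaults to all years with a complete window. At least 30
#'   calibration years are required.
#' @return A data frame `year`, `spei`, with attributes `month`, `scale`,
#'   `calibration`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' cl <- water_balance(gen_climate(cfg, "S1"))
#' s <- spei(cl, scale = 5, month = 7)
#' @export
spei <- function(wb, scale, month, calibration = NULL) {
  assert_number(scale, "scale", 1, 48)
  assert_number(month, "month", 1, 12)
  wb <- wb[order(wb$year, wb$month), ]
  # index of the target month in each year and the k-month window ending there
  idx <- which(wb$month == month)
  d <- vapply(idx, function(i) {
    if (i < scale) return(NA_real_)
    sum(wb$wb[(i - scale + 1):i])
  }, numeric(1))
  yrs <- wb$year[idx]
  ok <- !is.na(d)
  cal_years <- yrs[ok]
  if (!is.null(calibration))
    cal_years <- cal_years[cal_years >= calibration[1] & cal_years <= calibration[2]]
  if (length(cal_years) < 30)
    stopf("only %d complete calibration years (need >= 30)", length(cal_years))
  par <- fit_loglogistic(d[ok][yrs[ok] %in% cal_years])
  z <- rep(NA_real_, length(d))
  z[ok] <- qnorm(ploglogistic(d[ok], par))
  out <- data.frame(year = yrs, spei = z)
  attr(out, "month") <- month
  attr(out, "scale") <- scale
  attr(out, "calibration") <- range(cal_years)
  attr(out, "par") <- par
  out
}

#' Select the growth-relevant SPEI window
#'
#' Correlates SPEI series at every (target month, scale) combination with a
#' ring-width chronology over their common years and returns the window with
#' the highest Pearson correlation, together with the full correlation grid.
#'
#' @param wb Water-balance data frame (see [spei()]).
#' @param chronology Data frame `year`, `index` (see [build_chronology()]).
#' @param months,scales Candidate target months and scales.
#' @return A list with `month`, `scale`, `correlation`, the full `grid`
#'   (month x scale matrix of correlations) and `stable` (`FALSE` when the
#'   two best grid cells differ by < 0.02).
#' @export
select_spei_window <- function(wb, chronology, months = 1:12, scales = 1:12) {
  grid <- matrix(NA_real_, length(months), length(scales),
                 dimnames = list(month = months, scale = scales))
  for (i in seq_along(months)) {
    for (j in seq_along(scales)) {
      s <- spei(wb, scale = scales[j], month = months[i])
      m <- merge(s, chronology, by = "year")
      m <- m[complete.cases(m[c("spei", "index")]), ]
      if (nrow(m) < 10)
        stopf("only %d common years between SPEI and chronology (need >= 10)",
              nrow(m))
      grid[i, j] <- cor(m$spei, m$index)
    }
  }
  best <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  srt <- sort(grid, decreasing = TRUE)
  list(month = months[best[1]], scale = scales[best[2]],
       correlation = max(grid), grid = grid,
       stable = (srt[1] - srt[2]) >= 0.02)
}

#' Identify and classify drought events
#'
#' Averages SPEI across sites per year and selects event years either by
#' fixed thresholds or by ranking within sub-periods (the minima of each
#' period). Events are classified as mild (`threshold_severe < SPEI <=
#' threshold_mild`) or severe (`SPEI <= threshold_severe`).
#'
#' @param spei_list A single SPEI data frame or a list of them (one per site).
#' @param mode `"threshold"` selects every year below the mild threshold;
#'   `"rank"` selects the `n_per_period` lowest years within each period.
#' @param periods For `mode = "rank"`: list of `c(first, last)` year ranges.
#' @param n_per_period Events to pick per period in rank mode.
#' @param threshold_mild,threshold_severe Classification cut-offs (defaults
#'   -0.5 and -1.5).
#' @return Data frame `year`, `spei` (cross-site mean), `class`; zero rows
#'   (with a message) when no year falls below the mild threshold.
#' @export
identify_drought_events <- function(spei_list, mode = c("threshold", "rank"),
                                    periods = NULL, n_per_period = 2,
                                    threshold_mild = -0.5,
                                    threshold_severe = -1.5) {
  mode <- match.arg(mode)
  if (is.data.frame(spei_list)) spei_list <- list(spei_list)
  all <- do.call(rbind, lapply(spei_list, function(s) s[c("year", "spei")]))
  mu <- aggregate(spei ~ year, all, mean)
  classify <- function(v)
    ifelse(v <= threshold_severe, "severe",
           ifelse(v <= threshold_mild, "mild", "none"))
  if (mode == "threshold") {
    ev <- mu[classify(mu$spei) != "none", ]
  } else {
    if (is.null(periods)) stopf("rank mode requires 'periods'")
    picks <- lapply(periods, function(p) {
      sub <- mu[mu$year >= p[1] & mu$year <= p[2], ]
      head(sub[order(sub$spei), ], n_per_period)
    })
    ev <- do.call(rbind, picks)
    ev <- ev[classify(ev$spei) != "none", ]
  }
  if (nrow(ev) == 0) {
    message("no drought year below the mild threshold ", threshold_mild)
    return(data.frame(year = integer(), spei = numeric(), class = character()))
  }
  ev$class <- classify(ev$spei)
  ev <- ev[order(ev$year), ]
  rownames(ev) <- NULL
  ev
}
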