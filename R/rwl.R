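# Tucson (decadal) ring-width files.
#
# A collection of ring-width series is held the way dendro packages hold it:
# a data.frame with calendar years as rownames and one column per measurement
# series (mm), NA outside a series' span. The stop marker encodes precision:
# 999 for 0.01 mm files, -9999 for 0.001 mm files.

#' Read a Tucson ring-width file
#'
#' @param path Path to an RWL file in decadal format.
#' @return Data frame of ring widths in mm, years as rownames, one column per
#'   series id. The per-series precision (mm) is stored in attribute `prec`.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list() # id -> list(first_year, tokens)
  order_ids <- character()
  expect_year <- list()
  for (ln in seq_along(lines)) {
    # fixed-width series id in columns 1-8, then year, then up to 10 values
    id <- trimws(substr(lines[ln], 1, 8))
    tok <- strsplit(trimws(substring(lines[ln], 9)), "[[:space:]]+")[[1]]
    if (!nzchar(id) || length(tok) < 2)
      stopf("line %d: malformed Tucson record", ln)
    yr <- suppressWarnings(as.integer(tok[1]))
    if (is.na(yr)) stopf("line %d: unreadable decade year '%s'", ln, tok[1])
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals)) stopf("line %d: unreadable value", ln)
    if (is.null(recs[[id]])) {
      if (id %in% order_ids)
        stopf("line %d: duplicate series id '%s'", ln, id)
      recs[[id]] <- list(first = yr, vals = numeric())
      order_ids <- c(order_ids, id)
      expect_year[[id]] <- yr
    } else if (yr != expect_year[[id]]) {
      prev <- recs[[id]]$vals
      if (length(prev) && prev[length(prev)] %in% c(999, -9999))
        stopf("line %d: duplicate series id '%s'", ln, id)
      stopf("line %d: series '%s' year gap (expected %d, found %d)",
            ln, id, expect_year[[id]], yr)
    }
    recs[[id]]$vals <- c(recs[[id]]$vals, vals)
    expect_year[[id]] <- yr + length(vals)
  }
  series <- list()
  prec <- numeric()
  for (id in order_ids) {
    v <- recs[[id]]$vals
    marker <- v[length(v)]
    if (marker == 999) {
      p <- 0.01
    } else if (marker == -9999) {
      p <- 0.001
    } else {
      stopf("series '%s': missing stop marker (999 or -9999)", id)
    }
    v <- v[-length(v)]
    if (any(v < 0)) stopf("series '%s': negative ring width", id)
    series[[id]] <- list(first = recs[[id]]$first, w = v * p)
    prec[id] <- p
  }
  yr_min <- min(vapply(series, `[[`, 0, "first"))
  yr_max <- max(vapply(series, function(s) s$first + length(s$w) - 1L, 0))
  years <- yr_min:yr_max
  out <- as.data.frame(matrix(NA_real_, length(years), length(series),
                              dimnames = list(years, names(series))),
                       check.names = FALSE)
  for (id in names(series)) {
    s <- series[[id]]
    out[as.character(seq(s$first, length.out = length(s$w))), id] <- s$w
  }
  attr(out, "prec") <- prec
  out
}

#' Write ring-width series to a Tucson file
#'
#' @param rwl Data frame of ring widths in mm (years as rownames, one column
#'   per series).
#' @param path Output path.
#' @param prec Measurement precision in mm, `0.01` (stop marker 999) or
#'   `0.001` (stop marker -9999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path, prec = 0.01) {
  if (!prec %in% c(0.01, 0.001)) stopf("prec must be 0.01 or 0.001")
  if (any(nchar(colnames(rwl)) > 8))
    stopf("series ids longer than 8 characters do not fit the Tucson id field")
  if (anyDuplicated(colnames(rwl)))
    stopf("duplicate series ids")
  marker <- if (prec == 0.01) 999 else -9999
  years <- as.integer(rownames(rwl))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in colnames(rwl)) {
    w <- rwl[[id]]
    ok <- which(!is.na(w))
    if (!length(ok)) next
    if (any(diff(ok) != 1L))
      stopf("series '%s' has internal gaps; Tucson format requires contiguous years", id)
    yrs <- years[ok]
    vals <- c(round(w[ok] / prec), marker)
    vyrs <- c(yrs, max(yrs) + 1L)
    pad_id <- formatC(id, width = -8)
    i <- 1L
    while (i <= length(vals)) {
      y <- vyrs[i]
      n_in_row <- min(10L - (y %% 10L), length(vals) - i + 1L)
      row <- vals[i:(i + n_in_row - 1L)]
      writeLines(paste0(pad_id, formatC(y, width = 4),
                        paste(formatC(row, width = 6), collapse = "")), con)
      i <- i + n_in_row
    }
  }
  invisible(path)
}
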