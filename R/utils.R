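# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

# deterministic per-stream seed derived from a master seed and a label,
# kept within the 32-bit integer range
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  as.integer((as.numeric(seed) * 69069 + h * 7919) %% 2147483647)
}

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  ifelse(month == 2 & leap, 29L, d)
}
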