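# Drought-response model protocol: predictor standardization and screening,
# tree-level mixed models / stand-level linear models, all-subsets AICc
# selection, Nakagawa R-squared and variance-component effect sizes.
#
# Models used for selection are fitted by maximum likelihood (not REML)
# because AICc is compared across different fixed-effect sets.

#' Scale and center predictor columns
#'
#' @param data Data frame.
#' @param cols Columns to standardize; defaults to all numeric columns.
#' @return `data` with the chosen columns transformed to mean 0, SD 1, and a
#'   `scaling` attribute (`col`, `mean`, `sd`) for back-transformation.
#' @export
standardize <- function(data, cols = NULL) {
  if (is.null(cols))
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  rec <- data.frame(col = cols, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(cols)) {
    x <- data[[cols[i]]]
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stopf("column '%s' is constant: cannot standardize", cols[i])
    rec$mean[i] <- mean(x); rec$sd[i] <- s
    data[[cols[i]]] <- (x - rec$mean[i]) / s
  }
  attr(data, "scaling") <- rec
  data
}

#' Undo [standardize()]
#'
#' @param data A data frame produced by [standardize()] (or carrying its
#'   `scaling` attribute).
#' @param scaling Scaling record; defaults to `attr(data, "scaling")`.
#' @return Data frame on the original scale.
#' @export
unstandardize <- function(data, scaling = attr(data, "scaling")) {
  if (is.null(scaling)) stopf("no scaling record found")
  for (i in seq_len(nrow(scaling)))
    data[[scaling$col[i]]] <-
      data[[scaling$col[i]]] * scaling$sd[i] + scaling$mean[i]
  attr(data, "scaling") <- NULL
  data
}

#' Pairwise-correlation prefilter
#'
#' Among every pair of predictors with `|r| >= threshold`, drops the member
#' with the smaller absolute correlation to the response, iterating until no
#' pair violates the threshold.
#'
#' @param data Data frame holding predictors and response.
#' @param cols Predictor column names (numeric).
#' @param response Response column name.
#' @param threshold Correlation threshold (default 0.5).
#' @return Retained column names.
#' @export
correlation_prefilter <- function(data, cols, response, threshold = 0.5) {
  keep <- cols
  repeat {
    if (length(keep) < 2) break
    cm <- abs(cor(data[keep]))
    diag(cm) <- 0
    if (max(cm) < threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    ry <- abs(vapply(pair, function(p) cor(data[[p]], data[[response]]),
                     numeric(1)))
    keep <- setdiff(keep, pair[which.min(ry)])
  }
  keep
}

#' Variance-inflation-factor filter
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor j on the others;
#' iteratively drops the predictor with the largest VIF while any VIF exceeds
#' the threshold.
#'
#' @inheritParams correlation_prefilter
#' @param threshold VIF threshold (default 2).
#' @return Retained column names, with the final VIFs as attribute `vif`.
#' @export
vif_filter <- function(data, cols, threshold = 2) {
  keep <- cols
  vifs <- function(cs) vapply(cs, function(j) {
    r2 <- summary(lm(as.formula(paste0("`", j, "` ~ .")),
                     data[cs]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
  repeat {
    if (length(keep) < 2) break
    v <- vifs(keep)
    if (max(v) <= threshold) break
    keep <- setdiff(keep, keep[which.max(v)])
  }
  structure(keep, vif = if (length(keep) >= 2) vifs(keep) else
    setNames(rep(1, length(keep)), keep))
}

aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one drought-response model
#'
#' Tree-level models are linear mixed-effects models with a random intercept
#' for the grouping factor, fitted by maximum likelihood; stand-level models
#' (no `group`) are ordinary least squares. When the grouping factor is
#' degenerate (fewer than two groups with two or more observations) the model
#' falls back to fixed effects only, with a message.
#'
#' @param data Model frame (predictors already standardized).
#' @param response Response column name.
#' @param terms Character vector of fixed-effect terms (may include
#'   interactions as `"a:b"`); empty for an intercept-only model.
#' @param group Optional grouping column for a random intercept.
#' @param reml Refit by REML (only for reporting a selected model).
#' @return An object of class `standres_fit`: coefficient table, variance
#'   components, log-likelihood, AICc, `r2m`/`r2c` (mixed) or `r2adj`
#'   (linear), effect sizes, convergence/singularity flags.
#' @export
fit_mixed <- function(data, response, terms = character(), group = NULL,
                      reml = FALSE) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  mixed <- !is.null(group)
  if (mixed) {
    tab <- table(data[[group]])
    if (sum(tab >= 2) < 2) {
      message("grouping '", group, "' degenerate; falling back to fixed-only")
      mixed <- FALSE
    }
  }
  if (mixed) {
    fml <- as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
    fit <- suppressMessages(lme4::lmer(fml, data = data, REML = reml))
    # a boundary (singular) fit is a valid ML estimate; only true optimizer
    # failures count as non-convergence
    msgs <- unlist(fit@optinfo$conv$lme4$messages)
    conv <- (fit@optinfo$conv$opt == 0) &&
      !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    singular <- lme4::isSingular(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    s2_rand <- sum(vc$vcov[vc$grp != "Residual"])
    s2_resid <- vc$vcov[vc$grp == "Residual"]
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    X <- model.matrix(fit)
  } else {
    fml <- as.formula(paste(response, "~", rhs))
    fit <- lm(fml, data = data)
    conv <- TRUE; singular <- FALSE
    s2_rand <- 0
    s2_resid <- sigma(fit)^2
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    X <- model.matrix(fit)
  }
  eta <- as.vector(X %*% beta)
  s2_fixed <- var(eta)
  denom <- s2_fixed + s2_rand + s2_resid
  # per-term variance of the partial fixed-effect predictor
  asg <- attr(X, "assign")
  labs <- attr(terms(fml), "term.labels")
  labs <- labs[!grepl("\\|", labs)]
  es <- vapply(seq_along(labs), function(t) {
    cols <- which(asg == t)
    var(as.vector(X[, cols, drop = FALSE] %*% beta[cols])) / denom
  }, numeric(1))
  names(es) <- labs
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  n <- nobs(fit)
  out <- list(model = fit, response = response, terms = terms,
              mixed = mixed, group = if (mixed) group else NULL,
              coefficients = data.frame(term = names(beta),
                                        estimate = unname(beta),
                                        se = unname(se)),
              sigma2_fixed = s2_fixed, sigma2_random = s2_rand,
              sigma2_resid = s2_resid,
              loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
              effect_sizes = es,
              converged = conv, singular = singular)
  if (mixed) {
    r2 <- r2_nakagawa(s2_fixed, s2_rand, s2_resid)
    out$r2m <- r2[["r2m"]]; out$r2c <- r2[["r2c"]]
  } else {
    out$r2m <- out$r2c <- s2_fixed / denom
    out$r2adj <- summary(fit)$adj.r.squared
  }
  class(out) <- "standres_fit"
  out
}

#' @export
print.standres_fit <- function(x, ...) {
  cat(if (x$mixed) "Linear mixed model" else "Linear model",
      sprintf("(ML): %s ~ %s\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("AICc %.2f | R2m %.3f R2c %.3f | n %d\n",
              x$aicc, x$r2m, x$r2c, x$n))
  invisible(x)
}

#' Nakagawa marginal and conditional R-squared
#'
#' `R2m = s2_fixed / (s2_fixed + s2_random + s2_resid)`;
#' `R2c = (s2_fixed + s2_random) / (same denominator)`, where `s2_fixed` is
#' the variance of the fixed-effect linear predictor.
#'
#' @param sigma2_fixed Either a `standres_fit` object or the fixed-effect
#'   predictor variance.
#' @param sigma2_random,sigma2_resid Random-intercept and residual variances
#'   (ignored when a fit object is given).
#' @return Named vector `r2m`, `r2c`.
#' @export
r2_nakagawa <- function(sigma2_fixed, sigma2_random = NULL,
                        sigma2_resid = NULL) {
  if (inherits(sigma2_fixed, "standres_fit")) {
    f <- sigma2_fixed
    sigma2_random <- f$sigma2_random; sigma2_resid <- f$sigma2_resid
    sigma2_fixed <- f$sigma2_fixed
  }
  denom <- sigma2_fixed + sigma2_random + sigma2_resid
  c(r2m = sigma2_fixed / denom,
    r2c = (sigma2_fixed + sigma2_random) / denom)
}

#' Per-predictor effect sizes of a fitted model
#'
#' The effect size of a term is the variance of its partial fixed-effect
#' predictor (for a single standardized column, `beta^2`) divided by the
#' total model variance (fixed + random + residual). Interaction terms are
#' reported under their own name. With mutually orthogonal centered
#' predictors the effect sizes sum to the marginal R-squared.
#'
#' @param fit A `standres_fit` object.
#' @return Named numeric vector of proportions.
#' @export
effect_sizes <- function(fit) fit$effect_sizes

subset_respects_hierarchy <- function(subset) {
  inter <- subset[grepl(":", subset)]
  all(vapply(inter, function(tm)
    all(strsplit(tm, ":")[[1]] %in% subset), logical(1)))
}

#' All-subsets AICc model selection
#'
#' Fits every combination of candidate fixed-effect terms that respects the
#' marginality principle (an interaction is only included together with its
#' main effects) and ranks them by AICc. Ties within 1e-8 go to the model
#' with fewer parameters. Subsets with `n - k - 1 <= 0` are skipped, and
#' non-converged fits are excluded from the ranking; both are logged.
#'
#' @inheritParams fit_mixed
#' @param terms Candidate terms (at most 12).
#' @return List: `best` (refitted `standres_fit`), `ranking` (data frame with
#'   formula, k, AICc, delta), `log` (character vector of skipped/excluded
#'   models).
#' @export
all_subsets_aicc <- function(data, response, terms, group = NULL) {
  if (length(terms) > 12) stopf("more than 12 candidate terms (%d)", length(terms))
  subsets <- list(character())
  for (tm in terms)
    subsets <- c(subsets, lapply(subsets, c, tm))
  subsets <- Filter(subset_respects_hierarchy, subsets)
  rows <- list(); fits <- list(); log <- character()
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    lab <- if (length(sub)) paste(sub, collapse = " + ") else "1"
    f <- tryCatch(fit_mixed(data, response, sub, group),
                  error = function(e) e)
    if (inherits(f, "error")) {
      log <- c(log, paste0(lab, ": error - ", conditionMessage(f)))
      next
    }
    if (is.na(f$aicc)) {
      log <- c(log, paste0(lab, ": skipped (n - k - 1 <= 0)"))
      next
    }
    if (!f$converged) {
      log <- c(log, paste0(lab, ": excluded (did not converge)"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(formula = lab, k = f$k,
                                            aicc = f$aicc)
    fits[[length(fits) + 1L]] <- f
  }
  if (!length(rows))
    stopf("no candidate model could be fitted:\n%s",
          paste(head(log, 5), collapse = "\n"))
  rk <- do.call(rbind, rows)
  o <- order(round(rk$aicc / 1e-8) * 1e-8, rk$k) # AICc ties -> fewer params
  rk <- rk[o, ]
  fits <- fits[o]
  rk$delta <- rk$aicc - rk$aicc[1]
  rownames(rk) <- NULL
  list(best = fits[[1]], ranking = rk, log = log)
}

#' Predictor screening pipeline
#'
#' Correlation prefilter followed by the VIF filter, as applied before the
#' all-subsets search.
#'
#' @inheritParams correlation_prefilter
#' @param r_threshold Pairwise-correlation threshold (default 0.5).
#' @param vif_threshold VIF threshold (default 2).
#' @return Retained predictor names.
#' @export
screen_predictors <- function(data, cols, response, r_threshold = 0.5,
                              vif_threshold = 2) {
  keep <- correlation_prefilter(data, cols, response, r_threshold)
  as.character(vif_filter(data, keep, vif_threshold))
}

#' Stand-level drought-response model
#'
#' Ordinary least squares with the same screening and AICc selection as the
#' tree-level protocol; reports the adjusted R-squared of the best model.
#'
#' @inheritParams screen_predictors
#' @param terms Candidate predictor columns (numeric).
#' @param screen Apply [screen_predictors()] first (default `TRUE`).
#' @return As [all_subsets_aicc()]; the best fit carries `r2adj`.
#' @export
fit_stand_models <- function(data, response, terms, screen = TRUE,
                             r_threshold = 0.5, vif_threshold = 2) {
  if (screen)
    terms <- screen_predictors(data, terms, response, r_threshold,
                               vif_threshold)
  all_subsets_aicc(data, response, terms, group = NULL)
}
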