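test_that("standardize centers, scales, records and round-trips", {
  set.seed(14)
  d <- data.frame(a = rnorm(30, 5, 2), b = runif(30), g = letters[1:3])
  s <- standardize(d, c("a", "b"))
  expect_equal(unname(colMeans(s[c("a", "b")])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(vapply(s[c("a", "b")], sd, 1)), c(1, 1),
               tolerance = 1e-12)
  back <- unstandardize(s)
  expect_equal(back$a, d$a, tolerance = 1e-12)
  expect_error(standardize(data.frame(a = rep(1, 5))), "constant")
})

test_that("correlation prefilter keeps the response-relevant member", {
  set.seed(15)
  n <- 200
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- d$x1 # identical twin
  d$x3 <- rnorm(n)
  d$y <- d$x1 + rnorm(n, 0, 0.5)
  kept <- correlation_prefilter(d, c("x1", "x2", "x3"), "y")
  expect_length(intersect(kept, c("x1", "x2")), 1)
  expect_true("x3" %in% kept)
  # orthogonal predictors all retained
  o <- as.data.frame(qr.Q(qr(matrix(rnorm(80), 20, 4))))
  o$y <- rnorm(20)
  expect_length(correlation_prefilter(o, paste0("V", 1:4), "y"), 4)
  # greedy oracle on <= 8 columns
  set.seed(16)
  m <- as.data.frame(matrix(rnorm(100 * 6), 100))
  m$V2 <- m$V1 * 0.9 + rnorm(100, 0, 0.2)
  m$V5 <- m$V4 * -0.95 + rnorm(100, 0, 0.1)
  m$y <- m$V1 - m$V4 + rnorm(100)
  oracle <- function(cols, thr = 0.5) {
    repeat {
      if (length(cols) < 2) return(cols)
      cm <- abs(cor(m[cols])); diag(cm) <- 0
      if (max(cm) < thr) return(cols)
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- cols[ij]
      drop <- pair[which.min(abs(sapply(pair, function(p)
        cor(m[[p]], m$y))))]
      cols <- setdiff(cols, drop)
    }
  }
  expect_setequal(correlation_prefilter(m, paste0("V", 1:6), "y"),
                  oracle(paste0("V", 1:6)))
})

test_that("VIF filtering matches the per-column regression definition", {
  set.seed(17)
  # columns orthogonal to each other AND to the intercept (centered)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(200), 50, 4))))[, 2:5]
  o <- as.data.frame(q)
  names(o) <- paste0("V", 1:4)
  kept <- vif_filter(o, paste0("V", 1:4))
  expect_setequal(as.character(kept), paste0("V", 1:4))
  expect_true(all(abs(attr(kept, "vif") - 1) < 1e-10))
  d <- data.frame(x1 = rnorm(100))
  d$x2 <- d$x1 + rnorm(100, 0, 0.01)
  d$x3 <- rnorm(100)
  kept2 <- vif_filter(d, c("x1", "x2", "x3"))
  expect_length(intersect(kept2, c("x1", "x2")), 1)
  # oracle: VIF_j = 1/(1 - R2_j)
  set.seed(18)
  e <- as.data.frame(matrix(rnorm(100 * 4), 100))
  e$V2 <- e$V1 * 0.5 + e$V2 * 0.5
  v <- attr(vif_filter(e, paste0("V", 1:4), threshold = 1e6), "vif")
  for (j in paste0("V", 1:4)) {
    r2 <- summary(lm(e[[j]] ~ ., e[setdiff(paste0("V", 1:4), j)]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-9)
  }
})

test_that("mixed fits collapse to OLS when between-group variance is zero", {
  set.seed(19)
  n <- 120
  d <- data.frame(x = rnorm(n), g = rep(letters[1:4], each = n / 4))
  d$y <- 1 + 0.5 * d$x + rnorm(n, 0, 0.3)
  # force exactly zero between-group variance in the residual structure
  r <- resid(lm(y ~ x, d))
  d$y <- d$y - ave(r, d$g)
  fm <- fit_mixed(d, "y", "x", group = "g")
  ols <- lm(y ~ x, d)
  expect_lt(max(abs(fm$coefficients$estimate - coef(ols))), 1e-6)
  expect_true(fm$singular || fm$sigma2_random < 1e-6)
  # degenerate grouping falls back to a fixed-only fit with the same result
  d1 <- d; d1$g <- c("a", rep("b", n - 1))
  expect_message(ff <- fit_mixed(d1, "y", "x", group = "g"), "degenerate")
  expect_false(ff$mixed)
  expect_equal(ff$coefficients$estimate, unname(coef(ols)), tolerance = 1e-9)
})

test_that("a constructed group shift appears as random-intercept variance", {
  set.seed(20)
  g <- rep(letters[1:10], each = 40)
  shift <- rnorm(10, 0, 2)
  d <- data.frame(g = g, y = shift[match(g, letters)] + rnorm(400, 0, 0.5))
  fm <- fit_mixed(d, "y", character(), group = "g")
  expect_equal(sqrt(fm$sigma2_random), 2, tolerance = 0.5)
  expect_equal(sqrt(fm$sigma2_resid), 0.5, tolerance = 0.1)
})

test_that("log-likelihood is non-decreasing in nested fixed effects", {
  set.seed(22)
  d <- data.frame(x = rnorm(100), z = rnorm(100),
                  g = rep(letters[1:5], each = 20))
  d$y <- 0.4 * d$x + rnorm(100)
  f1 <- fit_mixed(d, "y", "x", group = "g")
  f2 <- fit_mixed(d, "y", c("x", "z"), group = "g")
  expect_gte(f2$loglik, f1$loglik - 1e-8)
})

test_that("AICc applies the small-sample correction exactly", {
  expect_equal(standres:::aicc(-47, 3, 20), 100 + 2 * 3 * 4 / 16)
  expect_true(is.na(standres:::aicc(-47, 19, 20)))
})

test_that("all-subsets selection equals brute-force enumeration", {
  set.seed(23)
  n <- 80
  d <- data.frame(matrix(rnorm(n * 5), n))
  names(d) <- paste0("x", 1:5)
  d$y <- 1 + 0.8 * d$x1 - 0.6 * d$x2 + rnorm(n, 0, 0.5)
  sel <- all_subsets_aicc(d, "y", paste0("x", 1:5))
  # oracle: enumerate all 32 subsets with plain lm + the AICc formula
  oracle <- list()
  for (mask in 0:31) {
    sub <- paste0("x", 1:5)[bitwAnd(mask, 2^(0:4)) > 0]
    rhs <- if (length(sub)) paste(sub, collapse = "+") else "1"
    f <- lm(as.formula(paste("y ~", rhs)), d)
    k <- length(coef(f)) + 1
    oracle[[mask + 1]] <- data.frame(
      formula = if (length(sub)) paste(sub, collapse = " + ") else "1",
      aicc = AIC(f) + 2 * k * (k + 1) / (n - k - 1))
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle$aicc), ]
  expect_equal(sel$ranking$formula, oracle$formula)
  expect_equal(sel$ranking$aicc, oracle$aicc, tolerance = 1e-9)
  expect_true(all(c("x1", "x2") %in% sel$best$terms))
})

test_that("interactions require their main effects in every subset", {
  set.seed(24)
  d <- data.frame(a = rnorm(60), b = rnorm(60))
  d$y <- d$a * d$b + rnorm(60)
  sel <- all_subsets_aicc(d, "y", c("a", "b", "a:b"))
  has_int <- grepl("a:b", sel$ranking$formula)
  expect_true(all(grepl("\\ba\\b", sel$ranking$formula[has_int])))
  expect_true(all(grepl("\\bb\\b", sel$ranking$formula[has_int])))
  expect_equal(nrow(sel$ranking), 5) # 1, a, b, a+b, a+b+a:b
})

test_that("Nakagawa R-squared follows its variance-component formula", {
  r2 <- r2_nakagawa(2, 1, 1)
  expect_equal(unname(r2), c(0.5, 0.75))
  expect_equal(r2_nakagawa(3, 0, 1)[["r2m"]], r2_nakagawa(3, 0, 1)[["r2c"]])
  # hand-computed worked example: 3 groups with known components
  set.seed(25)
  g <- rep(c("a", "b", "c"), each = 100)
  x <- rnorm(300)
  y <- 2 * x + c(a = -1, b = 0, c = 1)[g] + rnorm(300, 0, 1)
  fm <- fit_mixed(data.frame(x = x, g = g, y = y), "y", "x", group = "g")
  hand <- fm$sigma2_fixed / (fm$sigma2_fixed + fm$sigma2_random +
                               fm$sigma2_resid)
  expect_equal(fm$r2m, hand, tolerance = 1e-12)
  expect_lte(fm$r2m, fm$r2c)
})

test_that("effect sizes decompose variance and ignore supply order", {
  set.seed(26)
  # centered, mutually orthogonal, unit-SD predictors
  qm <- qr.Q(qr(cbind(1, matrix(rnorm(300), 100, 3))))[, 2:4] * sqrt(99)
  o <- as.data.frame(qm)
  names(o) <- c("p", "q", "r")
  o$y <- 0.5 * o$p - 0.3 * o$q + rnorm(100, 0, 0.4)
  f <- fit_mixed(o, "y", c("p", "q", "r"))
  es <- effect_sizes(f)
  # beta^2 * Var(x) / total variance for standardized columns
  beta <- f$coefficients$estimate[match(c("p", "q", "r"),
                                        f$coefficients$term)]
  tot <- f$sigma2_fixed + f$sigma2_resid
  expect_equal(unname(es), beta^2 / tot, tolerance = 1e-9)
  # with mutually orthogonal predictors the effect sizes sum to R2m
  expect_equal(sum(es), f$r2m, tolerance = 1e-6)
  f2 <- fit_mixed(o, "y", c("r", "q", "p"))
  expect_equal(es[c("p", "q", "r")], effect_sizes(f2)[c("p", "q", "r")],
               tolerance = 1e-10)
})

test_that("stand-level linear models report adjusted R-squared", {
  d <- data.frame(x = 1:20)
  d$y <- 2 + 3 * d$x # exact line: "perfect fit" warning is expected
  f <- suppressWarnings(fit_mixed(d, "y", "x"))
  expect_equal(f$r2adj, 1)
  set.seed(27)
  d2 <- data.frame(x = rnorm(40), z = rnorm(40))
  d2$y <- 1 + 0.7 * d2$x + rnorm(40, 0, 0.5)
  sel <- fit_stand_models(d2, "y", c("x", "z"), screen = FALSE)
  xc <- cbind(1, d2$x)
  beta <- solve(t(xc) %*% xc, t(xc) %*% d2$y) # normal-equation oracle
  only_x <- fit_mixed(d2, "y", "x")
  expect_equal(only_x$coefficients$estimate, as.vector(beta),
               tolerance = 1e-9)
  f0 <- fit_mixed(d2, "y", character())
  expect_equal(f0$r2adj, 0, tolerance = 1e-12)
})
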