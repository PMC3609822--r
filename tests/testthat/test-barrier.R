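# Correlation, normality and GLM/AIC analyses of the pairwise table.

# 21-pair table over 7 sites whose geographic indices are only moderately
# correlated, with genetic distance driven purely by straight distance at a
# paper-scale effect (single-factor t around 5)
toy_pairwise <- function(seed = 1, b_straight = 8e-4, noise = 0.17) {
  set.seed(seed)
  pops <- default_populations()$name
  pairs <- utils::combn(pops, 2)
  m <- ncol(pairs)
  straight <- runif(m, 50, 950)
  crossings <- rpois(m, 1)
  detoured <- straight + rexp(m, 1 / 150) * (crossings > 0)
  data.frame(pop_a = pairs[1, ], pop_b = pairs[2, ],
             fst = b_straight * straight + rnorm(m, 0, noise),
             straight_km = straight, detoured_km = detoured,
             crossings = crossings, cohort_pair = "x",
             stringsAsFactors = FALSE)
}

test_that("Pearson correlation matches the closed-form sums", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  r <- pearson_correlation(x, y)
  n <- 5
  rr <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(r$r, rr, tolerance = 1e-12)
  expect_equal(r$t, rr * sqrt((n - 2) / (1 - rr^2)), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), n - 2), tolerance = 1e-12)

  lin <- pearson_correlation(x, 2 * x + 1)
  expect_equal(lin$r, 1)

  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "input_error")
  expect_error(pearson_correlation(1:2, 2:3), class = "input_error")
})

test_that("single-predictor GLM t equals the correlation t", {
  for (seed in c(2, 8, 15)) {
    pw <- toy_pairwise(seed = seed)
    fit <- fit_glm_gaussian(pw, "straight")
    r <- pearson_correlation(pw$straight_km, pw$fst)
    t_slope <- fit$coefficients$t[fit$coefficients$term == "straight_km"]
    expect_equal(t_slope, r$t, tolerance = 1e-9)
  }
})

test_that("site correlation profiles subset the right pairs", {
  pw <- toy_pairwise(seed = 3)
  pr <- site_correlation_profile(pw, "Wamba")
  expect_equal(nrow(pr), 3L)
  expect_true(all(pr$n == 6))
  pr5 <- site_correlation_profile(pw, "Wamba", exclude = "TL2")
  expect_true(all(pr5$n == 5))
  expect_error(site_correlation_profile(pw, "Wamba", exclude = "Wamba"),
               class = "input_error")
})

test_that("KS normality check equals the brute-force ECDF computation", {
  x <- c(0.1, 0.5, 0.2, 0.9, 0.4)
  ks <- ks_normality(x)
  xs <- sort(x); n <- length(x)
  z <- stats::pnorm(xs, mean(x), stats::sd(x))
  d_ora <- max(pmax(abs(seq_len(n) / n - z), abs(z - (seq_len(n) - 1) / n)))
  expect_equal(ks$D, d_ora, tolerance = 1e-12)

  # values on the fitted normal's own quantiles: tiny D, p near 1
  q <- stats::qnorm(stats::ppoints(40))
  ksq <- ks_normality(q)
  expect_lt(ksq$D, 0.05)
  expect_gt(ksq$p, 0.95)

  expect_error(ks_normality(rep(1, 10)), class = "input_error")
  expect_error(ks_normality(1:4), class = "input_error")
})

test_that("Gaussian GLM reproduces normal equations and the AIC convention", {
  pw <- toy_pairwise(seed = 4)[1:6, ]
  fit <- fit_glm_gaussian(pw, c("straight", "crossings"))
  X <- cbind(1, pw$straight_km, pw$crossings)
  beta <- solve(t(X) %*% X, t(X) %*% pw$fst)
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-9)
  rss <- sum((pw$fst - X %*% beta)^2)
  n <- 6; k <- 2
  aic_hand <- n * log(2 * pi * rss / n) + n + 2 * (k + 2)
  expect_equal(fit$aic, aic_hand, tolerance = 1e-9)
})

test_that("GLM flags collinearity and perfect fits behave", {
  pw <- toy_pairwise(seed = 5)
  pw$detoured_km <- 2 * pw$straight_km
  expect_error(fit_glm_gaussian(pw, c("straight", "detoured")),
               class = "collinearity_error")

  lin <- toy_pairwise(seed = 6, noise = 1e-9)
  fit <- fit_glm_gaussian(lin, "straight")
  co <- fit$coefficients[fit$coefficients$term == "straight_km", ]
  expect_lt(co$p, 1e-12)
  expect_equal(co$sign, "+")
  expect_equal(co$stars, "***")
})

test_that("AIC penalises a useless extra predictor", {
  pw <- toy_pairwise(seed = 7)
  # make crossings pure noise, orthogonal to the response signal
  set.seed(77)
  pw$crossings <- rnorm(nrow(pw))
  a1 <- fit_glm_gaussian(pw, "straight")$aic
  a2 <- fit_glm_gaussian(pw, c("straight", "crossings"))$aic
  rss1 <- sum(residuals(fit_glm_gaussian(pw, "straight")$fit)^2)
  rss2 <- sum(residuals(fit_glm_gaussian(pw, c("straight", "crossings"))$fit)^2)
  n <- nrow(pw)
  expect_equal(a2 - a1, n * log(rss2 / rss1) + 2, tolerance = 1e-9)
})

test_that("statistics are invariant under row reordering", {
  pw <- toy_pairwise(seed = 9)
  shuf <- pw[sample(nrow(pw)), ]
  expect_equal(fit_glm_gaussian(pw, "detoured")$aic,
               fit_glm_gaussian(shuf, "detoured")$aic, tolerance = 1e-12)
  expect_equal(site_correlation_profile(pw, "Malebo")$r,
               site_correlation_profile(shuf, "Malebo")$r, tolerance = 1e-12)
  expect_equal(ks_normality(pw$fst)$D, ks_normality(shuf$fst)$D)
})

test_that("model comparison ranks models and honours exclusions", {
  pw <- toy_pairwise(seed = 10)
  mc <- model_comparison(pw)
  expect_setequal(mc$ranking$model,
                  c("straight", "detoured", "crossings", "straight+crossings"))
  expect_equal(mc$n_pairs, 21)
  expect_equal(unique(mc$ranking$n), 21)
  mc15 <- model_comparison(pw, exclude = "TL2")
  expect_equal(mc15$n_pairs, 15)
  expect_true(all(diff(mc$ranking$aic) >= 0))
})

test_that("model selection recovers a pure straight-distance effect", {
  # effect size scaled to a single-factor t of about 5 on 21 pairs; the
  # winner is judged among the three single-factor fits (the two-factor
  # model beats its own single factor by chance with chi-square probability
  # ~0.16, so including it caps any exact-winner rate near 84%)
  wins <- sum(vapply(1:100, function(s) {
    mc <- model_comparison(toy_pairwise(seed = s))
    rk <- mc$ranking[mc$ranking$model %in%
                       c("straight", "detoured", "crossings"), ]
    rk$model[which.min(rk$aic)] == "straight"
  }, logical(1)))
  expect_gte(wins, 80)
})

test_that("the Mantel extension agrees in sign with Pearson", {
  pops <- default_populations()
  sites <- data.frame(population = pops$name, latitude = pops$latitude,
                      longitude = pops$longitude)
  geo <- geo_index_table(sites, river_map())
  k <- nrow(sites)
  gmat <- matrix(0, k, k, dimnames = list(sites$population, sites$population))
  for (i in seq_len(nrow(geo))) {
    gmat[geo$pop_a[i], geo$pop_b[i]] <- gmat[geo$pop_b[i], geo$pop_a[i]] <-
      geo$straight_km[i]
  }
  set.seed(12)
  fmat <- gmat / max(gmat) + matrix(rnorm(k * k, 0, 0.05), k, k)
  fmat <- (fmat + t(fmat)) / 2; diag(fmat) <- 0
  mt <- mantel_test(fmat, gmat, n_perm = 199, seed = 3)
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)
})
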