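# Statistical comparison of genetic and geographic distance: Pearson
# correlations per site, normality check on the pairwise genetic distances,
# and Gaussian-GLM/AIC model selection over the geographic indices.
#
# Pairwise rows of a distance table are not independent observations; the
# analyses here deliberately follow the plain Pearson/GLM treatment of such
# tables, and a Mantel permutation test is offered as a clearly separate
# extension.

#' Assemble the pairwise geographic/genetic table
#'
#' One row per unordered population pair combining the genetic distance
#' (Phi-ST) with the three geographic indices, tagged by cohort pair when a
#' cohort map is given.
#'
#' @param fst an `"fst_result"` (or plain symmetric Phi-ST matrix).
#' @param geo data.frame from [geo_index_table()].
#' @param cohorts optional named vector population -> cohort label.
#' @return data.frame: pop_a, pop_b, fst, straight_km, detoured_km,
#'   crossings, cohort_pair.
#' @export
make_pairwise_table <- function(fst, geo, cohorts = NULL) {
  m <- if (inherits(fst, "fst_result")) unclass(fst$fst) else unclass(fst)
  out <- geo
  out$fst <- mapply(function(a, b) m[a, b], geo$pop_a, geo$pop_b)
  out$cohort_pair <- if (is.null(cohorts)) NA_character_ else {
    mapply(function(a, b) paste(sort(c(cohorts[[a]], cohorts[[b]])),
                                collapse = "-"),
           geo$pop_a, geo$pop_b)
  }
  out[, c("pop_a", "pop_b", "fst", "straight_km", "detoured_km",
          "crossings", "cohort_pair")]
}

#' Pearson correlation with t test
#'
#' @param x,y numeric vectors (`n >= 3`, both with nonzero variance).
#' @return list: r, t, p (two-sided, df = n - 2), n.
#' @export
pearson_correlation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs", "input_error")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero variance in x or y", "input_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = ct$p.value, n = n)
}

#' Correlations of genetic with geographic distance from one site
#'
#' Over the rows of the pairwise table involving `site` (optionally dropping
#' pairs with `exclude`), correlates Phi-ST with each of the three
#' geographic indices.
#'
#' @param table pairwise table from [make_pairwise_table()].
#' @param site population label.
#' @param exclude optional population to remove from the comparisons (must
#'   differ from `site`).
#' @return data.frame: index, r, t, p, n.
#' @export
site_correlation_profile <- function(table, site, exclude = NULL) {
  if (!is.null(exclude) && identical(exclude, site)) {
    abort("cannot exclude the focal site itself", "input_error")
  }
  rows <- table[table$pop_a == site | table$pop_b == site, , drop = FALSE]
  if (!is.null(exclude)) {
    rows <- rows[rows$pop_a != exclude & rows$pop_b != exclude, , drop = FALSE]
  }
  if (nrow(rows) < 3L) abort("too few pairs for correlation", "input_error")
  idx <- c(straight = "straight_km", detoured = "detoured_km",
           crossings = "crossings")
  out <- lapply(names(idx), function(nm) {
    r <- pearson_correlation(rows[[idx[[nm]]]], rows$fst)
    data.frame(index = nm, r = r$r, t = r$t, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the values against a normal distribution with plug-in sample mean
#' and sd, using the asymptotic KS p-value (no Lilliefors correction; the
#' Lilliefors variant is available via `lilliefors = TRUE` when the
#' `nortest` package is installed).
#'
#' @param values numeric vector, `n >= 5`, non-constant.
#' @param lilliefors use the Lilliefors estimated-parameter correction.
#' @return list: D, p, n.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) abort("need n >= 5", "input_error")
  if (stats::sd(values) == 0) abort("constant input", "input_error")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      abort("nortest package required for lilliefors = TRUE", "input_error")
    }
    kt <- nortest::lillie.test(values)
    return(list(D = unname(kt$statistic), p = kt$p.value, n = length(values)))
  }
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values),
                                        stats::sd(values), exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(values))
}

format_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Gaussian GLM of genetic distance on geographic predictors
#'
#' Ordinary least squares via a Gaussian identity-link GLM. The AIC follows
#' the full Gaussian log-likelihood convention (constants included, variance
#' counted as a parameter): `AIC = n log(2 pi RSS / n) + n + 2 (k + 2)` for
#' `k` predictors, which can be negative for well-fitting models on a
#' response of small magnitude.
#'
#' @param table pairwise table from [make_pairwise_table()].
#' @param predictors subset of `c("straight", "detoured", "crossings")`.
#' @return list of class `"glm_fit"`: coefficients data.frame (term,
#'   estimate, t, p, sign, stars), aic, n, predictors, and the underlying
#'   `glm` object as `fit`.
#' @export
fit_glm_gaussian <- function(table, predictors) {
  cols <- c(straight = "straight_km", detoured = "detoured_km",
            crossings = "crossings")
  predictors <- match.arg(predictors, names(cols), several.ok = TRUE)
  dat <- table[stats::complete.cases(table[, c("fst", cols[predictors])]), ]
  n <- nrow(dat)
  if (n <= length(predictors) + 1L) {
    abort("not enough complete rows for the requested model", "input_error")
  }
  X <- as.matrix(dat[, cols[predictors], drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    kappa_val <- kappa(cbind(1, scale(X)))
    abort(sprintf("collinear predictors (condition number %.3g)", kappa_val),
          "collinearity_error")
  }
  form <- stats::as.formula(paste("fst ~", paste(cols[predictors], collapse = " + ")))
  fit <- stats::glm(form, data = dat, family = stats::gaussian())
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1L],
    t = sm[, 3L],
    p = sm[, 4L],
    sign = ifelse(sm[, 1L] >= 0, "+", "-"),
    stars = format_stars(sm[, 4L]),
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, aic = stats::AIC(fit), n = n,
                 predictors = predictors, fit = fit), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Gaussian GLM (%s): AIC = %.2f, n = %d\n",
              paste(x$predictors, collapse = " + "), x$aic, x$n))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Compare single- and two-factor geographic models by AIC
#'
#' Fits the three single-factor Gaussian GLMs (straight, detoured,
#' crossings) and the straight + crossings two-factor model, optionally
#' after excluding every pair involving one population, and ranks them by
#' AIC.
#'
#' @param table pairwise table from [make_pairwise_table()].
#' @param exclude optional population label to drop from all pairs.
#' @return list: `fits` (named list of `"glm_fit"`), `ranking` data.frame
#'   (model, aic, n) sorted by AIC, `n_pairs`.
#' @export
model_comparison <- function(table, exclude = NULL) {
  if (!is.null(exclude)) {
    table <- table[table$pop_a != exclude & table$pop_b != exclude, ,
                   drop = FALSE]
  }
  specs <- list(straight = "straight",
                detoured = "detoured",
                crossings = "crossings",
                `straight+crossings` = c("straight", "crossings"))
  fits <- lapply(specs, function(p) fit_glm_gaussian(table, p))
  ranking <- data.frame(
    model = names(fits),
    aic = vapply(fits, function(f) f$aic, numeric(1L)),
    n = vapply(fits, function(f) f$n, numeric(1L)),
    stringsAsFactors = FALSE
  )
  ranking <- ranking[order(ranking$aic), ]
  rownames(ranking) <- NULL
  list(fits = fits, ranking = ranking, n_pairs = nrow(table))
}

#' Mantel permutation test (extension)
#'
#' Matrix-permutation alternative to the plain Pearson treatment of pairwise
#' tables, provided as a labelled extension; wraps [vegan::mantel()].
#'
#' @param gen symmetric genetic distance matrix.
#' @param geo symmetric geographic distance matrix (same labels).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: r, p, n_perm.
#' @export
mantel_test <- function(gen, geo, n_perm = 999L, seed = 1L) {
  gen <- unclass(gen); geo <- unclass(geo)
  geo <- geo[rownames(gen), rownames(gen)]
  set.seed(split_seed(seed, "mantel"))
  mt <- vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                      permutations = n_perm)
  list(r = unname(mt$statistic), p = mt$signif, n_perm = n_perm)
}
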