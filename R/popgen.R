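# Within-population diversity, pairwise Phi-ST with permutation tests,
# AMOVA variance partitioning and net population distances.
#
# Molecular-distance conventions follow the classical AMOVA framework: the
# matrix of inter-haplotype difference counts plays the role of squared
# Euclidean distances between individuals.

# individual-level "squared" distance matrix and population labels expanded
# from a haplotype table
expand_individuals <- function(table, d, pops = colnames(table$counts)) {
  hap_idx <- integer(0)
  pop_lab <- character(0)
  for (p in pops) {
    c_p <- table$counts[, p]
    hap_idx <- c(hap_idx, rep(seq_along(c_p), c_p))
    pop_lab <- c(pop_lab, rep(p, sum(c_p)))
  }
  M <- unclass(d)[table$haplotype_id, table$haplotype_id][hap_idx, hap_idx]
  list(M = M, pop = pop_lab)
}

# sum of within-group squared distances divided by group size, over groups;
# the AMOVA within-stratum sum of squared deviations
ssd_within <- function(M, grp) {
  out <- 0
  for (g in unique(grp)) {
    i <- which(grp == g)
    out <- out + sum(M[i, i]) / (2 * length(i))
  }
  out
}

amova_components <- function(M, grp) {
  N <- length(grp)
  sizes <- table(grp)
  G <- length(sizes)
  ssd_t <- sum(M) / (2 * N)
  ssd_w <- ssd_within(M, grp)
  ssd_a <- ssd_t - ssd_w
  df_a <- G - 1L
  df_w <- N - G
  sigma_w <- ssd_w / df_w
  n_prime <- (N - sum(sizes^2) / N) / df_a
  sigma_a <- (ssd_a / df_a - sigma_w) / n_prime
  phi <- sigma_a / (sigma_a + sigma_w)
  list(ssd_a = ssd_a, ssd_w = ssd_w, df_a = df_a, df_w = df_w,
       sigma_a = sigma_a, sigma_w = sigma_w, phi = phi)
}

#' Analysis of molecular variance (one grouping level)
#'
#' Partitions the total sum of squared inter-individual molecular distances
#' into among- and within-stratum components (method-of-moments variance
#' components with unequal sample sizes) and reports the Phi statistic with
#' an optional permutation test shuffling individuals among strata.
#'
#' @param table a `"hap_table"`.
#' @param d haplotype `"dist_matrix"` whose entries act as squared distances
#'   (difference counts, in the standard molecular-data convention).
#' @param strata named vector mapping each population to a stratum label;
#'   defaults to one stratum per population.
#' @param n_perm number of permutations for the Phi test (0 to skip).
#' @param seed RNG seed for the permutation test.
#' @return an object of class `"amova_result"`: data.frame `table`
#'   (stratum, df, SSD, sigma2, percent), `phi`, and `p` (permutation).
#' @export
amova <- function(table, d, strata = NULL, n_perm = 0L, seed = 1L) {
  pops <- colnames(table$counts)
  if (is.null(strata)) strata <- stats::setNames(pops, pops)
  if (!all(pops %in% names(strata))) {
    abort("every population needs a stratum label", "input_error")
  }
  ex <- expand_individuals(table, d)
  grp <- unname(strata[ex$pop])
  if (length(unique(grp)) < 2L) abort("need at least two strata", "input_error")
  comp <- amova_components(ex$M, grp)
  pct_a <- 100 * comp$sigma_a / (comp$sigma_a + comp$sigma_w)
  tab <- data.frame(
    stratum = c("among", "within", "total"),
    df = c(comp$df_a, comp$df_w, comp$df_a + comp$df_w),
    SSD = c(comp$ssd_a, comp$ssd_w, comp$ssd_a + comp$ssd_w),
    sigma2 = c(comp$sigma_a, comp$sigma_w, comp$sigma_a + comp$sigma_w),
    percent = c(pct_a, 100 - pct_a, 100),
    stringsAsFactors = FALSE
  )
  p <- NA_real_
  if (n_perm > 0L) {
    set.seed(split_seed(seed, "amova_perm"))
    ge <- vapply(seq_len(n_perm), function(i) {
      amova_components(ex$M, sample(grp))$phi >= comp$phi
    }, logical(1L))
    p <- (sum(ge) + 1) / (n_perm + 1)
  }
  structure(list(table = tab, phi = comp$phi, p = p), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi = %.4f, among-stratum variation %.2f%%",
              x$phi, x$table$percent[1L]))
  if (!is.na(x$p)) cat(sprintf(" (permutation p = %.4g)", x$p))
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pairwise population Phi-ST with permutation tests
#'
#' For every unordered population pair, the distance-based Phi statistic of a
#' two-group AMOVA on inter-haplotype distances (frequency-weighted by sample
#' counts). The permutation test shuffles individuals between the two
#' populations of the pair only, and reports
#' `p = (#{Phi_perm >= Phi_obs} + 1) / (n_perm + 1)`. Negative estimates are
#' retained as-is.
#'
#' @param table a `"hap_table"` (all populations with `n >= 2`).
#' @param d haplotype `"dist_matrix"` (difference counts).
#' @param n_perm permutations per pair.
#' @param seed RNG seed.
#' @return list of class `"fst_result"`: `fst` (symmetric matrix, zero
#'   diagonal) and `p` (permutation p-value matrix, `NA` diagonal).
#' @export
pairwise_fst <- function(table, d, n_perm = 1023L, seed = 1L) {
  pops <- colnames(table$counts)
  sizes <- colSums(table$counts)
  if (any(sizes < 2L)) {
    abort(sprintf("population(s) with fewer than 2 samples: %s",
                  paste(pops[sizes < 2L], collapse = ", ")), "input_error")
  }
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      ex <- expand_individuals(table, d, pops = c(pops[i], pops[j]))
      obs <- amova_components(ex$M, ex$pop)$phi
      fst[i, j] <- fst[j, i] <- obs
      if (n_perm > 0L) {
        set.seed(split_seed(seed, paste("fst", pops[i], pops[j])))
        ge <- vapply(seq_len(n_perm), function(r) {
          amova_components(ex$M, sample(ex$pop))$phi >= obs
        }, logical(1L))
        pmat[i, j] <- pmat[j, i] <- (sum(ge) + 1) / (n_perm + 1)
      }
    }
  }
  structure(list(fst = new_dist_matrix(fst, "fst", pops), p = pmat),
            class = "fst_result")
}

#' Within-population diversity estimates
#'
#' Haplotype (gene) diversity `h = n/(n-1) (1 - sum p_i^2)` with Nei's (1987)
#' sampling variance; mean number of pairwise differences `Pi` (over sample
#' pairs) with the Tajima (1983) total variance; nucleotide diversity
#' `pi = Pi / L` with the corresponding per-site variance (Nei 1987, eq.
#' 10.7). Variance estimators differ among legacy software implementations;
#' the forms used here are stated in the formulas above.
#'
#' @param table a `"hap_table"`.
#' @param pop population label.
#' @param d haplotype `"dist_matrix"` (difference counts).
#' @param L alignment length in sites.
#' @return a one-row data.frame: population, n, k (haplotypes), h, h_sd,
#'   mean_pairwise (Pi), mean_pairwise_sd, pi, pi_sd.
#' @export
diversity <- function(table, pop, d, L) {
  counts <- table$counts[, pop]
  n <- sum(counts)
  if (n < 2L) abort(sprintf("population '%s' has n < 2", pop), "insufficient_data")
  p <- counts / n
  sp2 <- sum(p^2)
  h <- n / (n - 1) * (1 - sp2)
  vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - sp2^2) + sp2 - sp2^2)
  m <- unclass(d)[table$haplotype_id, table$haplotype_id]
  Pi <- as.numeric(counts %*% m %*% counts) / (n * (n - 1))
  v_Pi <- (n + 1) / (3 * (n - 1)) * Pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * Pi^2
  pi <- Pi / L
  v_pi <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  data.frame(population = pop, n = n, k = sum(counts > 0),
             h = h, h_sd = sqrt(max(vh, 0)),
             mean_pairwise = Pi, mean_pairwise_sd = sqrt(v_Pi),
             pi = pi, pi_sd = sqrt(v_pi),
             stringsAsFactors = FALSE)
}

#' Number of polymorphic sites among a set of sequences
#'
#' Counts alignment columns at which at least two distinct unambiguous bases
#' are observed among the given sequences; gaps and `N` do not contribute.
#'
#' @param aln an [alignment()].
#' @param ids sequence ids to consider (default all).
#' @return integer count of polymorphic sites.
#' @export
polymorphic_sites <- function(aln, ids = aln$ids) {
  if (length(ids) == 0L) abort("need at least one sequence", "input_error")
  m <- aln$mat[ids, , drop = FALSE]
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }))
}

#' Per-population diversity table
#'
#' Convenience wrapper assembling the within-population diversity summary for
#' every population: sample size, number of haplotypes, polymorphic sites,
#' haplotype diversity, mean pairwise differences and nucleotide diversity
#' (each with sd).
#'
#' @param table a `"hap_table"`.
#' @param d haplotype `"dist_matrix"` (difference counts).
#' @param aln haplotype [alignment()] (representative sequences), used for
#'   polymorphic-site counts.
#' @return a data.frame with one row per population.
#' @export
diversity_table <- function(table, d, aln = hap_alignment(table)) {
  pops <- colnames(table$counts)
  rows <- lapply(pops, function(p) {
    row <- diversity(table, p, d, L = aln$L)
    present <- table$haplotype_id[table$counts[, p] > 0]
    row$polymorphic_sites <- polymorphic_sites(aln, present)
    row
  })
  out <- do.call(rbind, rows)
  out[, c("population", "n", "k", "polymorphic_sites", "h", "h_sd",
          "mean_pairwise", "mean_pairwise_sd", "pi", "pi_sd")]
}

#' Net (corrected) population distances
#'
#' `d_net(X, Y) = Pi_XY - (Pi_XX + Pi_YY) / 2` where every `Pi` is the
#' frequency-weighted mean inter-haplotype distance
#' `sum_ij p_i q_j d(i, j)` between the two populations' haplotype frequency
#' vectors (so two populations of identical composition are at net distance
#' exactly 0). Slightly negative values can occur through sampling noise and
#' are retained.
#'
#' @param table a `"hap_table"` (all populations with `n >= 2`).
#' @param d haplotype `"dist_matrix"`.
#' @return a `"dist_matrix"` with metric `"net_pairwise"`.
#' @export
net_population_distance <- function(table, d) {
  pops <- colnames(table$counts)
  sizes <- colSums(table$counts)
  if (any(sizes < 2L)) abort("all populations need n >= 2", "insufficient_data")
  m <- unclass(d)[table$haplotype_id, table$haplotype_id]
  freq <- sweep(table$counts, 2L, sizes, "/")
  pi_mat <- t(freq) %*% m %*% freq
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      out[i, j] <- out[j, i] <-
        pi_mat[i, j] - (pi_mat[i, i] + pi_mat[j, j]) / 2
    }
  }
  new_dist_matrix(out, "net_pairwise", pops)
}
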