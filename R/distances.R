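# Pairwise difference counts and Tamura-Nei (TN93) evolutionary distances,
# plus clade-level distance summaries.

new_dist_matrix <- function(m, metric, labels = rownames(m)) {
  dimnames(m) <- list(labels, labels)
  attr(m, "metric") <- metric
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d labels\n",
              attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# per-base indicator matrices (n x L) used to vectorise pairwise counts
base_indicators <- function(mat) {
  lapply(stats::setNames(nm = c("A", "C", "G", "T")),
         function(b) (mat == b) * 1)
}

# n x n matrices of per-pair site counts: comparable sites, matches, and the
# six pair-type counts needed by TN93 (AG, CT transitions; transversions)
pair_site_counts <- function(mat) {
  ind <- base_indicators(mat)
  valid <- ind$A + ind$C + ind$G + ind$T
  comparable <- tcrossprod(valid)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  ag <- tcrossprod(ind$A, ind$G); ag <- ag + t(ag)
  ct <- tcrossprod(ind$C, ind$T); ct <- ct + t(ct)
  diffs <- comparable - matches
  list(comparable = comparable, diffs = diffs,
       transitions_ag = ag, transitions_ct = ct,
       transversions = diffs - ag - ct)
}

#' Pairwise difference-count matrix
#'
#' Entry (i, j) is the number of sites at which sequences i and j carry
#' different unambiguous bases; sites where either sequence has a gap or `N`
#' are excluded pair by pair (pairwise deletion).
#'
#' @param aln an [alignment()] with at least two sequences.
#' @param strict error (rather than flag `NA` with a warning) when a pair has
#'   zero comparable sites.
#' @return a `"dist_matrix"` with metric `"diff_count"`; the per-pair number
#'   of comparable sites is attached as attribute `"comparable"`.
#' @export
pairwise_diff_matrix <- function(aln, strict = FALSE) {
  if (length(aln$ids) < 2L) abort("need at least two sequences", "input_error")
  pc <- pair_site_counts(aln$mat)
  d <- pc$diffs
  none <- pc$comparable == 0
  diag(none) <- FALSE
  if (any(none)) {
    if (strict) abort("pair(s) with zero comparable sites", "input_error")
    warning("pair(s) with zero comparable sites flagged as NA")
    d[none] <- NA_real_
  }
  diag(d) <- 0
  out <- new_dist_matrix(d, "diff_count", aln$ids)
  attr(out, "comparable") <- pc$comparable
  out
}

#' Tamura-Nei (TN93) distance matrix
#'
#' Evolutionary distances under the Tamura-Nei (1993) substitution model,
#' which allows distinct rates for purine (A<->G) and pyrimidine (C<->T)
#' transitions and for transversions, with unequal base frequencies. Base
#' frequencies are by default estimated once from all sequences pooled;
#' missing data are handled by pairwise deletion. Saturated pairs (a
#' logarithm argument <= 0) are reported as `NA` with a warning, or raise an
#' error in strict mode.
#'
#' @param aln an [alignment()].
#' @param freqs optional base frequencies (named `A, C, G, T`); estimated
#'   from the pooled alignment when omitted.
#' @param per_pair estimate base frequencies per pair instead of pooled.
#' @param strict error on saturated pairs.
#' @return a `"dist_matrix"` with metric `"tn93"`.
#' @export
tn93_distance_matrix <- function(aln, freqs = NULL, per_pair = FALSE,
                                 strict = FALSE) {
  if (length(aln$ids) < 2L) abort("need at least two sequences", "input_error")
  pc <- pair_site_counts(aln$mat)
  n <- length(aln$ids)
  if (is.null(freqs)) {
    tab <- table(factor(aln$mat, levels = c("A", "C", "G", "T")))
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- c("A", "C", "G", "T")
  }
  tn93_d <- function(P1, P2, Q, f) {
    gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
    gR <- gA + gG; gY <- gC + gT
    k1 <- 2 * gA * gG / gR
    k2 <- 2 * gT * gC / gY
    k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(NA_real_)
    -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }
  if (any(freqs <= 0)) abort("all four base frequencies must be positive", "input_error")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m <- pc$comparable[i, j]
      if (m == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
      f <- freqs
      if (per_pair) {
        tab <- table(factor(aln$mat[c(i, j), ], levels = c("A", "C", "G", "T")))
        f <- as.numeric(tab) / sum(tab)
        names(f) <- c("A", "C", "G", "T")
        if (any(f <= 0)) abort("per-pair base frequency of zero", "input_error")
      }
      d[i, j] <- d[j, i] <- tn93_d(pc$transitions_ag[i, j] / m,
                                   pc$transitions_ct[i, j] / m,
                                   pc$transversions[i, j] / m, f)
    }
  }
  bad <- is.na(d); diag(bad) <- FALSE
  if (any(bad & pc$comparable > 0)) {
    if (strict) abort("saturated pair(s): TN93 log argument <= 0", "saturation_error")
    warning("saturated pair(s) reported as NA")
  }
  if (any(bad & pc$comparable == 0)) {
    if (strict) abort("pair(s) with zero comparable sites", "input_error")
    warning("pair(s) with zero comparable sites flagged as NA")
  }
  out <- new_dist_matrix(d, "tn93", aln$ids)
  attr(out, "comparable") <- pc$comparable
  attr(out, "base_freqs") <- freqs
  out
}

#' Within- and between-clade distance summary
#'
#' Summarises a haplotype distance matrix over a clade partition: mean
#' pairwise distance within each clade (over unordered pairs; `NA` for
#' singleton clades), mean between each clade pair, and the corrected (net)
#' between-clade mean, `net = between - (within_i + within_j) / 2`. The
#' overall summary reports mean and sd of the between means over clade
#' pairs and of the within means over clades.
#'
#' @param d a `"dist_matrix"` over haplotypes.
#' @param clades named vector mapping every haplotype label to a clade label.
#' @return a list of class `"clade_dist_summary"` with `within` (named
#'   vector), `between`, `net` (matrices), `n_per_clade` and `overall`
#'   (between_mean, between_sd, within_mean, within_sd, ratio).
#' @export
clade_distance_summary <- function(d, clades) {
  labs <- rownames(d)
  if (!setequal(labs, names(clades)) || length(clades) != length(labs)) {
    abort("clade partition must assign every label exactly once", "partition_error")
  }
  clades <- clades[labs]
  cl <- sort(unique(clades))
  idx <- lapply(cl, function(g) which(clades == g))
  if (any(lengths(idx) == 0L)) abort("clade with zero members", "partition_error")
  k <- length(cl)
  within <- vapply(idx, function(i) cross_mean(d, i, i), numeric(1L))
  names(within) <- cl
  between <- matrix(NA_real_, k, k, dimnames = list(cl, cl))
  net <- between
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      between[i, j] <- cross_mean(d, idx[[i]], idx[[j]])
      net[i, j] <- between[i, j] - (within[i] + within[j]) / 2
    }
  }
  bvals <- between[upper.tri(between)]
  overall <- list(
    between_mean = mean(bvals), between_sd = stats::sd(bvals),
    within_mean = mean(within, na.rm = TRUE),
    within_sd = stats::sd(within[!is.na(within)]),
    ratio = mean(bvals) / mean(within, na.rm = TRUE)
  )
  structure(list(within = within, between = between, net = net,
                 n_per_clade = lengths(idx), overall = overall),
            class = "clade_dist_summary")
}

#' @export
print.clade_dist_summary <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "Clade distances: between %.2f +/- %.2f, within %.2f +/- %.2f (ratio %.2f)\n",
    o$between_mean, o$between_sd, o$within_mean, o$within_sd, o$ratio))
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param d a `"dist_matrix"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  df <- data.frame(label = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
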