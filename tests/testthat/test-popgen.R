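# Diversity estimators, pairwise Phi-ST, AMOVA and net distances.

toy_table <- function(counts, seqs = NULL) {
  k <- nrow(counts)
  if (is.null(seqs)) seqs <- distinct_seqs(rownames(counts))
  # representative toy sequences are only placeholders; tests pass explicit
  # distance matrices alongside
  hap_table(seqs, counts)
}

dist_from <- function(m) {
  structure(m, metric = "diff_count", class = c("dist_matrix", "matrix"))
}

test_that("diversity matches enumeration on the two-haplotype example", {
  counts <- rbind(H1 = c(P = 2L), H2 = c(P = 2L))
  seqs <- c(H1 = "AAAA", H2 = "AAAT")
  m <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  tab <- hap_table(seqs, counts)
  out <- diversity(tab, "P", dist_from(m), L = 4)
  expect_equal(out$h, (4 / 3) * (1 - 0.5))
  expect_equal(out$mean_pairwise, (2 * 2 * 3) / 6)
  ora <- oracle_diversity(c(H1 = 2, H2 = 2), m)
  expect_equal(out$h, ora$h)
  expect_equal(out$mean_pairwise, ora$Pi)
})

test_that("diversity agrees with the pair-enumeration oracle on random tables", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    counts <- matrix(rpois(k, 3) + 1L, k, 1,
                     dimnames = list(sprintf("H%d", 1:k), "P"))
    m <- matrix(sample(0:20, k * k, TRUE), k, k)
    m <- m + t(m); diag(m) <- 0
    dimnames(m) <- dimnames(counts)[c(1, 1)]
    tab <- toy_table(counts)
    out <- diversity(tab, "P", dist_from(m), L = 100)
    ora <- oracle_diversity(stats::setNames(counts[, 1], rownames(counts)), m)
    expect_equal(out$h, ora$h, tolerance = 1e-12)
    expect_equal(out$mean_pairwise, ora$Pi, tolerance = 1e-12)
    expect_equal(out$pi, out$mean_pairwise / 100, tolerance = 1e-12)
  }
})

test_that("monomorphic populations have zero diversity", {
  counts <- rbind(H1 = c(P = 5L, Q = 2L), H2 = c(P = 0L, Q = 3L))
  m <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  out <- diversity(toy_table(counts), "P", dist_from(m), L = 10)
  expect_equal(out$h, 0)
  expect_equal(out$mean_pairwise, 0)
  expect_equal(out$pi, 0)
  expect_error(diversity(toy_table(rbind(H1 = c(P = 1L))), "P",
                         dist_from(matrix(0, 1, 1, dimnames = list("H1", "H1"))),
                         L = 10),
               class = "insufficient_data")
})

test_that("haplotype diversity is label-invariant and rewards evenness", {
  m <- matrix(5, 3, 3, dimnames = list(paste0("H", 1:3), paste0("H", 1:3)))
  diag(m) <- 0
  even <- rbind(H1 = c(P = 4L), H2 = c(P = 4L), H3 = c(P = 4L))
  skew <- rbind(H1 = c(P = 9L), H2 = c(P = 2L), H3 = c(P = 1L))
  h_even <- diversity(toy_table(even), "P", dist_from(m), 10)$h
  h_skew <- diversity(toy_table(skew), "P", dist_from(m), 10)$h
  expect_gt(h_even, h_skew)
  perm <- c(3, 1, 2)
  m2 <- m[perm, perm]
  relab <- rbind(H3 = c(P = 4L), H1 = c(P = 4L), H2 = c(P = 4L))
  tab2 <- hap_table(c(H3 = "GGGGG", H1 = "AAAAA", H2 = "CCCCC"), relab)
  expect_equal(diversity(tab2, "P", dist_from(m2), 10)$h, h_even)
})

test_that("polymorphic site counts scan columns correctly", {
  a <- alignment(c(h1 = "ACGTA", h2 = "ACGTA"))
  expect_equal(polymorphic_sites(a, "h1"), 0L)
  b <- alignment(c(h1 = "AAAAA", h2 = "CCCCA"))
  expect_equal(polymorphic_sites(b), 4L)
  cc <- alignment(c(h1 = "AAAA", h2 = "CAAA", h3 = "GAAA", h4 = "TAAA"))
  expect_equal(polymorphic_sites(cc), 1L)
  # gaps and N never create polymorphism
  d <- alignment(c(h1 = "A-NA", h2 = "AANA"))
  expect_equal(polymorphic_sites(d), 0L)
})

test_that("AMOVA matches the explicit-loop oracle on small fixtures", {
  set.seed(7)
  for (rep in 1:6) {
    k <- 4
    counts <- matrix(0L, k, 3, dimnames = list(paste0("H", 1:k), c("A", "B", "C")))
    while (any(colSums(counts) < 2)) {
      counts[] <- rpois(k * 3, 1.2)
    }
    m <- matrix(sample(0:12, k * k, TRUE), k, k)
    m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(rownames(counts), rownames(counts))
    tab <- toy_table(counts)
    res <- amova(tab, dist_from(m))
    haps <- unlist(lapply(colnames(counts), function(p)
      rep(rownames(counts), counts[, p])))
    grp <- unlist(lapply(colnames(counts), function(p) rep(p, sum(counts[, p]))))
    M <- m[haps, haps]
    ora <- oracle_amova(M, grp)
    expect_equal(res$table$SSD[1], ora$ssd_a, tolerance = 1e-9)
    expect_equal(res$table$SSD[2], ora$ssd_w, tolerance = 1e-9)
    expect_equal(res$table$percent[1], ora$pct_a, tolerance = 1e-9)
    expect_equal(res$phi, ora$phi, tolerance = 1e-9)
    expect_equal(sum(res$table$percent[1:2]), 100, tolerance = 1e-9)
    expect_equal(res$table$df[3], sum(colSums(counts)) - 1)
  }
})

test_that("AMOVA extremes behave: fixed differences and duplicated labels", {
  counts <- rbind(H1 = c(A = 5L, B = 0L), H2 = c(A = 0L, B = 5L))
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  res <- amova(toy_table(counts), dist_from(m))
  expect_equal(res$table$percent[1], 100, tolerance = 1e-9)
  expect_equal(res$phi, 1, tolerance = 1e-9)

  dup <- rbind(H1 = c(A = 5L, B = 5L), H2 = c(A = 3L, B = 3L),
               H3 = c(A = 2L, B = 2L))
  m3 <- matrix(c(0, 4, 7, 4, 0, 5, 7, 5, 0), 3, 3,
               dimnames = list(paste0("H", 1:3), paste0("H", 1:3)))
  res2 <- amova(toy_table(dup), dist_from(m3))
  expect_lt(res2$table$percent[1], 5)
  expect_error(amova(toy_table(dup), dist_from(m3),
                     strata = c(A = "x", B = "x")),
               class = "input_error")
})

test_that("pairwise Phi-ST reproduces two-group AMOVA and its limits", {
  counts <- rbind(H1 = c(A = 3L, B = 1L), H2 = c(A = 1L, B = 3L))
  m <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  tab <- toy_table(counts)
  fst <- pairwise_fst(tab, dist_from(m), n_perm = 0)
  haps <- c(rep("H1", 3), "H2", "H1", rep("H2", 3))
  grp <- rep(c("A", "B"), each = 4)
  ora <- oracle_amova(m[haps, haps], grp)
  expect_equal(unclass(fst$fst)["A", "B"], ora$phi, tolerance = 1e-9)

  # identical composition: the method-of-moments estimate is never
  # significantly positive (small negative values are finite-sample bias)
  same <- rbind(H1 = c(A = 4L, B = 4L), H2 = c(A = 4L, B = 4L))
  f0 <- pairwise_fst(toy_table(same), dist_from(m), n_perm = 199, seed = 5)
  expect_lt(unclass(f0$fst)["A", "B"], 0.05)
  expect_gt(unclass(f0$fst)["A", "B"], -0.25)
  expect_gt(f0$p["A", "B"], 0.5)

  fixed <- rbind(H1 = c(A = 6L, B = 0L), H2 = c(A = 0L, B = 6L))
  f1 <- pairwise_fst(toy_table(fixed), dist_from(m), n_perm = 99, seed = 5)
  expect_equal(unclass(f1$fst)["A", "B"], 1)
  expect_lt(f1$p["A", "B"], 0.05)

  expect_error(pairwise_fst(toy_table(rbind(H1 = c(A = 1L, B = 4L))),
                            dist_from(matrix(0, 1, 1,
                                             dimnames = list("H1", "H1"))),
                            n_perm = 0),
               class = "input_error")
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(99)
  haps <- paste0("H", 1:8)
  seqs <- stats::setNames(vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), ""), haps)
  dm <- pairwise_diff_matrix(alignment(seqs))
  ps <- vapply(1:200, function(i) {
    cnt <- cbind(A = tabulate(sample(8, 10, TRUE), 8),
                 B = tabulate(sample(8, 10, TRUE), 8))
    rownames(cnt) <- haps
    pairwise_fst(hap_table(seqs, cnt), dm, n_perm = 99, seed = i)$p["A", "B"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Phi-ST between populations drawn from one pool is near zero", {
  cfg <- sim_config(beta = 0, sigma = 1e9)
  vals <- vapply(1:10, function(s) {
    ds <- simulate_dataset(cfg, s)
    tab <- collapse_haplotypes(ds$aln, ds$meta)
    dc <- pairwise_diff_matrix(hap_alignment(tab))
    mean(pairwise_fst(tab, dc, n_perm = 0)$fst)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("net population distances follow the corrected-mean definition", {
  m <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  # identical composition -> exactly zero
  same <- rbind(H1 = c(A = 3L, B = 3L), H2 = c(A = 2L, B = 2L))
  net0 <- net_population_distance(toy_table(same), dist_from(m))
  expect_equal(unclass(net0)["A", "B"], 0)
  # two monomorphic populations at distance 4 -> net 4
  fixed <- rbind(H1 = c(A = 4L, B = 0L), H2 = c(A = 0L, B = 4L))
  net1 <- net_population_distance(toy_table(fixed), dist_from(m))
  expect_equal(unclass(net1)["A", "B"], 4)
  expect_equal(attr(net1, "metric"), "net_pairwise")
})

test_that("diversity table assembles all indices per population", {
  cfg <- sim_config()
  ds <- simulate_dataset(cfg, 4)
  tab <- collapse_haplotypes(ds$aln, ds$meta)
  dc <- pairwise_diff_matrix(hap_alignment(tab))
  div <- diversity_table(tab, dc)
  expect_equal(nrow(div), 7L)
  expect_equal(sum(div$n), 136)
  expect_true(all(div$h >= 0 & div$h <= 1))
  expect_true(all(div$k <= div$n))
  # internal consistency: nucleotide diversity x L = mean pairwise difference
  expect_equal(div$pi * 1121, div$mean_pairwise, tolerance = 1e-6)
})
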