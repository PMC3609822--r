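# NJ/UPGMA building, bootstrap support, collapsing and clade extraction.

test_that("NJ exactly recovers random additive trees", {
  for (seed in 1:10) {
    n <- sample(4:8, 1)
    tr <- random_additive_tree(n, seed)
    d <- ape::cophenetic.phylo(tr)
    est <- build_nj(d)
    expect_equal(rf_dist(tr, est), 0)
    expect_equal(sort(est$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("NJ topology agrees with an independent textbook NJ oracle", {
  for (seed in c(3, 12, 31)) {
    set.seed(seed)
    n <- 5
    m <- matrix(stats::runif(n * n, 1, 10), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    est <- build_nj(m)
    expect_true(same_split_sets(tree_splits(est), oracle_nj_splits(m)))
  }
})

test_that("tree builders reject degenerate inputs", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(build_nj(m), class = "size_error")
  m3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m3[1, 2] <- m3[2, 1] <- NA
  expect_error(build_nj(m3), class = "input_error")
  expect_s3_class(build_upgma(m), "phylo")
})

test_that("UPGMA is exact on ultrametric matrices and merges by average", {
  tr <- ape::rcoal(6)
  d <- ape::cophenetic.phylo(tr)
  up <- build_upgma(d)
  expect_equal(ape::cophenetic.phylo(up)[rownames(d), colnames(d)], d,
               tolerance = 1e-8)

  m <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  up3 <- build_upgma(m)
  cp <- ape::cophenetic.phylo(up3)
  expect_equal(cp["A", "B"], 2)
  expect_equal(cp["A", "C"], 7) # mean(8, 6): average-linkage merge height
  expect_equal(cp["B", "C"], 7)
})

# two clearly separated 4-taxon groups: 20 diagnostic sites plus a couple of
# private mutations per tip
separated_groups_aln <- function(L = 120, n_diag = 20, seed = 5) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  flip <- function(x) c(A = "G", G = "A", C = "T", T = "C")[[x]]
  other <- base
  for (s in seq_len(n_diag)) other[s] <- flip(other[s])
  mk <- function(tmpl, priv_at) {
    x <- tmpl
    for (s in priv_at) x[s] <- flip(x[s])
    paste(x, collapse = "")
  }
  seqs <- c(
    a1 = mk(base, 30), a2 = mk(base, 40), a3 = mk(base, 50), a4 = mk(base, 60),
    b1 = mk(other, 70), b2 = mk(other, 80), b3 = mk(other, 90),
    b4 = mk(other, 100))
  alignment(seqs)
}

test_that("bootstrap support is seeded, reproducible and finds real splits", {
  a <- separated_groups_aln()
  t1 <- bootstrap_support(a, n_reps = 200, seed = 77)
  t2 <- bootstrap_support(a, n_reps = 200, seed = 77)
  expect_identical(t1$node.label, t2$node.label)

  # central bipartition {a*} | {b*} must be near-certain
  splits <- tree_splits(t1)
  ntip <- ape::Ntip(t1)
  pp <- ape::prop.part(ape::unroot(t1))
  central <- which(vapply(pp, function(s) {
    labs <- sort(t1$tip.label[s])
    identical(labs, sort(c("a1", "a2", "a3", "a4"))) ||
      identical(labs, sort(c("b1", "b2", "b3", "b4")))
  }, logical(1)))
  sup <- t1$node.label[central]
  expect_true(any(sup >= 95, na.rm = TRUE))
})

test_that("single-replicate supports are 0 or 100", {
  a <- separated_groups_aln(seed = 9)
  t1 <- bootstrap_support(a, n_reps = 1, seed = 4)
  sup <- t1$node.label[-1]
  expect_true(all(sup %in% c(0, 100)))
})

test_that("identical sequences yield no supported bipartitions", {
  a <- alignment(stats::setNames(rep(strrep("ACGT", 10), 5), letters[1:5]))
  t1 <- bootstrap_support(a, n_reps = 50, seed = 2)
  expect_true(all(t1$node.label[-1] == 0))
})

test_that("support collapsing contracts exactly the weak branches", {
  tr <- ape::read.tree(text = "((a:1,b:1)60:1,(c:1,d:1)80:1,e:1);")
  col <- collapse_low_support(tr, 70)
  expect_equal(ape::Ntip(col), 5L)
  expect_equal(col$Nnode, 2L) # one of the two internal branches contracted
  splits <- tree_splits(col)
  expect_true(same_split_sets(splits, list(c("c", "d"))))

  # all supported: unchanged; all weak: star
  hi <- ape::read.tree(text = "((a:1,b:1)90:1,(c:1,d:1)80:1,e:1);")
  expect_equal(collapse_low_support(hi, 70)$Nnode, ape::unroot(hi)$Nnode)
  lo <- ape::read.tree(text = "((a:1,b:1)10:1,(c:1,d:1)20:1,e:1);")
  expect_equal(collapse_low_support(lo, 70)$Nnode, 1L)
})

test_that("collapsing preserves leaves and only removes bipartitions", {
  a <- separated_groups_aln(seed = 13)
  t1 <- bootstrap_support(a, n_reps = 100, seed = 3)
  col <- collapse_low_support(t1, 70)
  expect_setequal(col$tip.label, t1$tip.label)
  canon <- function(s) paste(s, collapse = "|")
  s_orig <- vapply(tree_splits(t1), canon, "")
  s_col <- vapply(tree_splits(col), canon, "")
  expect_true(all(s_col %in% s_orig))
})

test_that("clade extraction partitions leaves deterministically", {
  # rooted tree with two supported sister clusters of 3 + 2 leaves
  tr <- ape::read.tree(text = "((a,b,c)80,(d,e)90);")
  cl <- extract_clades(tr, 70)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(unname(cl[c("a", "b", "c")]), rep("G1", 3))
  expect_equal(unname(cl[c("d", "e")]), rep("G2", 2))

  # star tree: every leaf its own clade
  star <- ape::read.tree(text = "((a,b)10,(c,d)20,e);")
  cls <- extract_clades(star, 70)
  expect_equal(length(unique(cls)), 5L)

  # two supported clusters hanging off an unrooted backbone
  tr2 <- ape::read.tree(text = "((a:1,b:1)95:1,(c:1,d:1)99:1,(e:1,f:1)10:1);")
  cl2 <- extract_clades(tr2, 70)
  expect_equal(unname(cl2["a"]), unname(cl2["b"]))
  expect_equal(unname(cl2["c"]), unname(cl2["d"]))
  expect_false(cl2[["e"]] == cl2[["f"]])
})

test_that("clade extraction recovers simulated clades through the bootstrap", {
  for (seed in c(2, 6)) {
    cfg <- sim_config()
    hp <- simulate_haplotypes(cfg, seed)
    bt <- bootstrap_support(hp$aln, n_reps = 100, seed = seed)
    cl <- extract_clades(bt, 70)
    expect_equal(length(unique(cl)), cfg$n_clades)
    expect_equal(ari(cl[names(hp$clades)], hp$clades), 1)
  }
})

test_that("trees round-trip to Newick with supports", {
  a <- separated_groups_aln(seed = 21)
  t1 <- bootstrap_support(a, n_reps = 50, seed = 6)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree(t1, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, t1$tip.label)
  expect_equal(rf_dist(back, t1), 0)
})
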