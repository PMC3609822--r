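# Independent oracle implementations and fixture builders used across the
# suite. Oracles deliberately use different code paths (explicit loops,
# closed forms) from the package implementations they check.

rand_seqs <- function(n, L, seed = 1) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)),
    sprintf("s%02d", seq_len(n)))
}

# brute-force pairwise difference counts with pairwise deletion
oracle_diff_matrix <- function(strings) {
  n <- length(strings)
  chars <- strsplit(strings, "")
  out <- matrix(0, n, n, dimnames = list(names(strings), names(strings)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      out[i, j] <- sum(a[ok] != b[ok])
    }
  }
  out
}

# explicit-loop AMOVA decomposition (squared distances = entries of M)
oracle_amova <- function(M, grp) {
  N <- length(grp)
  groups <- unique(grp)
  G <- length(groups)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
    ss_total <- ss_total + M[i, j]
  }
  ss_total <- ss_total / N
  ss_within <- 0
  for (g in groups) {
    idx <- which(grp == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in seq(a + 1, length(idx))) {
        s <- s + M[idx[a], idx[b]]
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_a <- G - 1; df_w <- N - G
  sigma_w <- ss_within / df_w
  n_prime <- (N - sum(table(grp)^2) / N) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n_prime
  list(ssd_a = ss_among, ssd_w = ss_within,
       sigma_a = sigma_a, sigma_w = sigma_w,
       pct_a = 100 * sigma_a / (sigma_a + sigma_w),
       phi = sigma_a / (sigma_a + sigma_w))
}

# enumeration-based within-population diversity
oracle_diversity <- function(counts, dmat) {
  haps <- rep(names(counts), counts)
  n <- length(haps)
  pairs_d <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pairs_d <- c(pairs_d, dmat[haps[i], haps[j]])
  }
  p <- counts / n
  list(h = n / (n - 1) * (1 - sum(p^2)), Pi = mean(pairs_d))
}

# textbook neighbor-joining returning the set of nontrivial bipartitions
# (each as a sorted character vector of leaf labels)
oracle_nj_splits <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  clusters <- as.list(labs)
  act <- seq_len(n)
  D <- d
  splits <- list()
  while (length(act) > 2) {
    m <- length(act)
    r <- rowSums(D[act, act])
    q <- matrix(Inf, m, m)
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      q[i, j] <- (m - 2) * D[act[i], act[j]] - r[i] - r[j]
    }
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    a <- act[ij[1]]; b <- act[ij[2]]
    newc <- sort(c(clusters[[a]], clusters[[b]]))
    if (length(newc) <= n - 2) splits <- c(splits, list(newc))
    Dnew <- (D[a, ] + D[b, ] - D[a, b]) / 2
    D <- rbind(cbind(D, new = Dnew), new = c(Dnew, 0))
    k <- nrow(D)
    rownames(D)[k] <- colnames(D)[k] <- paste0("c", k)
    clusters[[k]] <- newc
    act <- c(setdiff(act, c(a, b)), k)
  }
  splits
}

tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- ape::Ntip(tree)
  pp <- ape::prop.part(tree)
  out <- list()
  for (i in seq_along(pp)) {
    s <- tree$tip.label[pp[[i]]]
    if (length(s) >= 2 && length(s) <= ntip - 2) out <- c(out, list(sort(s)))
  }
  out
}

same_split_sets <- function(a, b) {
  # bipartition sides are defined up to complement
  all_labs <- sort(unique(unlist(c(a, b))))
  canon <- function(s) {
    comp <- setdiff(all_labs, s)
    paste(if (length(s) <= length(comp)) s else comp, collapse = "|")
  }
  setequal(vapply(a, canon, ""), vapply(b, canon, ""))
}

ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2)); si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2)); n2 <- choose(sum(tab), 2)
  e <- si * sj / n2
  (sij - e) / ((si + sj) / 2 - e)
}

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
  tr
}

# independent crossing-count oracle: solves each segment pair by 2x2 linear
# system and de-duplicates intersection points by coordinates
oracle_crossings <- function(a, b, map, R = 6371) {
  lat0 <- (a[1] + b[1]) / 2; lon0 <- (a[2] + b[2]) / 2
  prj <- function(lat, lon) c(R * (lon - lon0) * pi / 180 * cos(lat0 * pi / 180),
                              R * (lat - lat0) * pi / 180)
  p1 <- prj(a[1], a[2]); p2 <- prj(b[1], b[2])
  total <- 0
  for (rv in unclass(map)) {
    if (rv$width_class != "large") next
    pts <- t(apply(rv$coords, 1, function(cc) prj(cc[2], cc[1])))
    hits <- NULL
    for (k in seq_len(nrow(pts) - 1)) {
      q1 <- pts[k, ]; q2 <- pts[k + 1, ]
      A <- cbind(p2 - p1, -(q2 - q1))
      if (abs(det(A)) < 1e-12) next
      tu <- solve(A, q1 - p1)
      if (all(tu >= -1e-12) && all(tu <= 1 + 1e-12)) {
        hits <- rbind(hits, p1 + tu[1] * (p2 - p1))
      }
    }
    if (!is.null(hits)) {
      total <- total + nrow(unique(round(hits, 6)))
    }
  }
  total
}

# fine-lattice shortest-path oracle for the detoured distance (planar, km)
oracle_grid_detour <- function(a, b, map, n_grid = 80, pad = 0.2, R = 6371) {
  lat0 <- (a[1] + b[1]) / 2; lon0 <- (a[2] + b[2]) / 2
  prj <- function(lat, lon) c(R * (lon - lon0) * pi / 180 * cos(lat0 * pi / 180),
                              R * (lat - lat0) * pi / 180)
  p1 <- prj(a[1], a[2]); p2 <- prj(b[1], b[2])
  segs <- NULL
  for (rv in unclass(map)) {
    if (rv$width_class != "large") next
    pts <- t(apply(rv$coords, 1, function(cc) prj(cc[2], cc[1])))
    # close off the mouth (first vertex) with a long ray, as the definition
    # of the detour requires passage around the headwater only
    dirv <- pts[1, ] - pts[2, ]; dirv <- dirv / sqrt(sum(dirv^2))
    pts <- rbind(pts[1, ] + dirv * 1e4, pts)
    segs <- rbind(segs, cbind(pts[-nrow(pts), , drop = FALSE],
                              pts[-1, , drop = FALSE]))
  }
  # bounding box padded around sites and river vertices (excluding the ray)
  core <- rbind(p1, p2, segs[-1, 1:2, drop = FALSE],
                segs[-1, 3:4, drop = FALSE])
  xr <- range(core[, 1]); yr <- range(core[, 2])
  xr <- xr + c(-1, 1) * pad * diff(xr); yr <- yr + c(-1, 1) * pad * diff(yr)
  xs <- seq(xr[1], xr[2], length.out = n_grid)
  ys <- seq(yr[1], yr[2], length.out = n_grid)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  nodes <- rbind(nodes, p1, p2)
  id1 <- nrow(nodes) - 1; id2 <- nrow(nodes)
  crosses <- function(u, v) {
    r <- v - u
    d1 <- r[1] * (segs[, 2] - u[2]) - r[2] * (segs[, 1] - u[1])
    d2 <- r[1] * (segs[, 4] - u[2]) - r[2] * (segs[, 3] - u[1])
    s1 <- (segs[, 3] - segs[, 1]) * (u[2] - segs[, 2]) -
      (segs[, 4] - segs[, 2]) * (u[1] - segs[, 1])
    s2 <- (segs[, 3] - segs[, 1]) * (v[2] - segs[, 2]) -
      (segs[, 4] - segs[, 2]) * (v[1] - segs[, 1])
    any(d1 * d2 < 0 & s1 * s2 < 0)
  }
  # 8-neighbour lattice edges + connections of the two sites to nearby nodes
  idx <- function(i, j) (j - 1) * n_grid + i
  ed <- list(); w <- list(); k <- 0
  for (j in seq_len(n_grid)) {
    for (i in seq_len(n_grid)) {
      from <- idx(i, j)
      for (step in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
        i2 <- i + step[1]; j2 <- j + step[2]
        if (i2 < 1 || i2 > n_grid || j2 < 1 || j2 > n_grid) next
        to <- idx(i2, j2)
        if (!crosses(nodes[from, ], nodes[to, ])) {
          k <- k + 1
          ed[[k]] <- c(from, to)
          w[[k]] <- sqrt(sum((nodes[from, ] - nodes[to, ])^2))
        }
      }
    }
  }
  d2 <- function(p) sqrt((nodes[seq_len(n_grid^2), 1] - p[1])^2 +
                           (nodes[seq_len(n_grid^2), 2] - p[2])^2)
  for (pid in c(id1, id2)) {
    near <- order(d2(nodes[pid, ]))[1:12]
    for (nd in near) {
      if (!crosses(nodes[pid, ], nodes[nd, ])) {
        k <- k + 1
        ed[[k]] <- c(pid, nd)
        w[[k]] <- sqrt(sum((nodes[pid, ] - nodes[nd, ])^2))
      }
    }
  }
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  g <- igraph::add_edges(g, unlist(ed))
  igraph::distances(g, v = id1, to = id2, weights = unlist(w))[1, 1]
}

# k distinct placeholder sequences of equal length
distinct_seqs <- function(ids) {
  k <- length(ids)
  stats::setNames(vapply(seq_len(k), function(i) {
    x <- rep("A", k + 2)
    x[i] <- "C"
    paste(x, collapse = "")
  }, character(1)), ids)
}

rf_dist <- function(t1, t2) as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
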