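# Neighbor-joining and UPGMA tree building, site bootstrap, support-based
# collapsing and haplogroup (clade) extraction.

check_dist_input <- function(d, min_n) {
  if (nrow(d) < min_n) {
    abort(sprintf("need at least %d labels, got %d", min_n, nrow(d)), "size_error")
  }
  if (anyNA(unclass(d)) || any(is.nan(unclass(d)))) {
    abort("distance matrix contains NA/NaN entries", "input_error")
  }
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix (unrooted tree).
#' Negative branch lengths can arise and are retained; use
#' [clamp_negative_branches()] for display.
#'
#' @param d a `"dist_matrix"` (or plain symmetric matrix) with `n >= 3`.
#' @return an `ape::phylo` tree.
#' @export
build_nj <- function(d) {
  check_dist_input(d, 3L)
  ape::nj(stats::as.dist(unclass(d)))
}

#' UPGMA (average-linkage) tree
#'
#' @param d a `"dist_matrix"` with `n >= 2`.
#' @return a rooted ultrametric `ape::phylo` tree.
#' @export
build_upgma <- function(d) {
  check_dist_input(d, 2L)
  ape::as.phylo(stats::hclust(stats::as.dist(unclass(d)), method = "average"))
}

#' Clamp negative branch lengths to zero
#' @param tree an `ape::phylo`.
#' @return the tree with `edge.length` floored at 0.
#' @export
clamp_negative_branches <- function(tree) {
  if (!is.null(tree$edge.length)) tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Site-bootstrap support for a distance tree
#'
#' Resamples alignment sites with replacement, rebuilds the tree for each
#' replicate, and scores every internal branch of the point-estimate tree by
#' the percentage of replicates containing the same bipartition. A replicate
#' counts as containing a bipartition only when the corresponding internal
#' branch is positively resolved: internal branches of length `<= 1e-8` in a
#' replicate tree are collapsed before counting, so data with no signal
#' (e.g. identical sequences) yield no supported bipartitions. Replicates in
#' which some pair has no comparable sites (or a saturated TN93 pair) are
#' skipped and counted in the attribute `"n_skipped"`.
#'
#' @param aln an [alignment()].
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; same seed gives identical supports.
#' @param metric `"diff_count"` or `"tn93"` distances.
#' @param builder tree-building function, [build_nj()] (default) or
#'   [build_upgma()].
#' @return the point-estimate tree with `node.label` holding percent support
#'   (root label `NA`); attributes `"n_valid_reps"` and `"n_skipped"`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              metric = c("diff_count", "tn93"),
                              builder = build_nj) {
  metric <- match.arg(metric)
  if (n_reps < 1L) abort("n_reps must be >= 1", "input_error")
  dist_fun <- switch(metric,
                     diff_count = pairwise_diff_matrix,
                     tn93 = tn93_distance_matrix)
  point <- builder(dist_fun(aln, strict = TRUE))
  trees <- vector("list", n_reps)
  n_valid <- 0L
  for (r in seq_len(n_reps)) {
    set.seed(split_seed(seed, "bootstrap", r))
    sites <- sample.int(aln$L, aln$L, replace = TRUE)
    rep_aln <- aln_subset(aln, sites = sites)
    d <- tryCatch(suppressWarnings(dist_fun(rep_aln)), error = function(e) NULL)
    if (is.null(d) || anyNA(unclass(d))) next
    n_valid <- n_valid + 1L
    trees[[n_valid]] <- ape::di2multi(builder(d), tol = 1e-8)
  }
  if (n_valid == 0L) abort("all bootstrap replicates degenerate", "bootstrap_error")
  trees <- trees[seq_len(n_valid)]
  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_valid
  support[1L] <- NA_real_ # root: trivial bipartition
  point$node.label <- support
  attr(point, "n_valid_reps") <- n_valid
  attr(point, "n_skipped") <- n_reps - n_valid
  point
}

# indices (into edge rows) of internal edges whose child-node support is
# below the threshold; NA supports are treated as supported (kept)
low_support_edges <- function(tree, threshold) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- ape::Ntip(tree)
  idx <- which(tree$edge[, 2L] > ntip)
  s <- sup[tree$edge[idx, 2L] - ntip]
  idx[!is.na(s) & s < threshold]
}

#' Collapse branches below a bootstrap-support threshold
#'
#' Contracts every internal branch whose support is below `threshold`
#' (percent), producing a multifurcating tree; the leaf set and all retained
#' branch lengths are unchanged.
#'
#' @param tree an `ape::phylo` whose `node.label` holds percent supports.
#' @param threshold support threshold in percent.
#' @return a (possibly multifurcating) `ape::phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 70) {
  if (is.null(tree$node.label)) abort("tree has no support labels", "input_error")
  drop <- low_support_edges(tree, threshold)
  if (length(drop) == 0L) return(tree)
  had_lengths <- !is.null(tree$edge.length)
  if (!had_lengths) tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[drop] <- -1
  out <- ape::di2multi(tree, tol = -0.5)
  if (!had_lengths) out$edge.length <- NULL
  out
}

# centroid internal node: removing it leaves the smallest possible largest
# component (in leaves); ties broken by node number
centroid_node <- function(tree) {
  ntip <- ape::Ntip(tree)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  internal <- seq.int(ntip + 1L, ntip + tree$Nnode)
  worst <- vapply(internal, function(v) {
    comp <- igraph::components(igraph::delete_vertices(g, v))$membership
    # vertex ids shift after deletion; recompute tip membership by name
    keep <- setdiff(seq_len(ntip + tree$Nnode), v)
    tips <- comp[match(seq_len(ntip), keep)]
    max(table(tips))
  }, numeric(1L))
  internal[which.min(worst)]
}

#' Extract haplogroups (clades) from a supported tree
#'
#' Collapses branches below `min_support`, roots the collapsed tree (at its
#' existing root when rooted, otherwise at the centroid node of the
#' multifurcating backbone), and returns the partition of leaves into the
#' maximal supported clusters hanging off the root; leaves attached directly
#' to the root become singleton clades. Clades are labelled `G1, G2, ...` by
#' decreasing size, then by the lexicographically smallest member.
#'
#' @param tree an `ape::phylo` with percent supports in `node.label`.
#' @param min_support support threshold in percent.
#' @return named character vector mapping each leaf label to a clade label.
#' @export
extract_clades <- function(tree, min_support = 70) {
  ct <- collapse_low_support(tree, min_support)
  if (!ape::is.rooted(ct)) {
    v <- centroid_node(ct)
    ntip <- ape::Ntip(ct)
    root_now <- ct$edge[1L, 1L]
    if (v != root_now) {
      ct <- ape::root(clamp_negative_branches(ct), node = v,
                      resolve.root = FALSE)
    }
  }
  ntip <- ape::Ntip(ct)
  root <- ct$edge[1L, 1L]
  kids <- ct$edge[ct$edge[, 1L] == root, 2L]
  groups <- lapply(kids, function(k) {
    if (k <= ntip) ct$tip.label[k]
    else ct$tip.label[unlist(ape::prop.part(ct)[[k - ntip]])]
  })
  # prop.part on rooted tree: list indexed by internal node - ntip of tip sets
  ord <- order(-lengths(groups),
               vapply(groups, function(g) sort(g)[1L], character(1L)))
  groups <- groups[ord]
  res <- unlist(lapply(seq_along(groups), function(i) {
    stats::setNames(rep(sprintf("G%d", i), length(groups[[i]])), groups[[i]])
  }))
  res[ct$tip.label]
}

#' Write a tree with supports to Newick
#' @param tree an `ape::phylo` (supports, if any, in `node.label`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (!is.null(tree$node.label) && is.numeric(tree$node.label)) {
    lab <- round(tree$node.label, 1)
    tree$node.label <- ifelse(is.na(lab), "", as.character(lab))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
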