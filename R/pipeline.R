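# End-to-end orchestration: from input files to the full set of result
# tables (haplotype table, trees, clade summary, diversity, Phi-ST, AMOVA,
# geographic indices, correlations and GLM/AIC comparison).

read_cohort_table <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("population", "cohort") %in% names(df))) {
      abort("cohort table needs columns population, cohort", "config_error")
    }
    return(stats::setNames(df$cohort, df$population))
  }
  x
}

#' Run the full phylogeography pipeline
#'
#' Executes every stage in order and writes one TSV/Newick/JSON artifact per
#' stage under `out_dir`: haplotype table; NJ haplotype tree, its
#' support-collapsed version and the clade partition; within/between clade
#' distance summary; per-population diversity; pairwise Phi-ST with
#' permutation p-values; AMOVA over populations (and over cohorts when a
#' cohort map is given); UPGMA population tree on net distances; geographic
#' index table; per-site correlation profiles; GLM/AIC model comparison; and
#' a machine-readable run log. Any stage failure aborts with a stage-tagged
#' error; artifacts already written are retained.
#'
#' @param alignment path to the aligned per-sample FASTA.
#' @param metadata path to the sample metadata TSV.
#' @param rivers path to the river GeoJSON (set `NULL` to skip the
#'   geographic stages).
#' @param cohorts named vector population -> cohort, or path to a TSV with
#'   columns population, cohort; `NULL` skips cohort analyses.
#' @param out_dir output directory.
#' @param n_boot bootstrap replicates for the haplotype tree.
#' @param collapse_threshold percent support below which branches collapse.
#' @param n_perm permutations for the Phi-ST tests.
#' @param tree_metric distance used for tree building (`"tn93"` default).
#' @param exclude_population optional population excluded in a second
#'   correlation/model-selection pass.
#' @param seed master seed for all stochastic stages.
#' @return (invisibly) a list with every computed object and `paths`.
#' @export
run_pipeline <- function(alignment, metadata, rivers = NULL, cohorts = NULL,
                         out_dir, n_boot = 1000L, collapse_threshold = 70,
                         n_perm = 1023L, tree_metric = c("tn93", "diff_count"),
                         exclude_population = NULL, seed = 1L) {
  tree_metric <- match.arg(tree_metric)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)),
            "pipeline_error")
    })
  }
  paths <- list()
  out <- function(f) file.path(out_dir, f)

  aln <- stage("read", read_alignment(alignment))
  meta <- stage("read", read_metadata(metadata))
  cohorts <- stage("read", read_cohort_table(cohorts))
  map <- NULL
  if (!is.null(rivers)) map <- stage("read", read_rivers(rivers))

  tab <- stage("haplotypes", collapse_haplotypes(aln, meta))
  paths$haplotype_table <- write_hap_table(tab, out("haplotype_table.tsv"))
  spec <- stage("haplotypes", locality_specificity(tab))

  haln <- hap_alignment(tab)
  dcount <- stage("distances", pairwise_diff_matrix(haln, strict = TRUE))
  dtree <- if (tree_metric == "tn93") {
    stage("distances", tn93_distance_matrix(haln, strict = TRUE))
  } else dcount

  btree <- stage("tree", bootstrap_support(haln, n_reps = n_boot, seed = seed,
                                           metric = tree_metric))
  paths$nj_tree <- write_tree(btree, out("nj_tree.nwk"))
  ctree <- stage("tree", collapse_low_support(btree, collapse_threshold))
  paths$nj_tree_collapsed <- write_tree(ctree, out("nj_tree_collapsed.nwk"))
  clades <- stage("tree", extract_clades(btree, collapse_threshold))
  utils::write.table(
    data.frame(haplotype_id = names(clades), clade = unname(clades)),
    out("clades.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths$clades <- out("clades.tsv")

  csum <- stage("clade_distances", clade_distance_summary(dcount, clades))
  cd <- data.frame(clade_a = rownames(csum$between)[row(csum$between)][upper.tri(csum$between)],
                   clade_b = colnames(csum$between)[col(csum$between)][upper.tri(csum$between)],
                   between = csum$between[upper.tri(csum$between)],
                   net = csum$net[upper.tri(csum$net)])
  utils::write.table(cd, out("clade_distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$clade_distances <- out("clade_distances.tsv")

  div <- stage("diversity", diversity_table(tab, dcount, haln))
  utils::write.table(div, out("diversity.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$diversity <- out("diversity.tsv")

  fst <- stage("fst", pairwise_fst(tab, dcount, n_perm = n_perm, seed = seed))
  fst_out <- unclass(fst$fst)
  fst_out[upper.tri(fst_out)] <- fst$p[upper.tri(fst$p)]
  utils::write.table(
    data.frame(population = rownames(fst_out), fst_out, check.names = FALSE),
    out("fst.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths$fst <- out("fst.tsv")

  am_pop <- stage("amova", amova(tab, dcount))
  am_rows <- cbind(grouping = "populations", am_pop$table)
  am_coh <- NULL
  if (!is.null(cohorts)) {
    am_coh <- stage("amova", amova(tab, dcount, strata = cohorts))
    am_rows <- rbind(am_rows, cbind(grouping = "cohorts", am_coh$table))
  }
  utils::write.table(am_rows, out("amova.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$amova <- out("amova.tsv")

  net <- stage("net_distance", net_population_distance(tab, dcount))
  upgma <- stage("net_distance", build_upgma(net))
  paths$upgma <- write_tree(upgma, out("upgma_populations.nwk"))

  geo <- pairwise <- profiles <- models <- NULL
  if (!is.null(map)) {
    sites <- stage("geography", population_centroids(meta))
    geo <- stage("geography", geo_index_table(sites, map))
    utils::write.table(geo, out("geo_indices.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$geo_indices <- out("geo_indices.tsv")

    pairwise <- stage("barriers", make_pairwise_table(fst, geo, cohorts))
    utils::write.table(pairwise, out("pairwise_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$pairwise_table <- out("pairwise_table.tsv")

    profiles <- stage("barriers", {
      res <- lapply(sites$population, function(s) {
        pr <- cbind(site = s, excluded = "none",
                    site_correlation_profile(pairwise, s))
        if (!is.null(exclude_population) && s != exclude_population) {
          pr <- rbind(pr, cbind(site = s, excluded = exclude_population,
                                site_correlation_profile(pairwise, s,
                                                         exclude_population)))
        }
        pr
      })
      do.call(rbind, res)
    })
    utils::write.table(profiles, out("correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$correlations <- out("correlations.tsv")

    models <- stage("barriers", {
      mc <- model_comparison(pairwise)
      rk <- cbind(excluded = "none", mc$ranking)
      if (!is.null(exclude_population)) {
        mc2 <- model_comparison(pairwise, exclude = exclude_population)
        rk <- rbind(rk, cbind(excluded = exclude_population, mc2$ranking))
      }
      rk
    })
    utils::write.table(models, out("model_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$model_comparison <- out("model_comparison.tsv")
  }

  log <- list(
    package_version = as.character(utils::packageVersion("mtphylogeo")),
    seed = seed,
    parameters = list(n_boot = n_boot, collapse_threshold = collapse_threshold,
                      n_perm = n_perm, tree_metric = tree_metric,
                      exclude_population = exclude_population),
    inputs = list(
      alignment = unname(tools::md5sum(alignment)),
      metadata = unname(tools::md5sum(metadata)),
      rivers = if (is.null(rivers)) NULL else unname(tools::md5sum(rivers))),
    n_samples = sum(tab$counts),
    n_haplotypes = length(tab$haplotype_id),
    n_clades = length(unique(clades)),
    bootstrap_valid = attr(btree, "n_valid_reps"),
    locality_specific = spec$n_specific,
    locality_shared = spec$n_shared
  )
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE, digits = NA)
  paths$run_log <- out("run_log.json")

  invisible(list(
    haplotypes = tab, specificity = spec, diff_matrix = dcount,
    tree = btree, collapsed_tree = ctree, clades = clades,
    clade_summary = csum, diversity = div, fst = fst,
    amova_populations = am_pop, amova_cohorts = am_coh, net = net,
    upgma = upgma, geo = geo, pairwise = pairwise, profiles = profiles,
    models = models, paths = paths
  ))
}
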