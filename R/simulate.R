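# Synthetic landscape-genetics generator: clade-structured haplotype
# sequences, river-structured population frequencies, and sampled datasets
# in exactly the file dialects the readers consume.
#
# The generator is a phenomenological stand-in for coalescent migration
# models: haplotype frequencies follow a Dirichlet whose concentration for a
# haplotype decays exponentially with the effective distance between a
# population and the haplotype's home population, where effective distance
# is straight-line km plus a river-crossing penalty. It is fast, has
# closed-form expectations, and exposes the qualitative features the
# pipeline is meant to detect (deep clades, locality-specific haplotypes,
# isolation by distance, and optional riverine barriers).

#' Default simulated populations and rivers
#'
#' Seven study-like populations (sample sizes 16, 7, 35, 7, 37, 18, 16 in a
#' west/central/east cohort layout) and a three-river landscape (two large
#' rivers, one small). Coordinates are synthetic stand-ins.
#' @return `default_populations()`: a data.frame (name, cohort, latitude,
#'   longitude, n); `default_rivers()`: a [river_map()].
#' @export
default_populations <- function() {
  # seven study-like populations; coordinates are synthetic stand-ins placed
  # in a west-to-east band, sample sizes 16, 7, 35, 7, 37, 18, 16
  data.frame(
    name = c("Malebo", "LacTumba", "Lomako", "Salonga", "Wamba", "Iyondji", "TL2"),
    cohort = c("west", "west", "central", "central", "central", "central", "east"),
    latitude = c(-2.53, -0.90, 0.83, -2.00, 0.18, -0.05, -2.80),
    longitude = c(16.42, 18.00, 21.08, 21.30, 22.48, 22.80, 25.00),
    n = c(16L, 7L, 35L, 7L, 37L, 18L, 16L),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_populations
#' @export
default_rivers <- function() {
  river_map(list(
    list(name = "east_barrier", width_class = "large",
         coords = cbind(c(24.20, 24.30, 24.60, 25.00, 25.50),
                        c(0.80, -1.50, -3.50, -5.00, -6.00)),
         headwater = "last"),
    list(name = "west_barrier", width_class = "large",
         coords = cbind(c(20.00, 19.70, 19.30, 19.00),
                        c(1.50, -0.80, -2.50, -4.00)),
         headwater = "last"),
    list(name = "minor_stream", width_class = "small",
         coords = cbind(c(21.5, 21.8), c(1.0, -1.0)),
         headwater = "last")
  ))
}

#' Simulation configuration
#'
#' Parameters of the synthetic generator. Defaults emulate the magnitudes of
#' a well-sampled mtDNA control-region survey: a 1121-site alignment, 54
#' haplotypes in 6 deeply diverged clades (between-clade Poisson mutation
#' count `lambda_b = 15` per clade ancestor, within-clade `lambda_w = 4` per
#' haplotype, giving an expected between/within mean-difference ratio of
#' about `(lambda_b + lambda_w) / lambda_w = 4.75`), and 7 populations of
#' 16, 7, 35, 7, 37, 18 and 16 samples on a west-to-east landscape with two
#' large rivers and one small one.
#'
#' @param L alignment length (sites).
#' @param n_clades number of clades.
#' @param haps_per_clade haplotypes per clade.
#' @param lambda_b expected mutations separating a clade ancestor from the
#'   root.
#' @param lambda_w expected private mutations per haplotype.
#' @param populations data.frame: name, cohort, latitude, longitude, n.
#' @param rivers a [river_map()].
#' @param beta riverine barrier strength: km of effective distance added per
#'   large-river crossing (`beta = 0` makes rivers genetically inert).
#' @param sigma distance-decay scale (km) of haplotype sharing.
#' @param alpha0 Dirichlet concentration of a haplotype at its home
#'   population.
#' @param clade_homes optional named vector clade label -> population name;
#'   sampled uniformly when `NULL`.
#' @param jitter_sd sd (degrees) of sample-coordinate jitter about the
#'   population centre.
#' @param finite_sites allow recurrent mutation (sites drawn with
#'   replacement across branches) instead of the default infinite-sites
#'   model.
#' @param ts_bias transition/transversion preference of each substitution
#'   (1 = unbiased; larger values favour transitions, for TN93
#'   distance-estimator tests).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(L = 1121L, n_clades = 6L, haps_per_clade = 9L,
                       lambda_b = 15, lambda_w = 4,
                       populations = default_populations(),
                       rivers = default_rivers(),
                       beta = 0, sigma = 150, alpha0 = 0.5,
                       clade_homes = NULL, jitter_sd = 0.05,
                       finite_sites = FALSE, ts_bias = 1) {
  if (lambda_b <= lambda_w || lambda_w < 0) {
    abort("need lambda_b > lambda_w >= 0", "config_error")
  }
  if (beta < 0) abort("beta must be >= 0", "config_error")
  if (n_clades * (lambda_b + haps_per_clade * lambda_w) > 0.8 * L) {
    abort("requested mutation counts too large for alignment length",
          "config_error")
  }
  drop <- populations$n == 0L
  if (any(drop)) {
    warning(sprintf("excluding population(s) with 0 samples: %s",
                    paste(populations$name[drop], collapse = ", ")))
    populations <- populations[!drop, , drop = FALSE]
  }
  structure(list(L = L, n_clades = n_clades, haps_per_clade = haps_per_clade,
                 lambda_b = lambda_b, lambda_w = lambda_w,
                 populations = populations, rivers = rivers,
                 beta = beta, sigma = sigma, alpha0 = alpha0,
                 clade_homes = clade_homes, jitter_sd = jitter_sd,
                 finite_sites = finite_sites, ts_bias = ts_bias),
            class = "sim_config")
}

# substitute at the given sites; ts_bias > 1 favours transitions (A<->G,
# C<->T) over each transversion, emulating the bias the TN93 model corrects
mutate_sites <- function(seq_vec, sites, ts_bias = 1) {
  bases <- c("A", "C", "G", "T")
  partner <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in sites) {
    alt <- setdiff(bases, seq_vec[s])
    w <- ifelse(alt == partner[[seq_vec[s]]], ts_bias, 1)
    seq_vec[s] <- sample(alt, 1L, prob = w)
  }
  seq_vec
}

#' Simulate clade-structured haplotype sequences
#'
#' A random root sequence; each clade ancestor carries `Poisson(lambda_b)`
#' substitutions and each haplotype a further `Poisson(lambda_w)` private
#' substitutions. Under the default infinite-sites model every substitution
#' hits a previously unmutated site, so the haplotype genealogy is exactly
#' additive (no homoplasy) and expectations are analytic: expected
#' within-clade pairwise difference `2 lambda_w`, between-clade
#' `2 lambda_b + 2 lambda_w`. With `finite_sites = TRUE` mutation sites are
#' drawn with replacement across branches, allowing recurrent mutation.
#' Colliding (identical) haplotypes are regenerated; when `lambda_w = 0`
#' within-clade duplicates are structural and are kept.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed.
#' @return list: `aln` (an [alignment()] with ids `H001, ...`) and `clades`
#'   (named vector haplotype -> clade label `K1, ...`).
#' @export
simulate_haplotypes <- function(cfg, seed = 1L) {
  set.seed(split_seed(seed, "haplotypes"))
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, cfg$L, replace = TRUE)
  n_h <- cfg$n_clades * cfg$haps_per_clade
  pool <- sample.int(cfg$L) # site-consumption order (infinite-sites model)
  used <- 0L
  draw_sites <- function(k) {
    if (cfg$finite_sites) return(sample.int(cfg$L, min(k, cfg$L)))
    if (used + k > cfg$L) {
      abort("requested mutations exceed alignment length", "config_error")
    }
    s <- pool[seq_len(k) + used]
    used <<- used + k
    s
  }
  mats <- matrix(NA_character_, n_h, cfg$L)
  clade_lab <- character(n_h)
  row <- 0L
  seen <- character(0)
  for (cl in seq_len(cfg$n_clades)) {
    anc <- mutate_sites(root, draw_sites(stats::rpois(1L, cfg$lambda_b)),
                        cfg$ts_bias)
    for (h in seq_len(cfg$haps_per_clade)) {
      row <- row + 1L
      for (try in seq_len(100L)) {
        hap <- mutate_sites(anc, draw_sites(stats::rpois(1L, cfg$lambda_w)),
                            cfg$ts_bias)
        key <- paste(hap, collapse = "")
        if (!key %in% seen || cfg$lambda_w == 0) break
      }
      seen <- c(seen, key)
      mats[row, ] <- hap
      clade_lab[row] <- sprintf("K%d", cl)
    }
  }
  ids <- sprintf("H%03d", seq_len(n_h))
  rownames(mats) <- ids
  list(aln = alignment(mats), clades = stats::setNames(clade_lab, ids))
}

#' Effective inter-population distances of a simulated landscape
#'
#' `d_eff = straight-line km + beta * large-river crossings`.
#'
#' @param cfg a [sim_config()].
#' @return symmetric matrix over population names.
#' @export
effective_distances <- function(cfg) {
  pops <- cfg$populations
  k <- nrow(pops)
  d <- matrix(0, k, k, dimnames = list(pops$name, pops$name))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      a <- c(pops$latitude[i], pops$longitude[i])
      b <- c(pops$latitude[j], pops$longitude[j])
      d[i, j] <- d[j, i] <- straight_distance(a, b) +
        cfg$beta * tributary_crossings(a, b, cfg$rivers)
    }
  }
  d
}

#' Simulate haplotype frequencies per population
#'
#' Each population's frequency vector is Dirichlet with concentration
#' `alpha0 * exp(-d_eff(pop, home(haplotype)) / sigma)`, where a haplotype's
#' home is its clade's home population.
#'
#' @param cfg a [sim_config()].
#' @param clades named vector haplotype -> clade (from
#'   [simulate_haplotypes()]).
#' @param seed integer master seed.
#' @return list: `freq` (haplotype x population matrix, columns sum to 1),
#'   `d_eff`, `homes` (named vector clade -> population).
#' @export
simulate_population_frequencies <- function(cfg, clades, seed = 1L) {
  set.seed(split_seed(seed, "frequencies"))
  d_eff <- effective_distances(cfg)
  pops <- cfg$populations$name
  clade_ids <- sort(unique(clades))
  homes <- cfg$clade_homes
  if (is.null(homes)) {
    homes <- stats::setNames(sample(pops, length(clade_ids), replace = TRUE),
                             clade_ids)
  }
  if (!all(clade_ids %in% names(homes))) {
    abort("clade_homes must cover every clade", "config_error")
  }
  haps <- names(clades)
  freq <- matrix(0, length(haps), length(pops),
                 dimnames = list(haps, pops))
  for (p in pops) {
    alpha <- cfg$alpha0 * exp(-d_eff[p, homes[clades[haps]]] / cfg$sigma)
    draw <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(draw) <= 0) {
      draw <- as.numeric(alpha == max(alpha))
    }
    freq[, p] <- draw / sum(draw)
  }
  list(freq = freq, d_eff = d_eff, homes = homes)
}

#' Simulate a full dataset in memory
#'
#' Draws per-sample haplotypes from the population frequency vectors and
#' assembles the per-sample alignment, metadata, river map and a truth
#' record for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed driving every stage.
#' @return list: `aln` (per-sample [alignment()]), `meta` (metadata
#'   data.frame), `rivers`, `cohorts` (named vector), and `truth` (list:
#'   haplotypes alignment, clades, freq, d_eff, homes, sample_haplotypes).
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  hp <- simulate_haplotypes(cfg, seed)
  fr <- simulate_population_frequencies(cfg, hp$clades, seed)
  set.seed(split_seed(seed, "samples"))
  pops <- cfg$populations
  hap_strings <- aln_strings(hp$aln)
  sample_rows <- list()
  seqs <- character(0)
  s <- 0L
  for (i in seq_len(nrow(pops))) {
    nm <- pops$name[i]
    hap_draw <- sample(names(hap_strings), pops$n[i], replace = TRUE,
                       prob = fr$freq[, nm])
    for (h in hap_draw) {
      s <- s + 1L
      sid <- sprintf("S%03d", s)
      seqs[sid] <- hap_strings[[h]]
      sample_rows[[s]] <- data.frame(
        sample_id = sid, population = nm,
        sex = sample(c("male", "female", "unknown"), 1L,
                     prob = c(0.4, 0.4, 0.2)),
        latitude = pops$latitude[i] + stats::rnorm(1L, 0, cfg$jitter_sd),
        longitude = pops$longitude[i] + stats::rnorm(1L, 0, cfg$jitter_sd),
        haplotype = h, stringsAsFactors = FALSE)
    }
  }
  meta_full <- do.call(rbind, sample_rows)
  meta <- meta_full[, c("sample_id", "population", "sex", "latitude",
                        "longitude")]
  cohorts <- stats::setNames(pops$cohort, pops$name)
  list(aln = alignment(seqs), meta = meta, rivers = cfg$rivers,
       cohorts = cohorts,
       truth = list(haplotypes = hp$aln, clades = hp$clades, freq = fr$freq,
                    d_eff = fr$d_eff, homes = fr$homes,
                    sample_haplotypes = stats::setNames(meta_full$haplotype,
                                                        meta_full$sample_id)))
}

#' Simulate a dataset and write it to disk
#'
#' Writes `samples.fasta`, `metadata.tsv`, `rivers.geojson`, `cohorts.tsv`
#' and a JSON truth record, in exactly the dialects the readers consume.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed.
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the dataset (as from [simulate_dataset()])
#'   and `paths`.
#' @export
simulate_samples <- function(cfg, seed = 1L, dir) {
  ds <- simulate_dataset(cfg, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    alignment = file.path(dir, "samples.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    rivers = file.path(dir, "rivers.geojson"),
    cohorts = file.path(dir, "cohorts.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_alignment(ds$aln, paths$alignment)
  write_metadata(ds$meta, paths$metadata)
  write_rivers(ds$rivers, paths$rivers)
  utils::write.table(
    data.frame(population = names(ds$cohorts), cohort = unname(ds$cohorts)),
    paths$cohorts, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    seed = seed,
    clades = as.list(ds$truth$clades),
    homes = as.list(ds$truth$homes),
    freq = apply(ds$truth$freq, 2L, identity, simplify = FALSE),
    haplotype_sequences = as.list(aln_strings(ds$truth$haplotypes)),
    sample_haplotypes = as.list(ds$truth$sample_haplotypes)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, paths = paths))
}
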