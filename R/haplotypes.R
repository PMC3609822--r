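# Collapsing per-sample sequences into haplotypes and summarising their
# geographic distribution.

#' Collapse per-sample sequences into haplotypes
#'
#' Samples with byte-identical aligned sequences share one haplotype.
#' Identity is evaluated site by site including gaps, and `N` matches only
#' itself, so two samples that differ only at an ambiguous site are kept as
#' distinct haplotypes (any residual ambiguity is expected to have been
#' resolved upstream). Haplotype ids `H001, H002, ...` are assigned by order
#' of first appearance in the alignment, with lexicographic sequence order
#' breaking ties among simultaneous first appearances.
#'
#' @param aln an [alignment()] of per-sample sequences.
#' @param meta metadata `data.frame` covering every alignment id.
#' @return an object of class `"hap_table"` with elements:
#'   `haplotype_id`, `sequences` (named character vector of representative
#'   sequences), `counts` (haplotype x population integer matrix),
#'   `counts_sex` (haplotype x population x sex array) and `sample_map`
#'   (named vector sample id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, meta) {
  missing_ids <- setdiff(aln$ids, meta$sample_id)
  if (length(missing_ids)) {
    abort(sprintf("alignment id(s) absent from metadata: %s",
                  paste(utils::head(missing_ids, 3L), collapse = ", ")),
          "consistency_error")
  }
  seqs <- aln_strings(aln)
  first_idx <- match(unique(seqs), seqs)
  # order of first appearance, lexicographic among equal first positions
  ord <- order(first_idx, seqs[first_idx])
  reps <- seqs[first_idx][ord]
  hap_ids <- sprintf("H%03d", seq_along(reps))
  names(reps) <- hap_ids
  sample_map <- hap_ids[match(seqs, reps)]
  names(sample_map) <- aln$ids

  meta_row <- match(aln$ids, meta$sample_id)
  pops <- sort(unique(meta$population[meta_row]))
  sexes <- c("male", "female", "unknown")
  counts <- table(factor(sample_map, levels = hap_ids),
                  factor(meta$population[meta_row], levels = pops))
  counts_sex <- table(factor(sample_map, levels = hap_ids),
                      factor(meta$population[meta_row], levels = pops),
                      factor(meta$sex[meta_row], levels = sexes))
  structure(list(
    haplotype_id = hap_ids,
    sequences = reps,
    counts = unclass(as.matrix(counts)),
    counts_sex = unclass(counts_sex),
    sample_map = sample_map
  ), class = "hap_table")
}

#' Build a haplotype table directly from counts
#'
#' @param sequences named character vector (haplotype id -> sequence);
#'   sequences must be distinct.
#' @param counts haplotype x population matrix of sample counts.
#' @return a `"hap_table"` object (without sex stratification or sample map).
#' @export
hap_table <- function(sequences, counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- names(sequences)
  stopifnot(identical(rownames(counts), names(sequences)))
  if (anyDuplicated(sequences)) abort("duplicate haplotype sequences", "input_error")
  structure(list(
    haplotype_id = names(sequences),
    sequences = sequences,
    counts = counts,
    counts_sex = NULL,
    sample_map = NULL
  ), class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d haplotypes, %d populations, %d samples\n",
              length(x$haplotype_id), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Alignment of the representative haplotype sequences
#' @param table a `"hap_table"`.
#' @return an [alignment()] of one sequence per haplotype.
#' @export
hap_alignment <- function(table) alignment(table$sequences)

#' Locality specificity of haplotypes
#'
#' Counts, for every haplotype, how many populations carry it, and tallies
#' locality-specific (exactly one carrier population) against shared
#' haplotypes; also reports, per population, the proportion of its
#' haplotypes that are shared with at least one other population.
#'
#' @param table a `"hap_table"`.
#' @return a list with `per_haplotype` (data.frame: haplotype_id,
#'   n_populations, specific), `n_specific`, `n_shared`, and `per_population`
#'   (data.frame: population, n_haplotypes, n_shared, prop_shared).
#' @export
locality_specificity <- function(table) {
  if (length(table$haplotype_id) == 0L) abort("empty haplotype table", "input_error")
  present <- table$counts > 0
  n_pops <- rowSums(present)
  per_hap <- data.frame(
    haplotype_id = table$haplotype_id,
    n_populations = as.integer(n_pops),
    specific = n_pops == 1L,
    stringsAsFactors = FALSE
  )
  shared_hap <- n_pops > 1L
  per_pop <- data.frame(
    population = colnames(table$counts),
    n_haplotypes = colSums(present),
    n_shared = colSums(present & shared_hap),
    stringsAsFactors = FALSE
  )
  per_pop$prop_shared <- ifelse(per_pop$n_haplotypes > 0,
                                per_pop$n_shared / per_pop$n_haplotypes, NA_real_)
  rownames(per_pop) <- NULL
  list(per_haplotype = per_hap,
       n_specific = sum(per_hap$specific),
       n_shared = sum(!per_hap$specific),
       per_population = per_pop)
}

#' Write a haplotype table to TSV
#'
#' Columns: `haplotype_id`, `sequence`, then one count column per population.
#'
#' @param table a `"hap_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hap_table <- function(table, path) {
  df <- data.frame(haplotype_id = table$haplotype_id,
                   sequence = unname(table$sequences),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype table written by [write_hap_table()]
#' @param path path to the TSV file.
#' @return a `"hap_table"`.
#' @export
read_hap_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  seqs <- df$sequence
  names(seqs) <- df$haplotype_id
  counts <- as.matrix(df[, setdiff(names(df), c("haplotype_id", "sequence")),
                         drop = FALSE])
  rownames(counts) <- df$haplotype_id
  hap_table(seqs, counts)
}
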