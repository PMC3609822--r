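# Reading and validating aligned sequences and sample metadata.

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct an aligned sequence set
#'
#' An alignment is stored as a character matrix (rows = sequences, columns =
#' sites) over the alphabet `A, C, G, T, -` (gap) and `N` (ambiguous). All
#' sequences must have the same length and unique identifiers.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix with row names.
#' @return an object of class `"aln"` with elements `mat` (character matrix),
#'   `ids` and `L` (number of sites).
#' @export
alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(rownames(mat))) abort("alignment matrix needs row names", "input_error")
  } else {
    if (length(seqs) == 0L) abort("empty alignment", "input_error")
    ids <- names(seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
      abort("all sequences need identifiers", "input_error")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[lens != lens[1L]][1L]
      abort(sprintf("unequal sequence lengths: '%s' has %d sites, expected %d",
                    bad, nchar(seqs[[bad]]), lens[1L]), "alignment_error")
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  mat[] <- toupper(mat)
  if (anyDuplicated(rownames(mat))) {
    abort(sprintf("duplicated sequence id '%s'",
                  rownames(mat)[duplicated(rownames(mat))][1L]), "input_error")
  }
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad)) {
    abort(sprintf("characters outside alphabet {A,C,G,T,-,N}: %s",
                  paste(bad, collapse = ", ")), "input_error")
  }
  structure(list(mat = mat, ids = rownames(mat), L = ncol(mat)), class = "aln")
}

#' Read an aligned FASTA file
#'
#' Sequences must be pre-aligned (equal length once gaps are included); the
#' package does not perform alignment itself.
#'
#' @param path path to a FASTA file.
#' @return an [alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "input_error")
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0L) {
    abort("empty FASTA file", "input_error")
  }
  seqs <- vapply(as.character(recs), function(x) paste(toupper(x), collapse = ""),
                 character(1L))
  names(seqs) <- names(recs)
  alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln an [alignment()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", aln$ids), aln_strings(aln)))
  writeLines(lines, path)
  invisible(path)
}

#' Sequences of an alignment as strings
#' @param aln an [alignment()] object.
#' @return named character vector.
#' @export
aln_strings <- function(aln) {
  out <- apply(aln$mat, 1L, paste, collapse = "")
  names(out) <- aln$ids
  out
}

#' Subset an alignment by sequence id or site index
#' @param aln an [alignment()] object.
#' @param ids sequence ids (or indices) to keep.
#' @param sites optional site index vector (with replacement allowed, for
#'   bootstrap resampling).
#' @return an [alignment()] object.
#' @export
aln_subset <- function(aln, ids = aln$ids, sites = NULL) {
  mat <- aln$mat[ids, , drop = FALSE]
  if (!is.null(sites)) mat <- mat[, sites, drop = FALSE]
  structure(list(mat = mat, ids = rownames(mat), L = ncol(mat)), class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("Aligned sequence set: %d sequences x %d sites\n",
              length(x$ids), x$L))
  invisible(x)
}

#' Read sample metadata
#'
#' Expects a UTF-8 tab-separated file with a header row containing at least
#' `sample_id` and `population`; optional columns `sex` (male/female/unknown;
#' empty values become `"unknown"`), `latitude` and `longitude` (decimal
#' degrees WGS84). Lines starting with `#` are ignored.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with columns `sample_id`, `population`, `sex`,
#'   `latitude`, `longitude`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "input_error")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("metadata missing required columns: %s",
                  paste(miss, collapse = ", ")), "input_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicated sample_id '%s'",
                  df$sample_id[duplicated(df$sample_id)][1L]), "input_error")
  }
  if (any(is.na(df$population) | df$population == "")) {
    abort("empty population label", "input_error")
  }
  sex <- if ("sex" %in% names(df)) tolower(df$sex) else rep("", nrow(df))
  sex[is.na(sex) | sex == ""] <- "unknown"
  if (!all(sex %in% c("male", "female", "unknown"))) {
    abort("sex must be male, female, unknown or empty", "input_error")
  }
  parse_coord <- function(col, lo, hi, what) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & raw != "" & is.na(out)
    if (any(bad)) abort(sprintf("malformed %s '%s'", what, raw[bad][1L]), "input_error")
    if (any(out < lo | out > hi, na.rm = TRUE)) {
      abort(sprintf("%s out of range [%g, %g]", what, lo, hi), "input_error")
    }
    out
  }
  out <- data.frame(
    sample_id = df$sample_id,
    population = df$population,
    sex = sex,
    latitude = parse_coord("latitude", -90, 90, "latitude"),
    longitude = parse_coord("longitude", -180, 180, "longitude"),
    stringsAsFactors = FALSE
  )
  n_missing <- sum(is.na(out$latitude) | is.na(out$longitude))
  if (n_missing > 0L) {
    message(sprintf("%d sample(s) without coordinates", n_missing))
  }
  out
}

#' Write sample metadata to TSV
#' @param meta a metadata `data.frame` as returned by [read_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
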