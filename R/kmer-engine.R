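#' k-mer counting configuration
#'
#' Parameters of the canonical k-mer counting stage. `k` must be odd so that
#' no k-mer equals its own reverse complement and the canonical form is
#' unique. `min_count` is the within-accession multiplicity floor: counts
#' below it are discarded immediately, which suppresses sequencing-error
#' k-mers in raw-read input. For assembled (error-free, single-copy)
#' sequences use `min_count = 1`, since every genomic k-mer occurs once.
#'
#' @param k k-mer length in bases; odd, >= 3. Default 51.
#' @param min_count minimum within-accession multiplicity; >= 1. Default 2.
#' @return An object of class `kmer_config`.
#' @export
#' @examples
#' kmer_config(k = 7, min_count = 1)
kmer_config <- function(k = 51, min_count = 2) {
  .check_scalar(k, "k", lower = 3)
  .check_scalar(min_count, "min_count", lower = 1)
  if (k %% 2 != 1) stop("'k' must be odd so the canonical form is unique")
  structure(list(k = as.integer(k), min_count = as.integer(min_count)),
            class = "kmer_config")
}

#' Canonicalize k-mers
#'
#' Returns, for each input k-mer, the lexicographic minimum of the k-mer and
#' its reverse complement. k-mers containing characters outside ACGT are not
#' errors: they come back as `NA` and are tallied in the `"n_skipped"`
#' attribute, mirroring how the counting stage skips N-spanning windows.
#'
#' @param kmers character vector of k-mers, all of length `k`.
#' @param k k-mer length; defaults to the length of the first k-mer.
#' @return Character vector of canonical forms (`NA` where skipped), with
#'   attribute `n_skipped`.
#' @export
#' @examples
#' canonicalize(c("CGT", "AAA"))  # "ACG", "AAA"
canonicalize <- function(kmers, k = nchar(kmers[1])) {
  res <- canonicalize_cpp(as.character(kmers), as.integer(k))
  structure(res$kmers, n_skipped = res$n_skipped)
}

#' Count canonical k-mers in one accession's sequences
#'
#' Multiplicity is accumulated over canonical forms across all records
#' (contigs or reads). Windows spanning a non-ACGT character are skipped and
#' counted in `n_skipped`. Members are the canonical k-mers whose total count
#' reaches `config$min_count`.
#'
#' @param seqs character vector of uppercase DNA sequences.
#' @param config a [kmer_config()].
#' @param accession_id optional accession identifier carried on the result.
#' @return An object of class `kmer_set`: list with `kmers` (sorted canonical
#'   k-mer strings), `k`, `accession_id`, `n_skipped`, `n_distinct`.
#' @export
count_kmers <- function(seqs, config = kmer_config(), accession_id = NULL) {
  stopifnot(inherits(config, "kmer_config"))
  res <- count_kmers_cpp(as.character(seqs), config$k, config$min_count)
  structure(list(kmers = res$kmers, k = config$k,
                 accession_id = accession_id,
                 n_skipped = res$n_skipped, n_distinct = res$n_distinct),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> %s: %d canonical %d-mers (%.0f windows skipped)\n",
              if (is.null(x$accession_id)) "?" else x$accession_id,
              length(x$kmers), x$k, x$n_skipped))
  invisible(x)
}

.new_kmer_matrix <- function(kmers, presence, accessions, k) {
  dimnames(presence) <- NULL
  structure(list(kmers = kmers, presence = presence,
                 accessions = accessions, k = as.integer(k)),
            class = "kmer_matrix")
}

#' Build a k-mer presence/absence matrix from per-accession k-mer sets
#'
#' Rows are restricted to k-mers whose occupancy c (number of accessions
#' containing them) satisfies 2 <= c <= n - 2: k-mers in fewer than two
#' accessions or in all but one are removed, and k-mers present in every
#' accession are removed as well since they carry no variance (see the
#' methods vignette). Rows are ordered by k-mer byte order, which coincides
#' with the order of the 2-bit encoding.
#'
#' @param kmersets list of [count_kmers()] results, one per accession.
#' @param accessions accession ids; defaults to the ids carried by the sets.
#' @return An object of class `kmer_matrix`: `kmers` (character), `presence`
#'   (raw 0/1 matrix, one row per k-mer, one column per accession),
#'   `accessions`, `k`.
#' @export
build_matrix <- function(kmersets, accessions = NULL) {
  if (is.null(accessions))
    accessions <- vapply(kmersets, function(s) {
      if (is.null(s$accession_id)) NA_character_ else s$accession_id
    }, character(1))
  n <- length(kmersets)
  if (n < 4L) stop("need >= 4 accessions; the occupancy filter is degenerate below this")
  if (anyNA(accessions) || anyDuplicated(accessions))
    stop("accession ids must be present and unique")
  k <- kmersets[[1]]$k
  all_kmers <- sort(unique(unlist(lapply(kmersets, `[[`, "kmers"))),
                    method = "radix")
  pres <- matrix(as.raw(0L), nrow = length(all_kmers), ncol = n)
  for (j in seq_len(n))
    pres[match(kmersets[[j]]$kmers, all_kmers), j] <- as.raw(1L)
  occ <- row_occupancy_cpp(pres)
  keep <- occ >= 2L & occ <= n - 2L
  .new_kmer_matrix(all_kmers[keep], pres[keep, , drop = FALSE], accessions, k)
}

#' Build a k-mer matrix directly from sequences (fast path)
#'
#' Equivalent to [count_kmers()] per accession followed by [build_matrix()],
#' but streamed in compiled code so panel-scale inputs (tens of accessions at
#' megabase genome size) stay within desk-scale memory.
#'
#' @param seq_list named list; one character vector of sequences per accession.
#' @param config a [kmer_config()].
#' @return A `kmer_matrix` (see [build_matrix()]).
#' @export
kmer_matrix_from_sequences <- function(seq_list, config = kmer_config()) {
  stopifnot(inherits(config, "kmer_config"))
  if (length(seq_list) < 4L) stop("need >= 4 accessions")
  ids <- names(seq_list)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("seq_list must be named with unique accession ids")
  res <- kmer_matrix_cpp(lapply(seq_list, as.character),
                         config$k, config$min_count)
  .new_kmer_matrix(res$kmers, res$presence, ids, config$k)
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf("<kmer_matrix> %d x %d (k = %d)\n", nrow(x$presence),
              length(x$accessions), x$k))
  invisible(x)
}

#' @export
dim.kmer_matrix <- function(x) dim(x$presence)

#' Row occupancy of a k-mer matrix
#' @param matrix a `kmer_matrix`.
#' @return Integer vector: per row, the number of accessions with the k-mer.
#' @export
occupancy <- function(matrix) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  row_occupancy_cpp(matrix$presence)
}

#' Subset a k-mer matrix by row and/or accession
#'
#' Internal-style helper used by the sampling, bootstrap and GWAS stages.
#' No refiltering is applied: row/column subsetting is positional.
#'
#' @param matrix a `kmer_matrix`.
#' @param rows,cols integer indices (default: keep all).
#' @return A `kmer_matrix`.
#' @export
subset_matrix <- function(matrix, rows = NULL, cols = NULL) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  kmers <- matrix$kmers; pres <- matrix$presence; acc <- matrix$accessions
  if (!is.null(rows)) { kmers <- kmers[rows]; pres <- pres[rows, , drop = FALSE] }
  if (!is.null(cols)) { acc <- acc[cols]; pres <- pres[, cols, drop = FALSE] }
  .new_kmer_matrix(kmers, pres, acc, matrix$k)
}

#' Random row sample of a k-mer matrix
#'
#' Uniform sample of rows without replacement; accession columns unchanged.
#' Used to draw the 100,000-k-mer subsets that feed the phylogeny and PCA.
#'
#' @param matrix a `kmer_matrix`.
#' @param n number of rows to draw (default 100000); must not exceed the
#'   row count.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A `kmer_matrix` with `n` rows.
#' @export
sample_rows <- function(matrix, n = 100000, seed = 1) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  nr <- nrow(matrix$presence)
  if (n > nr) stop(sprintf("requested %d rows but matrix has %d", n, nr))
  idx <- .with_seed(seed, sample.int(nr, n))
  subset_matrix(matrix, rows = idx)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
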