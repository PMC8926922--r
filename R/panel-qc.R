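#' Genotype matrix container
#'
#' Per-site biallelic calls across a panel. Calls are coded 0 (hom-ref),
#' 1 (het), 2 (hom-alt), `NA` (missing). Positions must be strictly
#' increasing within each chromosome.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param calls integer matrix, sites x accessions, with accession column
#'   names.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, calls) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(calls), nrow(calls) == nrow(sites),
            !is.null(colnames(calls)))
  if (anyDuplicated(colnames(calls))) stop("duplicate accession ids")
  ok <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) stop("positions must be strictly increasing within chromosome")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("calls must be 0/1/2/NA")
  structure(list(sites = sites, calls = calls), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d accessions (%d chromosome(s))\n",
              nrow(x$sites), ncol(x$calls), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Window-stratified SNP sampling
#'
#' Draws up to `per_window` sites uniformly without replacement from every
#' non-overlapping window of `window` bases per chromosome; windows holding
#' fewer sites contribute all of them. This is the thinning step ahead of
#' pairwise identity-by-state, which needs only a representative site set.
#'
#' @param matrix a `genotype_matrix`.
#' @param window window size in bases (default 4e6).
#' @param per_window sites drawn per window (default 100).
#' @param seed integer seed.
#' @return A `genotype_matrix` restricted to the sampled sites (original site
#'   order preserved), with attribute `site_index`.
#' @export
sample_snps <- function(matrix, window = 4e6, per_window = 100, seed = 1) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  if (window <= 0) stop("'window' must be > 0")
  sites <- matrix$sites
  if (nrow(sites) == 0L) {
    message("empty genotype matrix; returning empty subset")
    return(structure(genotype_matrix(sites, matrix$calls), site_index = integer(0)))
  }
  win_id <- paste(sites$chrom, (sites$pos - 1) %/% window)
  idx <- .with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(sites)), win_id), function(ix) {
      if (length(ix) <= per_window) ix else sort(sample(ix, per_window))
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  out <- genotype_matrix(sites[idx, , drop = FALSE],
                         matrix$calls[idx, , drop = FALSE])
  attr(out, "site_index") <- idx
  out
}

#' Pairwise identity by state
#'
#' For every unordered accession pair: the percentage of sites with identical
#' non-missing calls among the sites non-missing in both members.
#' Heterozygous is its own state, so het vs hom-ref counts as a mismatch.
#' Pairs with zero co-called sites get `NA` identity.
#'
#' @param matrix a `genotype_matrix` (typically a [sample_snps()] subset).
#' @return data.frame with columns `a`, `b`, `n_sites`, `identity` (percent);
#'   `n * (n - 1) / 2` rows.
#' @export
pairwise_ibs <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  n <- ncol(calls)
  if (n < 2L) stop("need >= 2 accessions")
  called <- !is.na(calls)
  storage.mode(called) <- "double"
  co_called <- crossprod(called)
  equal <- matrix(0, n, n)
  for (g in 0:2) {
    ind <- !is.na(calls) & calls == g
    storage.mode(ind) <- "double"
    equal <- equal + crossprod(ind)
  }
  ut <- which(upper.tri(co_called), arr.ind = TRUE)
  ids <- colnames(calls)
  data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
             n_sites = co_called[ut],
             identity = ifelse(co_called[ut] > 0,
                               100 * equal[ut] / co_called[ut], NA_real_),
             stringsAsFactors = FALSE)
}

#' Heterozygous call fraction per accession
#'
#' (# het calls) / (# non-missing biallelic calls); `NA` when an accession
#' has no non-missing calls. Values above the residual-heterogeneity
#' threshold (0.1 by convention) indicate a non-inbred or mixed seed stock.
#'
#' @param matrix a `genotype_matrix`.
#' @param accession optional single accession id; default all.
#' @return Named numeric vector of fractions.
#' @export
het_fraction <- function(matrix, accession = NULL) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  calls <- matrix$calls
  if (!is.null(accession)) {
    if (!accession %in% colnames(calls)) stop("unknown accession")
    calls <- calls[, accession, drop = FALSE]
  }
  n_called <- colSums(!is.na(calls))
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  ifelse(n_called > 0, n_het / n_called, NA_real_)
}

#' Panel quality-control report
#'
#' Runs windowed SNP sampling, pairwise identity-by-state and residual
#' heterozygosity, and applies the redundancy and heterogeneity thresholds.
#'
#' @param matrix a `genotype_matrix`.
#' @param window,per_window,seed passed to [sample_snps()].
#' @param ibs_threshold percent identity above which a pair is redundant
#'   (default 99.5; strict inequality).
#' @param het_threshold heterozygous fraction above which an accession is
#'   flagged for residual heterogeneity (default 0.1; strict inequality).
#' @return An object of class `qc_report`: `ibs` (pairs table),
#'   `redundant_pairs`, `het` (per-accession fractions), `flagged`,
#'   `n_missing` (per-accession missing-call counts), thresholds.
#' @export
qc_report <- function(matrix, window = 4e6, per_window = 100, seed = 1,
                      ibs_threshold = 99.5, het_threshold = 0.1) {
  sub <- sample_snps(matrix, window = window, per_window = per_window, seed = seed)
  ibs <- pairwise_ibs(sub)
  het <- het_fraction(matrix)
  red <- ibs[!is.na(ibs$identity) & ibs$identity > ibs_threshold, , drop = FALSE]
  structure(list(ibs = ibs,
                 redundant_pairs = red[, c("a", "b")],
                 het = het,
                 flagged = names(het)[!is.na(het) & het > het_threshold],
                 n_missing = colSums(is.na(matrix$calls)),
                 ibs_threshold = ibs_threshold, het_threshold = het_threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d pairs, %d redundant, %d flagged heterogeneous\n",
              nrow(x$ibs), nrow(x$redundant_pairs), length(x$flagged)))
  invisible(x)
}

#' Select a non-redundant, genetically stable accession set
#'
#' Accessions flagged for residual heterogeneity are dropped first. The
#' remaining redundant pairs form a graph; from each connected component
#' exactly one accession is retained - the one with the fewest missing
#' calls, ties broken by lexicographic id.
#'
#' @param report a [qc_report()].
#' @return Character vector of retained accession ids (original panel order).
#' @export
select_nonredundant <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  all_ids <- names(report$het)
  keep <- setdiff(all_ids, report$flagged)
  pairs <- report$redundant_pairs
  pairs <- pairs[pairs$a %in% keep & pairs$b %in% keep, , drop = FALSE]
  if (nrow(pairs) > 0) {
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE,
                                       vertices = data.frame(name = keep))
    comp <- igraph::components(g)$membership
    drop <- unlist(lapply(split(names(comp), comp), function(members) {
      if (length(members) == 1L) return(character(0))
      miss <- report$n_missing[members]
      ord <- order(miss, members)
      members[-ord[1]]
    }), use.names = FALSE)
    keep <- setdiff(keep, drop)
  }
  all_ids[all_ids %in% keep]
}
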