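# Association core: correlation prefilter, nested-model likelihood-ratio
# regression with PCA covariates, effective-variant Bonferroni threshold,
# exact k-mer placement and Manhattan-style plot coordinates.

#' Correlation prefilter of matrix rows against a phenotype
#'
#' Pearson correlation between each row's 0/1 presence vector and the
#' phenotype vector; rows whose absolute correlation exceeds `threshold`
#' (strictly) are retained. This is a computational sieve ahead of the
#' regression stage, not a significance test. Accessions without a phenotype
#' are dropped from both sides; rows that become constant on the retained
#' accessions are skipped and counted.
#'
#' @param matrix a `kmer_matrix`.
#' @param phenotype named numeric vector (accession -> score) or a
#'   data.frame with columns `accession`, `value`.
#' @param threshold absolute-correlation retention threshold (default 0.2).
#' @return data.frame with columns `row` (matrix row index), `kmer`,
#'   `pearson_r`; attributes `n_skipped` (zero-variance rows) and
#'   `accessions` (the phenotype-complete accession set used).
#' @export
prefilter <- function(matrix, phenotype, threshold = 0.2) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  y <- .align_phenotype(matrix, phenotype)
  if (length(y$idx) < 4L) stop("phenotype covers < 4 matrix accessions")
  if (sd(y$value) == 0) stop("zero-variance phenotype")
  pres <- matrix$presence[, y$idx, drop = FALSE]
  r <- row_pearson_cpp(pres, y$value)
  skipped <- sum(is.na(r))
  keep <- which(!is.na(r) & abs(r) > threshold)
  out <- data.frame(row = keep, kmer = matrix$kmers[keep],
                    pearson_r = r[keep], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  attr(out, "accessions") <- matrix$accessions[y$idx]
  out
}

.align_phenotype <- function(matrix, phenotype) {
  if (is.data.frame(phenotype))
    phenotype <- setNames(phenotype$value, phenotype$accession)
  phenotype <- phenotype[!is.na(phenotype)]
  idx <- which(matrix$accessions %in% names(phenotype))
  list(idx = idx, value = as.numeric(phenotype[matrix$accessions[idx]]))
}

# Core LRT algebra shared by the scalar and matrix paths. Null model:
# y ~ intercept + covariates; full model adds the presence term. With the
# Gaussian likelihood and variance profiled out the statistic is
# n * ln(RSS_null / RSS_full), chi-square with 1 df under the null.
# Implemented through the orthonormal covariate basis Q: with x~ and y~ the
# residuals of x and y on Q, RSS_full = RSS_null * (1 - r_partial^2).
.lrt_core <- function(xQ, xy, xx, Q, y) {
  n <- length(y)
  Qty <- crossprod(Q, y)                       # q x 1
  yy <- sum(y^2) - sum(Qty^2)                  # RSS_null
  num <- xy - as.numeric(xQ %*% Qty)           # x~' y~
  den <- xx - rowSums(xQ^2)                    # x~' x~
  degenerate <- den <= 1e-10 * pmax(1, xx)
  r2 <- ifelse(degenerate, 0, pmin(num^2 / (den * yy), 1))
  perfect <- !degenerate & (1 - r2 < 1e-12)  # RSS_full ~ 0: p underflows
  stat <- -n * log1p(-r2)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  p[perfect] <- 0
  score <- ifelse(p < 1e-300, 300, -log10(p))
  score[degenerate] <- 0
  direction <- ifelse(num >= 0, 1L, -1L)
  data.frame(score = score, direction = direction, statistic = stat,
             p = p, degenerate = degenerate)
}

.covariate_basis <- function(covariates, n) {
  X0 <- cbind(intercept = rep(1, n), covariates)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) stop("covariate matrix is rank deficient")
  qr.Q(qr0)
}

#' Likelihood-ratio association score for one presence vector
#'
#' Compares `phenotype ~ intercept + covariates` against the same model plus
#' the k-mer presence term, under a Gaussian likelihood with the variance
#' profiled out: statistic `n * ln(RSS_null / RSS_full)`, p-value from
#' chi-square with 1 df. The association score is -log10 p, capped at 300
#' (p below 1e-300, e.g. perfect separation). A presence vector collinear
#' with the covariates scores 0 with `degenerate = TRUE`.
#'
#' @param presence 0/1 vector, one entry per accession.
#' @param phenotype numeric vector, same order.
#' @param covariates optional numeric matrix (accessions x q), e.g. leading
#'   PCA scores.
#' @return List: `score`, `direction` (sign of the presence coefficient),
#'   `statistic`, `p`, `degenerate`.
#' @export
lrt_score <- function(presence, phenotype, covariates = NULL) {
  presence <- as.numeric(presence)
  n <- length(phenotype)
  stopifnot(length(presence) == n)
  q <- if (is.null(covariates)) 1L else 1L + ncol(covariates)
  if (n < q + 2L) stop("too few observations for the model")
  Q <- .covariate_basis(covariates, n)
  xQ <- matrix(crossprod(presence, Q), nrow = 1)
  res <- .lrt_core(xQ, sum(presence * phenotype), sum(presence^2), Q, phenotype)
  as.list(res[1, ])
}

# Vectorized LRT over candidate rows of a raw presence matrix.
.lrt_rows <- function(pres, phenotype, covariates = NULL) {
  n <- length(phenotype)
  Q <- .covariate_basis(covariates, n)
  xQ <- raw_crossprod_cpp(pres, Q)
  xy <- as.numeric(raw_crossprod_cpp(pres, cbind(phenotype)))
  xx <- as.numeric(row_occupancy_cpp(pres))    # binary rows: sum x^2 = sum x
  .lrt_core(xQ, xy, xx, Q, phenotype)
}

#' Bonferroni threshold with the effective-variant correction
#'
#' A single substitution alters k overlapping k-mers, so the total number of
#' tested k-mers is divided by k to get the effective number of variants;
#' the familywise threshold on the -log10 p scale is
#' `-log10(alpha / (n_tested / k))`. Reported raw and rounded to one decimal
#' (comparisons should use the raw value).
#'
#' @param n_tested total number of k-mers tested (>= 1).
#' @param k k-mer length (default 51).
#' @param alpha familywise error target (default 0.05).
#' @return List of class `threshold_spec`: `alpha`, `n_tested`, `k`,
#'   `effective_tests`, `score_threshold` (raw), `score_threshold_rounded`.
#' @export
#' @examples
#' bonferroni_threshold(5e9)$score_threshold_rounded  # 9.3
bonferroni_threshold <- function(n_tested, k = 51, alpha = 0.05) {
  .check_scalar(n_tested, "n_tested", lower = 1)
  effective <- max(1, n_tested / k)
  raw <- -log10(alpha / effective)
  structure(list(alpha = alpha, n_tested = n_tested, k = k,
                 effective_tests = effective, score_threshold = raw,
                 score_threshold_rounded = round(raw, 1)),
            class = "threshold_spec")
}

#' Place k-mers on target sequences by exact match
#'
#' Every exact occurrence of each k-mer (either strand; matching is on
#' canonical forms) is reported with the 1-based start of the forward-strand
#' window. k-mers with no occurrence are listed in the `unplaced` attribute.
#'
#' @param kmers character vector of k-mers (equal length).
#' @param targets named character vector of target sequences.
#' @return data.frame `kmer`, `target`, `position`, `strand`; attribute
#'   `unplaced`.
#' @export
place_kmers <- function(kmers, targets) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  if (length(kmers) == 0L)
    return(structure(data.frame(kmer = character(0), target = character(0),
                                position = integer(0), strand = character(0)),
                     unplaced = character(0)))
  k <- nchar(kmers[1])
  hits <- place_kmers_cpp(as.character(kmers), as.character(targets),
                          names(targets), as.integer(k))
  attr(hits, "unplaced") <- setdiff(kmers, hits$kmer)
  hits
}

#' Aggregate association records into plot coordinates
#'
#' In reference mode each integer on the x axis is a genomic block of
#' `block` bases: a k-mer placed at 1-based position p falls in block
#' `floor((p - 1) / block)` (0-based half-open blocks; block x starts at
#' 1-based coordinate `x * block + 1`). In anchored mode each integer is a
#' scaffold, ordered by its anchor position. Records with score above
#' `report_floor` are aggregated per (x, score rounded to one decimal,
#' direction) with the k-mer count per dot.
#'
#' @param records data.frame with columns `kmer`, `score`, `direction`.
#' @param placements data.frame from [place_kmers()] (reference mode: target
#'   = chromosome; anchored mode: target = scaffold id).
#' @param mode `"reference"` or `"anchored"`.
#' @param block block size in bases (reference mode, default 1e4).
#' @param report_floor minimum association score kept (default 6, strict).
#' @param anchored an `anchored_assembly` (required in anchored mode).
#' @param threshold optional `threshold_spec` carried into the attributes.
#' @return data.frame of class `plot_table` with columns `x`, `target`,
#'   `block_start` (reference mode), `score`, `direction`, `count`;
#'   attributes `mode`, `block`, `threshold`, `n_unplaced`.
#' @export
plot_table <- function(records, placements, mode = c("reference", "anchored"),
                       block = 1e4, report_floor = 6, anchored = NULL,
                       threshold = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("kmer", "score", "direction") %in% names(records)))
  sig <- records[records$score > report_floor, , drop = FALSE]
  m <- merge(sig, placements, by = "kmer")
  n_unplaced <- length(setdiff(sig$kmer, placements$kmer))
  if (n_unplaced > 0)
    message(sprintf("%d reported k-mers had no placement and were excluded",
                    n_unplaced))
  if (mode == "reference") {
    m$x <- (m$position - 1) %/% block
    key <- data.frame(x = m$x, target = m$target,
                      score = round(m$score, 1), direction = m$direction)
  } else {
    if (is.null(anchored) || !inherits(anchored, "anchored_assembly"))
      stop("anchored mode requires an 'anchored_assembly'")
    xo <- anchored$x_order
    m <- m[m$target %in% xo, , drop = FALSE]
    m$x <- match(m$target, xo) - 1L
    key <- data.frame(x = m$x, target = m$target,
                      score = round(m$score, 1), direction = m$direction)
  }
  if (nrow(key) == 0L) {
    out <- data.frame(x = integer(0), target = character(0),
                      block_start = numeric(0), score = numeric(0),
                      direction = integer(0), count = integer(0))
  } else {
    agg <- aggregate(list(count = rep(1L, nrow(key))), by = key, FUN = sum)
    agg <- agg[order(agg$target, agg$x, -agg$score), ]
    out <- data.frame(x = agg$x, target = agg$target,
                      block_start = if (mode == "reference")
                        agg$x * block + 1 else NA_real_,
                      score = agg$score, direction = agg$direction,
                      count = agg$count, row.names = NULL)
  }
  structure(out, mode = mode, block = block, threshold = threshold,
            n_unplaced = n_unplaced, class = c("plot_table", "data.frame"))
}

#' Run the full k-mer association scan
#'
#' Pipeline: align phenotype and matrix accessions (pairwise-complete),
#' compute PCA covariates on a fixed-seed row sample of the retained
#' accession set, correlation-prefilter all rows, score the candidates with
#' the nested-model likelihood-ratio test, and attach the effective-variant
#' Bonferroni threshold computed from the total number of matrix rows.
#'
#' @param matrix a `kmer_matrix`.
#' @param phenotype named numeric vector or data.frame (`accession`,
#'   `value`); accessions with missing phenotype are dropped for this run.
#' @param pcs number of leading PCA covariate dimensions (default 3; 0 for
#'   none).
#' @param prefilter_threshold absolute-correlation sieve (default 0.2).
#' @param alpha familywise error target (default 0.05).
#' @param pca_sample rows sampled for the covariate PCA (default 1e5, capped
#'   at the row count).
#' @param seed seed for the PCA row sample.
#' @return List of class `kmer_gwas`: `records` (data.frame `kmer`,
#'   `pearson_r`, `score`, `direction`, `degenerate`), `threshold`
#'   (`threshold_spec`), `n_tested`, `covariates`, `accessions`.
#' @export
run_kmer_gwas <- function(matrix, phenotype, pcs = 3, prefilter_threshold = 0.2,
                          alpha = 0.05, pca_sample = 1e5, seed = 1) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  y <- .align_phenotype(matrix, phenotype)
  sub <- subset_matrix(matrix, cols = y$idx)
  covar <- NULL
  if (pcs > 0) {
    samp <- sample_rows(sub, n = min(pca_sample, nrow(sub$presence)), seed = seed)
    covar <- kmer_pca(samp, dims = pcs)$scores
  }
  cand <- prefilter(sub, setNames(y$value, sub$accessions),
                    threshold = prefilter_threshold)
  n_tested <- nrow(matrix$presence)
  thr <- bonferroni_threshold(n_tested, k = matrix$k, alpha = alpha)
  if (nrow(cand) > 0) {
    lrt <- .lrt_rows(sub$presence[cand$row, , drop = FALSE], y$value, covar)
    records <- data.frame(kmer = cand$kmer, pearson_r = cand$pearson_r,
                          score = lrt$score, direction = lrt$direction,
                          degenerate = lrt$degenerate,
                          stringsAsFactors = FALSE)
  } else {
    records <- data.frame(kmer = character(0), pearson_r = numeric(0),
                          score = numeric(0), direction = integer(0),
                          degenerate = logical(0))
  }
  structure(list(records = records, threshold = thr, n_tested = n_tested,
                 covariates = covar, accessions = sub$accessions),
            class = "kmer_gwas")
}

#' @export
print.kmer_gwas <- function(x, ...) {
  cat(sprintf(
    "<kmer_gwas> %d candidates of %d tested rows; threshold %.2f (rounded %.1f)\n",
    nrow(x$records), x$n_tested, x$threshold$score_threshold,
    x$threshold$score_threshold_rounded))
  invisible(x)
}
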