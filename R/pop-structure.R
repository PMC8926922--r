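# Population structure and diversity statistics computed from the k-mer
# presence/absence matrix (tree, PCA, Venn partition) and from the genotype
# matrix (Weir-Cockerham F_ST, LD decay).

#' Pairwise distance between accessions from k-mer presence
#'
#' Hamming proportion by default: d(a, b) = fraction of matrix rows where
#' presence differs. Jaccard distance (1 - intersection/union) is available
#' behind the `method` flag; both are plain dissimilarities suitable for
#' UPGMA.
#'
#' @param matrix a `kmer_matrix`.
#' @param method `"hamming"` (default) or `"jaccard"`.
#' @return A `dist` object with accession labels.
#' @export
kmer_distance <- function(matrix, method = c("hamming", "jaccard")) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  method <- match.arg(method)
  if (nrow(matrix$presence) == 0L) stop("matrix has zero rows")
  if (length(matrix$accessions) < 2L) stop("need >= 2 accessions")
  dm <- switch(method,
               hamming = column_hamming_cpp(matrix$presence),
               jaccard = column_jaccard_cpp(matrix$presence))
  dimnames(dm) <- list(matrix$accessions, matrix$accessions)
  stats::as.dist(dm)
}

# Deterministic UPGMA with size-weighted arithmetic-mean linkage. Ties are
# broken by the lexicographically smallest (min member id, max member id)
# pair. Returns an hclust-compatible structure.
.upgma_hclust <- function(d) {
  dm <- as.matrix(d)
  labels <- rownames(dm)
  n <- nrow(dm)
  if (any(!is.finite(dm))) stop("distances must be finite")
  size <- rep(1L, n)
  cl_id <- -seq_len(n)                      # hclust convention
  repr <- labels                            # smallest member label per cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (ii in seq_along(act)) for (jj in seq_len(ii - 1L)) {
      i <- act[jj]; j <- act[ii]
      dij <- dm[i, j]
      key <- sort(c(repr[i], repr[j]))
      if (dij < best_d - 1e-15 ||
          (abs(dij - best_d) <= 1e-15 &&
           (is.null(best_key) ||
            key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2])))) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    merge[m, ] <- sort(c(cl_id[i], cl_id[j]))
    height[m] <- best_d
    # size-weighted average linkage update, stored on slot i
    for (k in which(active)) {
      if (k == i || k == j) next
      dk <- (size[i] * dm[i, k] + size[j] * dm[j, k]) / (size[i] + size[j])
      dm[i, k] <- dk; dm[k, i] <- dk
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    repr[i] <- min(repr[i], repr[j])
    cl_id[i] <- m
    active[j] <- FALSE
  }
  order <- local({  # tip order by recursive traversal
    walk <- function(node) {
      if (node < 0) return(-node)
      c(walk(merge[node, 1]), walk(merge[node, 2]))
    }
    walk(n - 1L)
  })
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "upgma",
                 call = match.call(), dist.method = "kmer"),
            class = "hclust")
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group agglomeration with arithmetic-mean linkage
#' weighted by cluster sizes; the height of an internal node is half the
#' merge distance, so the tree is ultrametric. Tied merges are resolved by
#' the lexicographically smallest accession-id pair, making the output
#' deterministic.
#'
#' @param d a `dist` or symmetric matrix with labels.
#' @return An [ape::phylo] rooted ultrametric tree; attribute
#'   `merge_heights` holds the internal-node heights (half merge distances),
#'   attribute `hclust` the underlying agglomeration.
#' @export
upgma <- function(d) {
  hc <- .upgma_hclust(d)
  phy <- ape::as.phylo(hc)
  attr(phy, "merge_heights") <- hc$height / 2
  attr(phy, "hclust") <- hc
  phy
}

#' Bootstrap support for the UPGMA k-mer tree
#'
#' Matrix rows are resampled with replacement `replicates` times; each
#' replicate matrix yields a UPGMA tree, and the support of an internal node
#' of the original tree is the percentage of replicate trees containing the
#' same clade.
#'
#' @param matrix a `kmer_matrix` (>= 3 accessions).
#' @param replicates number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param method distance metric, see [kmer_distance()].
#' @return The UPGMA tree ([ape::phylo]) with integer percent supports in
#'   `node.label` (root label is the replicate count's 100).
#' @export
bootstrap_tree <- function(matrix, replicates = 100, seed = 1,
                           method = "hamming") {
  stopifnot(inherits(matrix, "kmer_matrix"))
  if (length(matrix$accessions) < 3L) stop("need >= 3 accessions")
  if (replicates < 1) stop("'replicates' must be >= 1")
  main <- upgma(kmer_distance(matrix, method))
  nr <- nrow(matrix$presence)
  reps <- .with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      idx <- sample.int(nr, nr, replace = TRUE)
      upgma(kmer_distance(subset_matrix(matrix, rows = idx), method))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.integer(round(100 * counts / replicates))
  main
}

#' PCA of accessions on k-mer presence
#'
#' Column-centered presence/absence decomposed by singular values; returns
#' the leading accession scores with a deterministic sign convention (the
#' largest-magnitude k-mer loading of each component is made positive).
#'
#' @param matrix a `kmer_matrix`; rows >= dims and accessions >= dims + 1.
#' @param dims number of leading dimensions (default 3).
#' @return List of class `kmer_pca`: `scores` (accessions x dims),
#'   `sdev`, `var_explained` (fractions, non-increasing), `dims`.
#' @export
kmer_pca <- function(matrix, dims = 3) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  nr <- nrow(matrix$presence); nc <- length(matrix$accessions)
  if (nr < dims || nc < dims + 1) stop("matrix too small for requested dims")
  x <- matrix(as.integer(matrix$presence), nr, nc)
  if (all(row_occupancy_cpp(matrix$presence) %in% c(0L, nc)))
    stop("zero-variance matrix")
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE, rank. = dims)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(dims), drop = FALSE]
  rownames(scores) <- matrix$accessions
  structure(list(scores = scores, sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2), dims = dims),
            class = "kmer_pca")
}

#' Three-set Venn partition of the k-mer space by lineage
#'
#' Each matrix row is assigned to the cell of the three-set Venn diagram
#' determined by which lineages contain it (presence in at least one
#' accession of the lineage). Percentages over all rows sum to 100; the sum
#' of the three single-lineage cells is the lineage-specific share of the
#' k-mer space.
#'
#' @param matrix a `kmer_matrix`.
#' @param labels named character vector accession -> lineage label.
#' @return data.frame with columns `cell` (e.g. `"L1"`, `"L1&L2"`,
#'   `"L1&L2&L3"`), `count`, `percent`.
#' @export
venn_partition <- function(matrix, labels) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  labels <- labels[matrix$accessions]
  if (anyNA(labels)) stop("every accession must be labeled")
  lineages <- sort(unique(labels))
  inlin <- vapply(lineages, function(l)
    rows_any_cpp(matrix$presence, which(labels == l) - 1L),
    logical(nrow(matrix$presence)))
  cell <- apply(inlin, 1L, function(z) paste(lineages[z], collapse = "&"))
  tab <- table(cell)
  data.frame(cell = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(matrix$presence),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weir & Cockerham (1984) per-site variance components for r populations.
# pop_calls: list of call matrices (sites x accessions, codes 0/1/2/NA).
# Returns data.frame with per-site a, b, c.
.wc_components <- function(pop_calls) {
  r <- length(pop_calls)
  n <- do.call(cbind, lapply(pop_calls, function(m) rowSums(!is.na(m))))
  p <- do.call(cbind, lapply(pop_calls, function(m) rowSums(m, na.rm = TRUE))) / (2 * n)
  h <- do.call(cbind, lapply(pop_calls, function(m) rowSums(m == 1L, na.rm = TRUE))) / n
  n[n == 0] <- NA
  nsum <- rowSums(n)
  nbar <- nsum / r
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  pbar <- rowSums(n * p) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  data.frame(a = a, b = b, c = c_)
}

#' Sliding-window fixation index (Weir & Cockerham)
#'
#' Per-site variance components a (among populations), b (among individuals
#' within populations) and c (within individuals) are estimated with the
#' Weir & Cockerham (1984) estimator, then combined per window both as the
#' ratio of sums (`fst_weighted`, the windowed weighted estimator) and as the
#' mean of per-site ratios (`fst_mean`). Windows slide by `step` within each
#' chromosome.
#'
#' @param matrix a `genotype_matrix`.
#' @param populations named list: population label -> accession ids (each
#'   with >= 2 accessions). All unordered population pairs are reported.
#' @param window window size in bases (default 1e6); must be > 0.
#' @param step step size in bases (default 1e5).
#' @return data.frame with columns `pop_a`, `pop_b`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_sites`, `fst_weighted`, `fst_mean`.
#' @export
fst_windows <- function(matrix, populations, window = 1e6, step = 1e5) {
  stopifnot(inherits(matrix, "genotype_matrix"), is.list(populations))
  if (window <= 0) stop("'window' must be > 0")
  if (length(populations) < 2L) stop("need >= 2 populations")
  if (any(sapply(populations, length) < 2L)) stop("each population needs >= 2 accessions")
  sites <- matrix$sites
  pair_idx <- utils::combn(names(populations), 2, simplify = FALSE)
  out <- list()
  for (pair in pair_idx) {
    comp <- .wc_components(list(
      matrix$calls[, populations[[pair[1]]], drop = FALSE],
      matrix$calls[, populations[[pair[2]]], drop = FALSE]))
    for (ch in unique(sites$chrom)) {
      in_ch <- sites$chrom == ch
      pos <- sites$pos[in_ch]
      cc <- comp[in_ch, , drop = FALSE]
      max_pos <- max(pos)
      starts <- seq(1, max(1, max_pos), by = step)
      for (s in starts) {
        e <- s + window - 1
        if (s > max_pos) break
        in_w <- which(pos >= s & pos <= e)
        num <- sum(cc$a[in_w], na.rm = TRUE)
        den <- sum(cc$a[in_w] + cc$b[in_w] + cc$c[in_w], na.rm = TRUE)
        per <- cc$a[in_w] / (cc$a[in_w] + cc$b[in_w] + cc$c[in_w])
        out[[length(out) + 1L]] <- data.frame(
          pop_a = pair[1], pop_b = pair[2], chrom = ch, start = s, end = e,
          n_sites = length(in_w),
          fst_weighted = if (den > 0) num / den else NA_real_,
          fst_mean = if (any(is.finite(per))) mean(per[is.finite(per)]) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay
#'
#' Composite r-squared between allele-dosage vectors of site pairs within
#' `max_dist` of each other on the same chromosome, binned by distance. Phase
#' is not required: the squared Pearson correlation of 0/1/2 dosages is the
#' standard composite-LD estimate for predominantly homozygous panels. The
#' decay distance per region is the midpoint of the first distance bin whose
#' mean r-squared falls below `r2_floor`.
#'
#' @param matrix a `genotype_matrix`.
#' @param max_dist maximum pair distance in bases (default 5e6).
#' @param bin_width distance bin width in bases (default 1e4).
#' @param regions optional data.frame `chrom`, `start`, `end`, `region`
#'   (1-based inclusive intervals, e.g. the R1/R2a/C/R2b/R3 recombination
#'   partition); pairs whose two sites fall in the same region contribute to
#'   that region's bins. All pairs contribute to region `"all"`.
#' @param r2_floor decay threshold on mean r-squared (default 0.1).
#' @param max_sites_per_chrom site cap per chromosome; denser chromosomes are
#'   thinned uniformly (default 2000) to bound the pair count.
#' @param seed seed for the thinning draw.
#' @return List of class `ld_decay`: `bins` (data.frame `region`,
#'   `dist_low`, `dist_high`, `mean_r2`, `n_pairs`) and `decay_distance`
#'   (named vector per region, `NA` when mean r-squared never drops below the
#'   floor).
#' @export
ld_decay <- function(matrix, max_dist = 5e6, bin_width = 1e4, regions = NULL,
                     r2_floor = 0.1, max_sites_per_chrom = 2000, seed = 1) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  sites <- matrix$sites
  pairs <- list()
  for (ch in unique(sites$chrom)) {
    ix <- which(sites$chrom == ch)
    if (length(ix) > max_sites_per_chrom)
      ix <- sort(.with_seed(seed, sample(ix, max_sites_per_chrom)))
    if (length(ix) < 2L) next
    pos <- sites$pos[ix]
    r2m <- suppressWarnings(
      cor(matrix$calls[ix, , drop = FALSE] |> t(),
          use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(r2m), arr.ind = TRUE)
    dist <- pos[pr[, 2]] - pos[pr[, 1]]
    keep <- dist > 0 & dist <= max_dist & is.finite(r2m[pr])
    if (!any(keep)) next
    df <- data.frame(chrom = ch,
                     pos_a = pos[pr[keep, 1]], pos_b = pos[pr[keep, 2]],
                     dist = dist[keep], r2 = r2m[pr][keep],
                     stringsAsFactors = FALSE)
    pairs[[ch]] <- df
  }
  if (length(pairs) == 0L) stop("no informative site pairs")
  pairs <- do.call(rbind, pairs)
  pairs$region <- "all"
  if (!is.null(regions)) {
    for (i in seq_len(nrow(regions))) {
      in_r <- pairs$chrom == regions$chrom[i] &
        pairs$pos_a >= regions$start[i] & pairs$pos_b <= regions$end[i]
      extra <- pairs[in_r, , drop = FALSE]
      if (nrow(extra)) { extra$region <- regions$region[i]; pairs <- rbind(pairs, extra) }
    }
  }
  pairs$bin <- (pairs$dist - 1) %/% bin_width
  agg <- aggregate(r2 ~ region + bin, data = pairs, FUN = mean)
  cnt <- aggregate(r2 ~ region + bin, data = pairs, FUN = length)
  bins <- data.frame(region = agg$region,
                     dist_low = agg$bin * bin_width + 1,
                     dist_high = (agg$bin + 1) * bin_width,
                     mean_r2 = agg$r2, n_pairs = cnt$r2,
                     stringsAsFactors = FALSE)
  bins <- bins[order(bins$region, bins$dist_low), ]
  rownames(bins) <- NULL
  decay <- vapply(split(bins, bins$region), function(b) {
    below <- which(b$mean_r2 < r2_floor)
    if (length(below) == 0L) NA_real_
    else (b$dist_low[below[1]] + b$dist_high[below[1]]) / 2
  }, numeric(1))
  structure(list(bins = bins, decay_distance = decay, r2_floor = r2_floor),
            class = "ld_decay")
}
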