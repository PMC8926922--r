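toy_matrix <- function(pres, ids = NULL) {
  # build a kmer_matrix by hand from a 0/1 integer matrix
  if (is.null(ids)) ids <- paste0("a", seq_len(ncol(pres)))
  sets <- lapply(seq_len(ncol(pres)), function(j) NULL)
  m <- structure(list(kmers = sprintf("K%04d", seq_len(nrow(pres))),
                      presence = matrix(as.raw(pres), nrow(pres)),
                      accessions = ids, k = 7L),
                 class = "kmer_matrix")
  m
}

test_that("k-mer distance equals the brute-force column comparison", {
  pres <- cbind(c(1, 0, 1, 1), c(1, 1, 1, 0))
  d <- kmer_distance(toy_matrix(pres))
  expect_equal(as.numeric(d), 0.5)  # 2 of 4 rows differ
  expect_equal(as.numeric(kmer_distance(toy_matrix(cbind(pres[, 1], pres[, 1])))), 0)
  withr::with_seed(2, {
    big <- matrix(rbinom(500 * 8, 1, 0.4), 500, 8)
  })
  d2 <- as.matrix(kmer_distance(toy_matrix(big)))
  brute <- outer(1:8, 1:8, Vectorize(function(i, j) mean(big[, i] != big[, j])))
  expect_equal(unname(d2), brute)
  # jaccard flag
  dj <- as.matrix(kmer_distance(toy_matrix(big), method = "jaccard"))
  bj <- outer(1:8, 1:8, Vectorize(function(i, j) {
    u <- sum(big[, i] | big[, j]); if (u == 0) 0 else 1 - sum(big[, i] & big[, j]) / u
  }))
  expect_equal(unname(dj), bj)
})

test_that("UPGMA reproduces the forced merge order and reference heights", {
  d <- as.dist(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tr <- upgma(d)
  expect_equal(sort(attr(tr, "merge_heights")), c(1, 2))
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 2)
  expect_equal(co["A", "C"], 4)
  # ultrametric: all root-to-tip depths equal
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-12)
  # random matrices agree with average-linkage hierarchical clustering
  for (s in 1:5) {
    withr::with_seed(s, {
      n <- 6 + s %% 3
      x <- matrix(runif(n * 10), n)
      dm <- dist(x)
      attr(dm, "Labels") <- paste0("t", seq_len(n))
    })
    mine <- upgma(dm)
    hc <- hclust(dm, method = "average")
    expect_equal(sort(attr(mine, "merge_heights")), sort(hc$height / 2))
    co_m <- ape::cophenetic.phylo(mine)
    co_h <- as.matrix(cophenetic(hc))[rownames(co_m), colnames(co_m)]
    expect_equal(co_m, co_h)
  }
  # degenerate all-equal distances resolve deterministically
  deq <- as.dist(matrix(1, 4, 4) - diag(4))
  attr(deq, "Labels") <- c("d", "b", "c", "a")
  t1 <- upgma(deq); t2 <- upgma(deq)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(unique(round(attr(t1, "merge_heights"), 12)), 0.5)
  expect_error(upgma(as.dist(matrix(NA_real_, 2, 2))), "finite")
})

test_that("bootstrap supports recover planted clades", {
  p <- small_panel()
  km <- small_matrix()
  bt <- bootstrap_tree(sample_rows(km, min(2000, nrow(km$presence)), seed = 2),
                       replicates = 60, seed = 3)
  expect_true(all(bt$node.label >= 0 & bt$node.label <= 100))
  lin <- split(names(p$truth$lineage_of), p$truth$lineage_of)
  for (l in names(lin)) {
    mrca <- ape::getMRCA(bt, lin[[l]])
    clade <- ape::extract.clade(bt, mrca)$tip.label
    expect_setequal(clade, lin[[l]])  # lineages are clades
    expect_gte(bt$node.label[mrca - ape::Ntip(bt)], 95)
  }
  # identical columns within two groups: the split cannot be broken
  pres <- cbind(1, 1, 1, 0, 0)[rep(1, 40), ] ; pres[1:20, 4:5] <- 1
  pres[1:20, 1:3] <- 0
  bt2 <- bootstrap_tree(toy_matrix(pres), replicates = 30, seed = 5)
  expect_true(all(bt2$node.label == 100))
})

test_that("PCA separates planted groups with a deterministic sign", {
  km <- small_matrix()
  labels <- small_panel()$truth$lineage_of[km$accessions]
  pc <- kmer_pca(km, dims = 3)
  expect_equal(dim(pc$scores), c(length(km$accessions), 3L))
  expect_true(all(diff(pc$var_explained[1:3]) <= 1e-12))
  # the three lineages occupy disjoint intervals on PC1 or PC2
  separated <- function(j) {
    rng <- vapply(split(pc$scores[, j], labels), range, numeric(2))
    ord <- order(rng[1, ])
    all(rng[2, ord][-3] < rng[1, ord][-1])
  }
  expect_true(separated(1) || separated(2))
  # duplicated accession columns get identical coordinates
  km2 <- subset_matrix(km, cols = c(seq_along(km$accessions), 1L))
  km2$accessions[length(km2$accessions)] <- "dup"
  pc2 <- kmer_pca(km2, dims = 2)
  expect_equal(pc2$scores["ACC001", ], pc2$scores["dup", ], tolerance = 1e-8)
  expect_error(kmer_pca(toy_matrix(matrix(1, 10, 5))), "zero-variance")
})

test_that("Venn partition is exhaustive, disjoint and truth-consistent", {
  km <- small_matrix()
  labels <- small_panel()$truth$lineage_of
  vp <- venn_partition(km, labels)
  expect_equal(sum(vp$percent), 100, tolerance = 1e-9)
  expect_identical(sum(vp$count), nrow(km$presence))
  # single-lineage row lands in the right cell
  pres <- rbind(c(1, 1, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0), c(1, 0, 1, 0, 1, 0))
  toy <- toy_matrix(pres, ids = paste0("x", 1:6))
  lab <- setNames(rep(c("L1", "L2", "L3"), each = 2), paste0("x", 1:6))
  vt <- venn_partition(toy, lab)
  expect_identical(vt$count[match(c("L1", "L2", "L1&L2&L3"), vt$cell)],
                   c(1L, 1L, 1L))
  # with no within-lineage diversity accessions equal their lineage
  # founders, so each cell count must equal set algebra over the founder
  # k-mer sets (independent route via count_kmers on the founders)
  p0 <- simulate_panel(panel_config(n_per_lineage = c(3, 3, 3),
                                    genome_length = 5e4, divergence = 0.02,
                                    within_diversity = 0, n_subpop = 1,
                                    sub_divergence = 0, het_fraction = 0,
                                    seed = 77))
  km0 <- kmer_matrix_from_sequences(p0$sequences, kmer_config(k = 31, min_count = 1))
  vp0 <- venn_partition(km0, p0$truth$lineage_of)
  fsets <- lapply(p0$lineage_sequences, function(s)
    count_kmers(unname(s), kmer_config(k = 31, min_count = 1))$kmers)
  inlin <- vapply(fsets, function(fs) km0$kmers %in% fs,
                  logical(length(km0$kmers)))
  cell_oracle <- apply(inlin, 1, function(z)
    paste(names(fsets)[z], collapse = "&"))
  tab <- table(cell_oracle)
  expect_identical(setNames(vp0$count, vp0$cell)[names(tab)],
                   setNames(as.integer(tab), names(tab)))
})

test_that("Weir-Cockerham per-site components match the frozen oracle", {
  # toy table hand-computed independently (numpy transcription of the 1984
  # estimator): 5 sites, pops of 4 and 3 individuals, codes 0/1/2/NA
  calls <- rbind(c(0, 0, 1, 0, 2, 2, 1),
                 c(1, 0, 0, 0, 2, 1, 2),
                 c(0, 0, 0, 0, 0, 0, 0),
                 c(2, 1, 0, NA, 0, 0, 1),
                 c(0, 2, 1, 1, 1, 2, NA))
  colnames(calls) <- c(paste0("p", 1:4), paste0("q", 1:3))
  gm <- genotype_matrix(data.frame(chrom = "c", pos = 1:5, ref = "A",
                                   alt = "C", stringsAsFactors = FALSE),
                        calls)
  pops <- list(P = paste0("p", 1:4), Q = paste0("q", 1:3))
  w <- fst_windows(gm, pops, window = 10, step = 10)
  expect_identical(nrow(w), 1L)
  expect_equal(w$fst_weighted, 0.3467782775775271, tolerance = 1e-10)
  # per-site thetas: 0.618058, 0.618058, NaN, 0, -0.107692; mean over finite
  expect_equal(w$fst_mean,
               mean(c(0.618058330004, 0.618058330004, 0, -0.107692307692)),
               tolerance = 1e-8)
  # fixed opposite alleles -> F_ST = 1
  fix <- cbind(matrix(0L, 5, 4), matrix(2L, 5, 3))
  colnames(fix) <- colnames(calls)
  gm1 <- genotype_matrix(gm$sites, fix)
  expect_equal(fst_windows(gm1, pops, 10, 10)$fst_weighted, 1)
  # one population split in two -> no differentiation
  withr::with_seed(9, {
    same <- matrix(sample(0:2, 40 * 200, TRUE, prob = c(.5, .1, .4)), 200, 40)
  })
  colnames(same) <- paste0("s", 1:40)
  gms <- genotype_matrix(data.frame(chrom = "c", pos = 1:200, ref = "A",
                                    alt = "C", stringsAsFactors = FALSE), same)
  f0 <- fst_windows(gms, list(A = paste0("s", 1:20), B = paste0("s", 21:40)),
                    window = 200, step = 200)
  expect_lte(f0$fst_weighted, 0.02)
})

test_that("windowed F_ST rises with lineage divergence", {
  fst_of <- function(divergence) {
    p <- simulate_panel(panel_config(n_per_lineage = c(10, 10),
                                     genome_length = 5e4, divergence = divergence,
                                     within_diversity = 0.002, het_fraction = 0,
                                     seed = 55))
    pops <- split(names(p$truth$lineage_of), p$truth$lineage_of)
    w <- fst_windows(p$genotypes, pops, window = 5e4, step = 5e4)
    w$fst_weighted[1]
  }
  sweep <- vapply(c(0.002, 0.01, 0.05), fst_of, numeric(1))
  expect_true(all(diff(sweep) > 0))
})

test_that("LD decay: perfect LD, null expectation and monotone decay", {
  # duplicated site -> r2 = 1
  withr::with_seed(3, {
    v <- sample(0:2, 30, TRUE)
  })
  calls <- cbind(a = v, b = v)
  calls <- t(calls)  # 2 sites x 30 accessions
  colnames(calls) <- paste0("i", 1:30)
  gm <- genotype_matrix(data.frame(chrom = "c", pos = c(100, 200), ref = "A",
                                   alt = "C", stringsAsFactors = FALSE), calls)
  ld <- ld_decay(gm, max_dist = 1e3, bin_width = 1e3)
  expect_equal(ld$bins$mean_r2, 1)
  # independent sites: mean r2 near 1/n
  n <- 60
  withr::with_seed(8, {
    ind <- matrix(rbinom(400 * n, 2, 0.5), 400, n)
  })
  colnames(ind) <- paste0("i", 1:n)
  gmi <- genotype_matrix(data.frame(chrom = "c", pos = seq_len(400) * 10,
                                    ref = "A", alt = "C",
                                    stringsAsFactors = FALSE), ind)
  ldi <- ld_decay(gmi, max_dist = 4000, bin_width = 4000)
  n_pairs <- ldi$bins$n_pairs[1]
  se <- sqrt(2) / n / sqrt(n_pairs) * 3  # loose 3.SE band for chi2_1/n means
  expect_lt(abs(ldi$bins$mean_r2[1] - 1 / n), 3 * se + 0.005)
  # block-copy genomes: mean r2 non-increasing over distance (isotonic fit)
  withr::with_seed(13, {
    blocks <- matrix(rbinom(30 * n, 2, 0.5), 30, n)
    hap <- blocks[rep(1:30, each = 10), ]            # 10 perfectly linked sites
    flip <- matrix(rbinom(300 * n, 1, 0.25), 300, n) # decay with distance
    noisy <- (hap + flip) %% 3
  })
  colnames(noisy) <- paste0("i", 1:n)
  gmb <- genotype_matrix(data.frame(chrom = "c", pos = seq_len(300) * 1000,
                                    ref = "A", alt = "C",
                                    stringsAsFactors = FALSE), noisy)
  ldb <- ld_decay(gmb, max_dist = 3e4, bin_width = 5e3)
  iso <- stats::isoreg(ldb$bins$dist_low, -ldb$bins$mean_r2)
  expect_gt(stats::cor(-iso$yf, ldb$bins$mean_r2), 0.9)
  expect_true(ldb$bins$mean_r2[1] > utils::tail(ldb$bins$mean_r2, 1))
})
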