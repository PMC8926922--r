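toy_km <- function(pres, ids = NULL, k = 7L) {
  if (is.null(ids)) ids <- paste0("a", seq_len(ncol(pres)))
  structure(list(kmers = sprintf("K%05d", seq_len(nrow(pres))),
                 presence = matrix(as.raw(pres), nrow(pres)),
                 accessions = ids, k = k),
            class = "kmer_matrix")
}

test_that("prefilter computes Pearson r and applies the strict threshold", {
  pres <- rbind(c(0, 0, 1, 1),   # r = 0.894 with 1:4
                c(1, 1, 0, 0),   # r = 0 with (1,2,1,2)
                c(1, 1, 1, 1))   # zero variance: skipped
  km <- toy_km(pres)
  y <- setNames(c(1, 2, 3, 4), km$accessions)
  out <- prefilter(km, y, threshold = 0.2)
  # rows 1 and 2 are +/- 0.894 against 1:4; the constant row is skipped
  expect_identical(out$row, c(1L, 2L))
  expect_equal(out$pearson_r, c(2, -2) / sqrt(5), tolerance = 1e-9)
  expect_identical(attr(out, "n_skipped"), 1L)
  y2 <- setNames(c(1, 2, 1, 2), km$accessions)
  out2 <- prefilter(km, y2, threshold = 0.2)
  expect_false(1 %in% out2$row)
  # threshold 0 retains every non-degenerate row (strict ">"), so row 2
  # (r = 0 against y2) is still excluded
  out3 <- prefilter(km, y, threshold = 0)
  expect_identical(out3$row, c(1L, 2L))
  expect_error(prefilter(km, setNames(rep(1, 4), km$accessions)), "zero-variance")
})

test_that("lrt_score handles null, perfect and collinear cases", {
  # orthogonal presence: statistic 0
  r <- lrt_score(c(1, 1, 0, 0), c(1, 2, 1, 2))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$score, 0, tolerance = 1e-9)
  # perfect separation: capped score
  r2 <- lrt_score(c(0, 0, 0, 1, 1, 1), c(1, 1, 1, 9, 9, 9))
  expect_equal(r2$score, 300)
  expect_identical(r2$direction, 1L)
  # direction follows the sign of the presence coefficient
  r3 <- lrt_score(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 9, 9, 8))
  expect_identical(r3$direction, -1L)
  # presence collinear with covariates: degenerate, score 0
  cov <- cbind(c(0, 0, 1, 1, 0, 1))
  r4 <- lrt_score(c(0, 0, 1, 1, 0, 1), rnorm(6), covariates = cov)
  expect_true(r4$degenerate)
  expect_equal(r4$score, 0)
  # agrees with R's own nested-OLS likelihood ratio
  withr::with_seed(31, {
    x <- rbinom(40, 1, 0.5); z <- rnorm(40); y <- 0.8 * x + 0.3 * z + rnorm(40)
  })
  mine <- lrt_score(x, y, covariates = cbind(z))
  full <- stats::lm(y ~ z + x); null <- stats::lm(y ~ z)
  stat <- 2 * (stats::logLik(full) - stats::logLik(null))
  expect_equal(mine$statistic, as.numeric(stat), tolerance = 1e-8)
})

test_that("null p values are uniform (KS calibration)", {
  n <- 60
  presence <- rep(c(0, 1), each = n / 2)
  withr::with_seed(17, {
    p_vals <- replicate(200, lrt_score(presence, rnorm(n))$p)
  })
  ks <- stats::ks.test(p_vals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni thresholds reproduce the closed form and monotonicity", {
  t5 <- bonferroni_threshold(5e9, 51, 0.05)
  expect_equal(t5$score_threshold, -log10(0.05 / (5e9 / 51)), tolerance = 1e-12)
  expect_equal(t5$score_threshold_rounded, 9.3)
  expect_equal(bonferroni_threshold(3e9)$score_threshold_rounded, 9.1)
  expect_equal(bonferroni_threshold(51)$score_threshold, -log10(0.05),
               tolerance = 1e-12)
  # strictly increasing in n_tested, decreasing in alpha
  ns <- c(1e6, 1e7, 1e8, 1e9)
  th <- vapply(ns, function(n) bonferroni_threshold(n)$score_threshold, numeric(1))
  expect_true(all(diff(th) > 0))
  al <- vapply(c(0.01, 0.05, 0.1), function(a)
    bonferroni_threshold(1e8, alpha = a)$score_threshold, numeric(1))
  expect_true(all(diff(al) < 0))
})

test_that("k-mer placement equals the sliding-window oracle on both strands", {
  ref <- c(tgt = random_dna(5000, seed = 41))
  k <- 21
  # constructed forward match
  q1 <- substr(ref, 101, 101 + k - 1)
  hit <- place_kmers(q1, ref)
  expect_true(any(hit$position == 101 & hit$strand == "+"))
  # reverse-complement query hits the same window with strand "-"
  q1rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(q1, "")[[1]]), collapse = ""))
  hit_rc <- place_kmers(q1rc, ref)
  expect_true(any(hit_rc$position == 101 & hit_rc$strand == "-"))
  # random queries vs brute-force search
  withr::with_seed(42, {
    starts <- sample(nchar(ref) - k, 20)
  })
  qs <- substring(ref, starts, starts + k - 1)
  hits <- place_kmers(qs, ref)
  for (i in seq_along(qs)) {
    brute <- integer(0)
    rcq <- chartr("ACGT", "TGCA", paste(rev(strsplit(qs[i], "")[[1]]), collapse = ""))
    for (p in seq_len(nchar(ref) - k + 1)) {
      w <- substr(ref, p, p + k - 1)
      if (w == qs[i] || w == rcq) brute <- c(brute, p)
    }
    expect_setequal(hits$position[hits$kmer == qs[i]], brute)
  }
  # absent k-mer is reported unplaced
  none <- place_kmers(paste(rep("A", k), collapse = ""), ref)
  expect_identical(attr(none, "unplaced"), paste(rep("A", k), collapse = ""))
})

test_that("plot-table block arithmetic and aggregation follow the convention", {
  rec <- data.frame(kmer = c("K1", "K2", "K3"), score = c(8, 8, 9.3),
                    direction = c(1L, 1L, -1L))
  plc <- data.frame(kmer = c("K1", "K2", "K3"),
                    target = "chr1", position = c(12001, 19999, 20000),
                    strand = "+")
  pt <- plot_table(rec, plc, block = 1e4, report_floor = 6)
  # 12001 and 19999 share block 1; 20000 (1-based) still belongs to block 1
  # under 0-based half-open blocks [10000, 20000)
  expect_identical(pt$x[pt$score == 8], 1)
  expect_identical(pt$count[pt$score == 8], 2L)
  expect_identical(pt$x[pt$score == 9.3], 1)
  # 1-based block start legend
  expect_true(all(pt$block_start == pt$x * 1e4 + 1))
  # position 20001 opens the next block
  plc2 <- plc; plc2$position[3] <- 20001
  pt2 <- plot_table(rec, plc2, block = 1e4)
  expect_identical(pt2$x[pt2$score == 9.3], 2)
  # report floor excludes low scores
  rec$score[1] <- 5
  expect_identical(sum(plot_table(rec, plc, block = 1e4)$count), 2L)
})

test_that("anchored-mode plot table uses scaffold x-order", {
  paf <- data.frame(query = c("s1", "s2"), qlen = 100, qstart = 0, qend = 100,
                    strand = "+", target = "chr1", tlen = 1e5,
                    tstart = c(5e4, 1e4), tend = c(5.1e4, 1.1e4),
                    n_match = 100, block_len = c(100, 100), mapq = 60)
  anc <- anchor_scaffolds(paf)
  rec <- data.frame(kmer = c("K1", "K2"), score = c(7, 8), direction = 1L)
  plc <- data.frame(kmer = c("K1", "K2"), target = c("s1", "s2"),
                    position = c(10, 10), strand = "+")
  pt <- plot_table(rec, plc, mode = "anchored", anchored = anc)
  # s2 anchors earlier on chr1, so it takes x = 0
  expect_identical(pt$x[pt$target == "s2"], 0L)
  expect_identical(pt$x[pt$target == "s1"], 1L)
  expect_error(plot_table(rec, plc, mode = "anchored"), "anchored_assembly")
})

test_that("structure correction lowers confounded lineage-k-mer scores", {
  p <- small_panel()
  km <- small_matrix()
  # confounded phenotype: strong lineage shift, no causal effect
  ph <- simulate_phenotype(p$truth, carriers = character(0), effect = 0,
                           lineage_shift = 3, noise_sd = 0.5, seed = 6)
  g0 <- run_kmer_gwas(km, ph, pcs = 0, prefilter_threshold = 0.2, seed = 2)
  g3 <- run_kmer_gwas(km, ph, pcs = 3, prefilter_threshold = 0.2, seed = 2)
  # median score of candidate (lineage-patterned) k-mers drops with PCs
  expect_lt(stats::median(g3$records$score), stats::median(g0$records$score))
})

test_that("prefilter soundness: causal k-mers clear |r| > 0.2 without structure", {
  for (s in 1:5) {
    frac <- c(0.3, 0.5, 0.7, 0.4, 0.6)[s]
    p <- simulate_panel(panel_config(n_per_lineage = c(10, 10),
                                     genome_length = 1e5, divergence = 0.01,
                                     within_diversity = 0.005, het_fraction = 0,
                                     causal = list(chrom = 1, start = 4e4,
                                                   length = 2000, effect = 2,
                                                   carrier_fraction = frac),
                                     seed = 600 + s))
    km <- kmer_matrix_from_sequences(p$sequences, kmer_config(31, 1))
    # lineage_shift = 0, effect / noise_sd = 2
    ph <- simulate_phenotype(p$truth, effect = 2, lineage_shift = 0,
                             noise_sd = 1, seed = 700 + s)
    cl <- p$truth$causal_locus
    carrier <- p$truth$carriers[1]
    # interior haplotype k-mers only: windows crossing the interval edge
    # pick up carrier-private flanking variation and are not causal markers
    hap <- substr(p$sequences[[carrier]][[cl$chrom]], cl$start, cl$end)
    causal_kmers <- setdiff(count_kmers(hap, kmer_config(31, 1))$kmers,
                            count_kmers(p$reference[[cl$chrom]],
                                        kmer_config(31, 1))$kmers)
    causal_kmers <- intersect(causal_kmers, km$kmers)
    expect_gt(length(causal_kmers), 0)
    cand <- prefilter(km, ph, threshold = 0.2)
    expect_true(all(causal_kmers %in% cand$kmer),
                label = sprintf("seed %d", 600 + s))
  }
})

test_that("coverage robustness: causal peak survives 5-fold, degrades at 1-fold", {
  block <- 1e4
  survives <- logical(5); degrades <- logical(5)
  for (s in 1:5) {
    p <- simulate_panel(panel_config(n_per_lineage = c(12, 12),
                                     genome_length = 2e5, divergence = 0.01,
                                     within_diversity = 0.005, het_fraction = 0,
                                     causal = list(chrom = 1, start = 8e4,
                                                   length = 3000, effect = 3),
                                     seed = 800 + s))
    ph <- simulate_phenotype(p$truth, effect = 3, noise_sd = 1, seed = 900 + s)
    carrier <- p$truth$carriers[1]
    true_blocks <- ((p$truth$causal_locus$start - 1) %/% block) :
      ((p$truth$causal_locus$end - 1) %/% block)
    peak <- function(fold) {
      reads <- lapply(seq_along(p$sequences), function(i)
        shred_reads(p$sequences[[i]], fold_coverage = fold, read_length = 150,
                    seed = 7000 + 100 * s + i))
      names(reads) <- names(p$sequences)
      km <- kmer_matrix_from_sequences(reads, kmer_config(k = 51, min_count = 2))
      g <- run_kmer_gwas(km, ph, pcs = 3, seed = s)
      sig <- g$records[g$records$score > 2, , drop = FALSE]
      if (nrow(sig) == 0) return(list(top = NA, score = 0))
      pl <- suppressMessages(place_kmers(sig$kmer, p$sequences[[carrier]]))
      pt <- suppressMessages(plot_table(g$records, pl, block = block,
                                        report_floor = 2))
      if (nrow(pt) == 0) return(list(top = NA, score = 0))
      top <- pt[which.max(pt$score), ]
      causal_sc <- pt$score[pt$target == "chr1" & pt$x %in% true_blocks]
      list(top = if (top$target == "chr1") top$x else -1,
           score = if (length(causal_sc)) max(causal_sc) else 0)
    }
    hi <- peak(5); lo <- peak(1)
    survives[s] <- !is.na(hi$top) && hi$top %in% true_blocks
    degrades[s] <- lo$score < hi$score
  }
  expect_gte(sum(survives), 4L)
  expect_gte(sum(degrades), 4L)
})
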