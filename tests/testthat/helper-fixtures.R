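# Shared fixtures, built in code. Panels are kept small: module tests never
# need more than a few hundred kilobases of genome.

random_dna <- function(len, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# small three-lineage panel reused across module tests
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_panel(panel_config(
        n_per_lineage = c(4, 4, 4), genome_length = 6e4, n_chromosomes = 2,
        divergence = 0.01, within_diversity = 0.002, het_fraction = 0.02,
        causal = list(chrom = 1, start = 10000, length = 2000, effect = 2),
        seed = 42))
    cache
  }
})

small_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- kmer_matrix_from_sequences(small_panel()$sequences,
                                           kmer_config(k = 31, min_count = 1))
    cache
  }
})

# brute-force canonical k-mer oracle: dictionary of all windows
oracle_count_kmers <- function(seqs, k, min_count = 1) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  tab <- new.env()
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      rc <- revcomp(w)
      can <- if (w <= rc) w else rc
      tab[[can]] <- (if (is.null(tab[[can]])) 0L else tab[[can]]) + 1L
    }
  }
  keys <- ls(tab)
  sort(keys[vapply(keys, function(x) tab[[x]] >= min_count, logical(1))],
       method = "radix")
}
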