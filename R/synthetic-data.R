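# Synthetic diploid panels with known ground truth.
#
# The generator emulates the statistical structure of a three-lineage wild
# diploid panel: lineages diverge from a common ancestor by independent
# substitution (star phylogeny), accessions add within-lineage diversity,
# a causal haplotype can be planted into a carrier subset, residual
# heterozygosity and missingness are recorded in the genotype truth, and
# duplicated accessions can be cloned in for QC testing. Substitutions are
# the only mutation type, so ancestor, lineage and accession coordinates
# coincide (no indels) and the genotype matrix is exact by construction.

#' Synthetic panel configuration
#'
#' @param n_per_lineage integer vector, accessions per lineage (up to 3
#'   lineages L1/L2/L3; zeros allowed).
#' @param genome_length total genome length in bases, split evenly across
#'   chromosomes. Must be at least `10 * k` of any k-mer stage run on it.
#' @param n_chromosomes number of chromosomes.
#' @param divergence per-base substitution probability on each lineage
#'   branch from the ancestor.
#' @param within_diversity per-base probability that a position is a
#'   segregating site within a lineage. Each segregating site's derived
#'   allele is carried by a random subset of the lineage's accessions, with
#'   the subset size drawn from the neutral 1/i frequency spectrum, so the
#'   panel holds shared within-lineage polymorphism (not just
#'   accession-private mutations). Lineages with a single accession fall
#'   back to private substitution.
#' @param n_subpop subpopulations per lineage (default 2). Diversity panels
#'   are hierarchically structured; each subpopulation founder diverges from
#'   its lineage founder by `sub_divergence`, so a panel of `L` lineages has
#'   `L * n_subpop - 1` genuine structure axes for PCA to capture.
#' @param sub_divergence per-base substitution probability on each
#'   subpopulation branch (default `divergence / 3`).
#' @param het_fraction probability that a genotype call of an accession is
#'   recorded heterozygous (the consensus sequence keeps one allele).
#' @param missing_rate probability that a genotype call is set missing.
#' @param causal optional list describing a planted causal haplotype:
#'   `chrom` (index), `start` (1-based), `length` (bases), `sub_rate`
#'   (per-base substitution rate inside the haplotype, default 0.01),
#'   `carrier_fraction` (fraction of accessions carrying it, default 0.5),
#'   `effect` (phenotype-unit effect size recorded in the truth ledger).
#' @param seed integer random seed; identical configurations and seeds give
#'   byte-identical output.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_per_lineage = c(3, 3, 3), genome_length = 3e5,
                         n_chromosomes = 1, divergence = 0.01,
                         within_diversity = 0.005, n_subpop = 2,
                         sub_divergence = divergence / 3, het_fraction = 0.01,
                         missing_rate = 0, causal = NULL, seed = 1) {
  stopifnot(length(n_per_lineage) >= 1, length(n_per_lineage) <= 3,
            all(n_per_lineage >= 0), sum(n_per_lineage) >= 1)
  for (p in c(divergence = divergence, within_diversity = within_diversity,
              sub_divergence = sub_divergence, het_fraction = het_fraction,
              missing_rate = missing_rate))
    if (p < 0 || p > 1) stop("all probabilities must lie in [0, 1]")
  .check_scalar(genome_length, "genome_length", lower = 1)
  .check_scalar(n_chromosomes, "n_chromosomes", lower = 1)
  .check_scalar(n_subpop, "n_subpop", lower = 1)
  if (!is.null(causal)) {
    stopifnot(is.list(causal), !is.null(causal$start), !is.null(causal$length))
    causal <- utils::modifyList(list(chrom = 1L, sub_rate = 0.01,
                                     carrier_fraction = 0.5, effect = 1),
                                causal)
    chrom_len <- floor(genome_length / n_chromosomes)
    if (causal$start < 1 || causal$start + causal$length - 1 > chrom_len)
      stop("causal interval outside chromosome bounds")
  }
  structure(list(n_per_lineage = as.integer(n_per_lineage),
                 genome_length = as.integer(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 divergence = divergence, within_diversity = within_diversity,
                 n_subpop = as.integer(n_subpop),
                 sub_divergence = sub_divergence,
                 het_fraction = het_fraction, missing_rate = missing_rate,
                 causal = causal, seed = as.integer(seed)),
            class = "panel_config")
}

.BASES <- charToRaw("ACGT")

.random_seq_raw <- function(len) .BASES[sample.int(4L, len, replace = TRUE)]

# predetermine one alternative allele per position (differs from ref);
# every substitution event at a position yields the same alt, so all
# simulated sites are biallelic.
.alt_alleles <- function(ref_raw) {
  len <- length(ref_raw)
  shift <- sample.int(3L, len, replace = TRUE)
  idx <- match(ref_raw, .BASES)
  .BASES[((idx - 1L + shift) %% 4L) + 1L]
}

.mutate_raw <- function(seq_raw, alt_raw, rate) {
  if (rate <= 0) return(seq_raw)
  idx <- which(runif(length(seq_raw)) < rate)
  seq_raw[idx] <- alt_raw[idx]
  seq_raw
}

#' Simulate a structured diploid panel with ground truth
#'
#' Lineage founders are derived from a single random ancestor by independent
#' substitution processes, so lineage-private variation exists by
#' construction; accessions add within-lineage substitutions on top. If a
#' causal haplotype is configured, the same mutated ancestor segment is
#' written verbatim into every carrier, so carriers share the haplotype as an
#' exact substring and non-carriers lack it.
#'
#' @param config a [panel_config()].
#' @return An object of class `kmer_panel`: list with
#'   \describe{
#'     \item{sequences}{named list, accession id -> named character vector of
#'       chromosome sequences (the diploid consensus).}
#'     \item{reference}{ancestor chromosome sequences (named character).}
#'     \item{lineage_sequences}{lineage founder sequences, usable as mosaic
#'       donors.}
#'     \item{genotypes}{`genotype_matrix` truth at every polymorphic site.}
#'     \item{truth}{`synthetic_truth` ledger: `lineage_of`, `causal_locus`,
#'       `carriers`, `duplicates`, `mosaic_intervals`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  lineages <- paste0("L", seq_along(config$n_per_lineage))
  n_acc <- sum(config$n_per_lineage)
  chrom_len <- config$genome_length %/% config$n_chromosomes
  if (chrom_len < 10L) stop("genome_length too small for the chromosome count")
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  acc_ids <- sprintf("ACC%03d", seq_len(n_acc))
  lineage_of <- setNames(rep(lineages, config$n_per_lineage), acc_ids)

  .with_seed(config$seed, {
    ancestor <- lapply(chroms, function(ch) .random_seq_raw(chrom_len))
    names(ancestor) <- chroms
    alt <- lapply(ancestor, .alt_alleles)
    founders <- lapply(lineages, function(l)
      lapply(chroms, function(ch)
        .mutate_raw(ancestor[[ch]], alt[[ch]], config$divergence)))
    names(founders) <- lineages
    for (l in lineages) names(founders[[l]]) <- chroms
    # hierarchical substructure: subpopulation founders within each lineage
    subpop_of <- setNames(character(n_acc), acc_ids)
    sub_founders <- list()
    for (l in lineages) {
      members <- acc_ids[lineage_of == l]
      sp <- rep(seq_len(config$n_subpop), length.out = length(members))
      for (s in seq_len(config$n_subpop)) {
        key <- paste0(l, ".", s)
        sub_founders[[key]] <- if (config$sub_divergence > 0)
          lapply(chroms, function(ch)
            .mutate_raw(founders[[l]][[ch]], alt[[ch]], config$sub_divergence))
        else founders[[l]]
        names(sub_founders[[key]]) <- chroms
        subpop_of[members[sp == s]] <- key
      }
    }
    acc_seqs <- setNames(vector("list", n_acc), acc_ids)
    for (a in acc_ids) acc_seqs[[a]] <- sub_founders[[subpop_of[[a]]]]
    # shared within-lineage polymorphism: segregating sites with carriers
    # drawn from the neutral 1/i derived-allele frequency spectrum
    if (config$within_diversity > 0) {
      for (l in lineages) {
        members <- acc_ids[lineage_of == l]
        n_l <- length(members)
        for (ch in chroms) {
          seg <- which(runif(chrom_len) < config$within_diversity)
          if (length(seg) == 0L) next
          if (n_l == 1L) {
            acc_seqs[[members]][[ch]][seg] <- alt[[ch]][seg]
            next
          }
          freq_p <- (1 / seq_len(n_l - 1)) / sum(1 / seq_len(n_l - 1))
          m <- sample.int(n_l - 1L, length(seg), replace = TRUE, prob = freq_p)
          carrier_of <- lapply(m, function(mi) sample.int(n_l, mi))
          site_of_pair <- rep(seg, m)
          acc_of_pair <- unlist(carrier_of)
          per_acc <- split(site_of_pair, factor(acc_of_pair, levels = seq_len(n_l)))
          for (j in seq_len(n_l)) {
            pos <- per_acc[[j]]
            if (length(pos))
              acc_seqs[[members[j]]][[ch]][pos] <- alt[[ch]][pos]
          }
        }
      }
    }

    causal_locus <- NULL; carriers <- character(0)
    if (!is.null(config$causal)) {
      cz <- config$causal
      ch <- chroms[cz$chrom]
      span <- cz$start:(cz$start + cz$length - 1L)
      hap <- ancestor[[ch]][span]
      sub_at <- which(runif(cz$length) < cz$sub_rate)
      if (length(sub_at) == 0L) sub_at <- ceiling(cz$length / 2)
      hap[sub_at] <- alt[[ch]][span][sub_at]
      # stratified draw: carrier frequency balanced across subpopulations so
      # the planted variant is unconfounded with structure (confounding is
      # exercised separately through lineage_shift in the phenotype model)
      carriers <- unlist(lapply(split(acc_ids, subpop_of), function(members) {
        m <- round(cz$carrier_fraction * length(members))
        if (m == 0L) return(character(0))
        sample(members, m)
      }), use.names = FALSE)
      if (length(carriers) == 0L) carriers <- sample(acc_ids, 1L)
      carriers <- sort(carriers)
      for (a in carriers) acc_seqs[[a]][[ch]][span] <- hap
      causal_locus <- list(chrom = ch, start = cz$start,
                           end = cz$start + cz$length - 1L,
                           effect = cz$effect)
    }

    # genotype truth: sites = positions where any accession differs from the
    # ancestor; per-site alt allele is predetermined, so sites are biallelic
    sites <- list(); calls <- list()
    for (ch in chroms) {
      ref_ch <- ancestor[[ch]]
      diff_any <- rep(FALSE, chrom_len)
      for (a in acc_ids) diff_any <- diff_any | (acc_seqs[[a]][[ch]] != ref_ch)
      pos <- which(diff_any)
      if (length(pos) == 0L) next
      cm <- matrix(0L, nrow = length(pos), ncol = n_acc,
                   dimnames = list(NULL, acc_ids))
      for (j in seq_len(n_acc)) {
        b <- acc_seqs[[j]][[ch]][pos]
        cm[, j] <- ifelse(b == ref_ch[pos], 0L,
                          ifelse(b == alt[[ch]][pos], 2L, NA_integer_))
      }
      sites[[ch]] <- data.frame(
        chrom = ch, pos = pos,
        ref = rawToChar(ref_ch[pos], multiple = TRUE),
        alt = rawToChar(alt[[ch]][pos], multiple = TRUE),
        stringsAsFactors = FALSE)
      calls[[ch]] <- cm
    }
    sites <- do.call(rbind, sites)
    calls <- do.call(rbind, calls)
    if (is.null(sites)) {  # monomorphic panel: empty but well-formed truth
      sites <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0))
      calls <- matrix(integer(0), 0L, n_acc, dimnames = list(NULL, acc_ids))
    }
    rownames(sites) <- NULL

    # residual heterozygosity and missingness overlays on the call matrix
    if (config$het_fraction > 0) {
      flip <- matrix(runif(length(calls)) < config$het_fraction, nrow(calls))
      calls[flip & !is.na(calls)] <- 1L
    }
    if (config$missing_rate > 0) {
      miss <- matrix(runif(length(calls)) < config$missing_rate, nrow(calls))
      calls[miss] <- NA_integer_
    }

    seq_chr <- lapply(acc_seqs, function(s) vapply(s, rawToChar, character(1)))
    truth <- structure(list(lineage_of = lineage_of, subpop_of = subpop_of,
                            causal_locus = causal_locus, carriers = carriers,
                            duplicates = list(), mosaic_intervals = NULL),
                       class = "synthetic_truth")
    structure(list(sequences = seq_chr,
                   reference = vapply(ancestor, rawToChar, character(1)),
                   lineage_sequences = lapply(founders, function(s)
                     vapply(s, rawToChar, character(1))),
                   alt_alleles = vapply(alt, rawToChar, character(1)),
                   genotypes = genotype_matrix(sites, calls),
                   truth = truth, config = config),
              class = "kmer_panel")
  })
}

#' @export
print.kmer_panel <- function(x, ...) {
  cat(sprintf("<kmer_panel> %d accessions, %d chromosome(s) x %d bp, %d truth sites\n",
              length(x$sequences), x$config$n_chromosomes,
              x$config$genome_length %/% x$config$n_chromosomes,
              nrow(x$genotypes$sites)))
  invisible(x)
}

#' Simulate a quantitative phenotype over a panel
#'
#' phenotype = baseline + effect * carrier_indicator + lineage_shift +
#' Gaussian(0, noise_sd), keyed by accession.
#'
#' @param truth a `synthetic_truth` (for the lineage labels).
#' @param carriers accession ids carrying the causal haplotype; must be a
#'   subset of the panel accessions.
#' @param effect additive effect of carrying the haplotype.
#' @param lineage_shift per-lineage phenotype offset: a single number applied
#'   as 0 for L1 and `lineage_shift * (lineage index - 1)` otherwise, or a
#'   named vector over lineages.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param baseline grand mean (default 10 phenotype units).
#' @param seed integer seed.
#' @return data.frame with columns `accession`, `value`.
#' @export
simulate_phenotype <- function(truth, carriers = truth$carriers, effect = 1,
                               lineage_shift = 0, noise_sd = 1, baseline = 10,
                               seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  acc <- names(truth$lineage_of)
  if (!all(carriers %in% acc)) stop("carriers must be a subset of the panel accessions")
  lin <- truth$lineage_of
  lineages <- sort(unique(lin))
  if (length(lineage_shift) == 1L && is.null(names(lineage_shift)))
    lineage_shift <- setNames(lineage_shift * (seq_along(lineages) - 1), lineages)
  if (!all(lineages %in% names(lineage_shift)))
    stop("lineage_shift must cover every lineage")
  .with_seed(seed, {
    value <- baseline + effect * as.numeric(acc %in% carriers) +
      unname(lineage_shift[lin]) + rnorm(length(acc), 0, noise_sd)
    data.frame(accession = acc, value = value, stringsAsFactors = FALSE)
  })
}

#' Shred sequences into error-free reads
#'
#' Reads are sampled uniformly over positions and strands so that total bases
#' approximate `fold_coverage` times the genome length (within one read); at
#' least one read is always emitted. Reads are exact substrings of the source
#' or its reverse complement (no error model; an optional per-base
#' substitution rate exercises the multiplicity filter).
#'
#' @param seqs named character vector of source sequences (one accession).
#' @param fold_coverage target coverage (> 0).
#' @param read_length read length in bases; must be >= the k of any k-mer
#'   stage that will consume the reads.
#' @param seed integer seed.
#' @param error_rate optional per-base substitution rate (default 0).
#' @return Character vector of reads.
#' @export
shred_reads <- function(seqs, fold_coverage, read_length = 150, seed = 1,
                        error_rate = 0) {
  .check_scalar(fold_coverage, "fold_coverage")
  if (fold_coverage <= 0) stop("'fold_coverage' must be > 0")
  .check_scalar(read_length, "read_length", lower = 1)
  lens <- nchar(seqs)
  if (any(lens < read_length)) stop("read_length exceeds a source sequence length")
  total <- sum(lens)
  n_reads <- max(1L, as.integer(ceiling(fold_coverage * total / read_length)))
  .with_seed(seed, {
    src <- sample.int(length(seqs), n_reads, replace = TRUE,
                      prob = lens / total)
    start <- floor(runif(n_reads) * (lens[src] - read_length + 1)) + 1
    rc <- runif(n_reads) < 0.5
    reads <- substring(seqs[src], start, start + read_length - 1)
    reads[rc] <- .rev_comp(reads[rc])
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        rr <- charToRaw(r)
        idx <- which(runif(length(rr)) < error_rate)
        if (length(idx)) rr[idx] <- .alt_alleles(rr)[idx]
        rawToChar(rr)
      }, character(1), USE.NAMES = FALSE)
    }
    unname(reads)
  })
}

#' Build a mosaic chromosome from lineage donor segments
#'
#' The mosaic is a positional copy: segment i covers mosaic coordinates
#' `[cursor, cursor + length)` and is copied from the same coordinates of its
#' donor lineage sequence, so donor-private variants ride along with each
#' segment. Truth intervals are returned in mosaic (= donor) coordinates.
#'
#' @param donors named list or character vector: lineage label -> donor
#'   chromosome sequence.
#' @param segment_plan data.frame with columns `length` (bases) and `donor`
#'   (lineage label present in `donors`).
#' @return List with `sequence` (the mosaic chromosome) and `intervals`
#'   (data.frame `start`, `end` 1-based inclusive, `donor`), non-overlapping
#'   and tiling the mosaic.
#' @export
make_mosaic <- function(donors, segment_plan) {
  donors <- unlist(donors)
  stopifnot(is.data.frame(segment_plan),
            all(c("length", "donor") %in% names(segment_plan)))
  if (!all(segment_plan$donor %in% names(donors)))
    stop("every planned donor lineage needs a donor sequence")
  total <- sum(segment_plan$length)
  if (any(nchar(donors[unique(segment_plan$donor)]) < total))
    stop("plan longer than a donor sequence")
  cursor <- 1L
  pieces <- character(nrow(segment_plan))
  iv <- segment_plan
  for (i in seq_len(nrow(segment_plan))) {
    len <- as.integer(segment_plan$length[i])
    pieces[i] <- substr(donors[[segment_plan$donor[i]]], cursor, cursor + len - 1L)
    iv$start[i] <- cursor
    iv$end[i] <- cursor + len - 1L
    cursor <- cursor + len
  }
  list(sequence = paste(pieces, collapse = ""),
       intervals = iv[, c("start", "end", "donor")])
}

#' Clone an accession with optional noise (redundancy planting)
#'
#' Copies an accession's sequences, substituting bases at `mismatch_rate`,
#' appends it to the panel, re-derives its genotype calls at the panel's
#' truth sites, and registers the pair in the truth ledger's duplicate list.
#'
#' @param panel a `kmer_panel`.
#' @param accession id of the accession to clone.
#' @param new_id id of the clone (default `<accession>_dup`).
#' @param mismatch_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @return The modified `kmer_panel`.
#' @export
clone_with_noise <- function(panel, accession, new_id = paste0(accession, "_dup"),
                             mismatch_rate = 0, seed = 1) {
  stopifnot(inherits(panel, "kmer_panel"), accession %in% names(panel$sequences))
  if (mismatch_rate < 0 || mismatch_rate >= 1) stop("'mismatch_rate' must be in [0, 1)")
  if (new_id %in% names(panel$sequences)) stop("'new_id' already present")
  .with_seed(seed, {
    src <- panel$sequences[[accession]]
    chrs <- names(src)
    sites <- panel$genotypes$sites
    call <- panel$genotypes$calls[, accession]  # clone inherits het overlay
    clone <- setNames(character(length(chrs)), chrs)
    for (ch in chrs) {
      rr <- charToRaw(src[[ch]])
      # mutate toward the panel-wide alt allele of each position so clone
      # mismatches register as opposite genotype calls, not no-calls
      alt <- if (!is.null(panel$alt_alleles)) charToRaw(panel$alt_alleles[[ch]])
             else .alt_alleles(rr)
      idx <- which(runif(length(rr)) < mismatch_rate)
      rr[idx] <- alt[idx]
      clone[[ch]] <- rawToChar(rr)
      hit <- sites$chrom == ch & sites$pos %in% idx
      call[hit] <- 2L  # mutated consensus base is the alt allele
    }
    panel$sequences[[new_id]] <- clone
    calls <- cbind(panel$genotypes$calls, call)
    colnames(calls) <- c(colnames(panel$genotypes$calls), new_id)
    panel$genotypes <- genotype_matrix(sites, calls)
    panel$truth$lineage_of[new_id] <- panel$truth$lineage_of[[accession]]
    panel$truth$duplicates <- c(panel$truth$duplicates,
                                list(c(accession, new_id)))
    if (accession %in% panel$truth$carriers)
      panel$truth$carriers <- sort(c(panel$truth$carriers, new_id))
    panel
  })
}
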