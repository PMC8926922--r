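# File-format plumbing: FASTA via Biostrings, phenotype/QC tables as TSV,
# the truth ledger as JSON, genotype truth as minimal VCF, the k-mer matrix
# as a packed binary file plus a TSV dump for small matrices.

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings; sequences are handled package-wide as
#' named uppercase character vectors. Writing wraps at 60 columns.
#'
#' @param path file path (gzip allowed on read).
#' @param seqs named character vector of sequences.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Write a phenotype table (2-column TSV: accession, value)
#' @param phenotype data.frame with `accession`, `value`.
#' @param path output path.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  write.table(phenotype[, c("accession", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#' @param path 2-column TSV (accession, value), with or without header.
#' @return Named numeric vector.
#' @export
read_phenotype_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("\t-?[0-9.]+([eE][+-]?[0-9]+)?$", first)
  d <- read.table(path, sep = "\t", header = header,
                  col.names = c("accession", "value"),
                  stringsAsFactors = FALSE)
  setNames(as.numeric(d$value), d$accession)
}

#' Write the synthetic truth ledger as JSON
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a genotype matrix as minimal VCF
#'
#' CHROM, POS (1-based), REF, ALT and per-accession GT fields coded 0/0,
#' 0/1, 1/1 and ./. for missing.
#'
#' @param matrix a `genotype_matrix`.
#' @param path output path (plain text).
#' @export
write_genotype_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  calls <- matrix$calls
  gt <- matrix(gt_code[calls + 1L], nrow(calls))
  gt[is.na(calls)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(calls)), collapse = "\t")),
             con)
  body <- cbind(matrix$sites$chrom, matrix$sites$pos, ".",
                matrix$sites$ref, matrix$sites$alt, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Uses VariantAnnotation; multiallelic records are skipped with a logged
#' count, remaining GT strings are decoded to 0/1/2/NA.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return A `genotype_matrix`; attribute `n_multiallelic`.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  keep <- n_alt == 1L
  n_multi <- sum(!keep)
  if (n_multi > 0) message(sprintf("%d multiallelic record(s) skipped", n_multi))
  vcf <- vcf[keep, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dec <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  calls <- matrix(unname(dec[gt]), nrow = nrow(gt),
                  dimnames = list(NULL, colnames(gt)))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    stringsAsFactors = FALSE)
  out <- genotype_matrix(sites, calls)
  attr(out, "n_multiallelic") <- n_multi
  out
}

# 2-bit packing of ACGT strings into raw bytes (4 bases per byte)
.pack_kmers <- function(kmers, k) {
  codes <- matrix(0L, nrow = k, ncol = length(kmers))
  m <- vapply(kmers, charToRaw, raw(k))
  lut <- integer(256); lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  codes[] <- lut[as.integer(m) + 1L]
  nbytes <- ceiling(k / 4)
  pad <- nbytes * 4 - k
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, ncol(codes)))
  dim(codes) <- c(4, nbytes, length(kmers))
  packed <- codes[1, , ] * 64L + codes[2, , ] * 16L + codes[3, , ] * 4L + codes[4, , ]
  as.raw(packed)
}

.unpack_kmers <- function(bytes, k, n) {
  nbytes <- ceiling(k / 4)
  v <- as.integer(bytes)
  dim(v) <- c(nbytes, n)
  codes <- array(0L, c(4L, nbytes, n))  # interleave: 4 bases per byte
  codes[1, , ] <- v %/% 64L %% 4L
  codes[2, , ] <- v %/% 16L %% 4L
  codes[3, , ] <- v %/% 4L %% 4L
  codes[4, , ] <- v %% 4L
  dim(codes) <- c(nbytes * 4, n)
  codes <- codes[seq_len(k), , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  apply(codes, 2L, function(cc) paste(bases[cc + 1L], collapse = ""))
}

#' Write/read the k-mer matrix in packed binary form
#'
#' Header: magic `"KMPA"`, format version, k, row count, column count and
#' the accession ids; body: per row, the 2-bit-packed k-mer
#' (`ceiling(k/4)` bytes) followed by a `ceiling(n/8)`-byte presence bitset.
#'
#' @param matrix a `kmer_matrix`.
#' @param path output path.
#' @return `read_kmer_matrix`: a `kmer_matrix`.
#' @export
write_kmer_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  nr <- nrow(matrix$presence); n <- length(matrix$accessions)
  writeBin(charToRaw("KMPA"), con)
  writeBin(c(1L, matrix$k, nr, n), con, size = 4L)
  ids <- charToRaw(paste(matrix$accessions, collapse = "\t"))
  writeBin(length(ids), con, size = 4L)
  writeBin(ids, con)
  if (nr > 0) {
    packed <- .pack_kmers(matrix$kmers, matrix$k)
    dim(packed) <- c(ceiling(matrix$k / 4), nr)
    bits <- packBits(rbind(matrix(as.integer(matrix$presence) |> as.raw(),
                                  nr, n) |> t(),
                           matrix(as.raw(0), (-n) %% 8, nr)), type = "raw")
    dim(bits) <- c(ceiling(n / 8), nr)
    writeBin(as.raw(rbind(packed, bits)), con)
  }
  invisible(path)
}

#' @rdname write_kmer_matrix
#' @export
read_kmer_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "KMPA") stop("not a k-mer matrix file")
  hdr <- readBin(con, "integer", 4L, size = 4L)
  version <- hdr[1]; k <- hdr[2]; nr <- hdr[3]; n <- hdr[4]
  if (version != 1L) stop("unsupported format version")
  id_len <- readBin(con, "integer", 1L, size = 4L)
  ids <- strsplit(rawToChar(readBin(con, "raw", id_len)), "\t")[[1]]
  kb <- ceiling(k / 4); bb <- ceiling(n / 8)
  body <- readBin(con, "raw", nr * (kb + bb))
  dim(body) <- c(kb + bb, nr)
  kmers <- if (nr > 0) .unpack_kmers(body[seq_len(kb), , drop = FALSE], k, nr)
           else character(0)
  pres <- matrix(as.raw(0), nr, n)
  if (nr > 0) {
    bits <- rawToBits(as.raw(body[kb + seq_len(bb), , drop = FALSE]))
    dim(bits) <- c(bb * 8, nr)
    pres[] <- t(bits[seq_len(n), , drop = FALSE] != as.raw(0)) |> as.integer() |> as.raw()
  }
  .new_kmer_matrix(kmers, pres, ids, k)
}

#' TSV dump of a (small) k-mer matrix
#' @param matrix a `kmer_matrix`.
#' @param path output path.
#' @export
write_kmer_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  d <- data.frame(kmer = matrix$kmers,
                  matrix(as.integer(matrix$presence), nrow(matrix$presence),
                         dimnames = list(NULL, matrix$accessions)),
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick form with integer supports as node labels
#' @param tree an [ape::phylo], e.g. from [bootstrap_tree()].
#' @param path output path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write segment assignments as BED (0-based half-open)
#' @param assignments a `segment_assignment`.
#' @param chrom chromosome name for column 1.
#' @param path output path.
#' @export
write_segments_bed <- function(assignments, chrom, path) {
  extra <- setdiff(names(assignments), c("start", "end"))
  d <- data.frame(chrom = chrom, start = assignments$start - 1L,
                  end = assignments$end, assignments[, extra, drop = FALSE])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
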