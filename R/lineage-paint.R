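# Lineage painting: identify lineage-specific k-mers in the diploid panel
# and assign 100-kb windows of a (hexaploid-like) target chromosome to the
# lineage that contributes the most lineage-specific k-mers.

#' Usable k-mers of a target subgenome
#'
#' A k-mer is usable when it occurs at exactly one locus across the
#' designated subgenome chromosomes (single-locus rule, computed over the
#' subgenome only). With landrace filtering enabled, the usable set is
#' additionally intersected with the union of presence over the landrace
#' k-mer sets, which masks recent alien introgressions.
#'
#' @param assembly named character vector: the subgenome chromosome
#'   sequences.
#' @param k k-mer length (default 51).
#' @param landrace_sets optional list of character vectors (canonical k-mer
#'   sets of landrace read data).
#' @return Character vector of canonical usable k-mers.
#' @export
usable_kmers <- function(assembly, k = 51, landrace_sets = NULL) {
  if (length(assembly) == 0L) stop("empty subgenome")
  occ <- occurrence_count_cpp(as.character(assembly), as.integer(k))
  usable <- occ$kmers[occ$counts == 1L]
  if (!is.null(landrace_sets)) {
    lr <- unique(unlist(landrace_sets))
    usable <- usable[usable %in% lr]
  }
  usable
}

#' Lineage-specific k-mer sets
#'
#' A k-mer is Lx-specific iff it is present in at least one accession of
#' lineage Lx and in zero accessions of every other lineage; all remaining
#' k-mers are shared. The cells partition the matrix k-mer space.
#'
#' @param matrix a `kmer_matrix`.
#' @param labels named character vector accession -> lineage label.
#' @return Object of class `lineage_kmer_sets`: `specific` (named list of
#'   character vectors per lineage), `shared`, `lineages`.
#' @export
lineage_specific <- function(matrix, labels) {
  stopifnot(inherits(matrix, "kmer_matrix"))
  labels <- labels[matrix$accessions]
  if (anyNA(labels)) stop("every accession must be labeled")
  lineages <- sort(unique(labels))
  inlin <- vapply(lineages, function(l)
    rows_any_cpp(matrix$presence, which(labels == l) - 1L),
    logical(nrow(matrix$presence)))
  n_in <- rowSums(inlin)
  specific <- lapply(seq_along(lineages), function(j)
    matrix$kmers[inlin[, j] & n_in == 1L])
  names(specific) <- lineages
  structure(list(specific = specific,
                 shared = matrix$kmers[n_in != 1L],
                 lineages = lineages),
            class = "lineage_kmer_sets")
}

#' @export
print.lineage_kmer_sets <- function(x, ...) {
  cat("<lineage_kmer_sets>",
      paste(sprintf("%s: %d", x$lineages,
                    vapply(x$specific, length, integer(1))), collapse = ", "),
      sprintf("| shared: %d\n", length(x$shared)))
  invisible(x)
}

#' Assign chromosome segments to donor lineages
#'
#' The chromosome is divided into non-overlapping segments of `segment`
#' bases; a k-mer belongs to the segment containing its forward-strand
#' window start. Thresholds are stated against a nominal segment k-mer count
#' of `nominal_kmers` (100,000 for 100-kb segments): a segment with fewer
#' than `usable_floor * nominal_kmers` usable-and-panel-present k-mers is
#' `unassigned`; otherwise it is labeled with the lineage whose specific
#' k-mer count exceeds every other lineage's by at least `margin` (10 =
#' 0.01% of 100,000), or `unresolved` when no lineage clears the margin.
#' A trailing partial segment is evaluated with thresholds scaled by its
#' actual window count and flagged `partial`.
#'
#' @param chrom_seq single chromosome sequence (character scalar).
#' @param usable usable k-mer set from [usable_kmers()].
#' @param lineage_sets a `lineage_kmer_sets` from the diploid panel.
#' @param panel_present optional character vector of k-mers present in at
#'   least one panel accession; defaults to the union of the lineage sets.
#' @param segment segment size in bases (default 1e5); must be >= k.
#' @param usable_floor fraction of nominal k-mers that must be usable and
#'   panel-present (default 0.20).
#' @param margin absolute count by which the top lineage must exceed each
#'   other lineage (default 10).
#' @param k k-mer length (default 51).
#' @param nominal_kmers nominal k-mers per full segment (default 1e5).
#' @return data.frame of class `segment_assignment`: `start`, `end` (1-based
#'   inclusive), `n_windows`, `n_usable`, `n_usable_present`, one
#'   `n_specific_<lineage>` column per lineage, `label`, `partial`.
#' @export
assign_segments <- function(chrom_seq, usable, lineage_sets,
                            panel_present = NULL, segment = 1e5,
                            usable_floor = 0.20, margin = 10, k = 51,
                            nominal_kmers = 1e5) {
  stopifnot(inherits(lineage_sets, "lineage_kmer_sets"), length(chrom_seq) == 1L)
  if (segment < k) stop("'segment' must be >= k")
  if (is.null(panel_present))
    panel_present <- c(unlist(lineage_sets$specific, use.names = FALSE),
                       lineage_sets$shared)
  cnt <- paint_counts_cpp(chrom_seq, as.integer(k), segment,
                          usable, panel_present, lineage_sets$specific)
  L <- nchar(chrom_seq)
  n_seg <- nrow(cnt)
  starts <- (seq_len(n_seg) - 1) * segment + 1
  ends <- pmin(starts + segment - 1, L)
  lineages <- lineage_sets$lineages
  seg_len <- ends - starts + 1
  partial <- seg_len < segment
  nominal_seg <- ifelse(partial, round(nominal_kmers * seg_len / segment),
                        nominal_kmers)
  floor_abs <- usable_floor * nominal_seg
  margin_seg <- pmax(1, round(margin * nominal_seg / nominal_kmers))
  spec <- cnt[, 3 + seq_along(lineages), drop = FALSE]
  colnames(spec) <- paste0("n_specific_", lineages)
  label <- character(n_seg)
  for (i in seq_len(n_seg)) {
    if (cnt[i, 3] < floor_abs[i]) { label[i] <- "unassigned"; next }
    s <- spec[i, ]
    top <- which.max(s)
    others <- s[-top]
    label[i] <- if (length(others) == 0L || all(s[top] - others >= margin_seg[i]))
      lineages[top] else "unresolved"
  }
  out <- data.frame(start = starts, end = ends, n_windows = cnt[, 1],
                    n_usable = cnt[, 2], n_usable_present = cnt[, 3],
                    spec, label = label, partial = partial,
                    stringsAsFactors = FALSE)
  class(out) <- c("segment_assignment", "data.frame")
  out
}

#' Per-lineage contribution summary
#'
#' Percentage of lineage-assigned segments attributed to each lineage,
#' per chromosome and genome-wide. Unassigned and unresolved segments are
#' excluded from the denominator.
#'
#' @param assignments a `segment_assignment` data.frame, or a named list of
#'   them (one per chromosome).
#' @return data.frame `chrom`, one percent column per lineage,
#'   `n_assigned`; the last row (`chrom == "genome"`) is the genome-wide
#'   summary. Percentages are `NA` when no segment was lineage-assigned.
#' @export
summarize_contribution <- function(assignments) {
  if (is.data.frame(assignments)) assignments <- list(chr = assignments)
  if (is.null(names(assignments)))
    names(assignments) <- paste0("chr", seq_along(assignments))
  lineages <- sort(setdiff(unique(unlist(lapply(assignments, `[[`, "label"))),
                           c("unassigned", "unresolved")))
  all_lin <- sort(unique(c(lineages,
                           sub("^n_specific_", "",
                               grep("^n_specific_", names(assignments[[1]]),
                                    value = TRUE)))))
  one <- function(df) {
    lab <- df$label[!(df$label %in% c("unassigned", "unresolved"))]
    n <- length(lab)
    pct <- if (n == 0) setNames(rep(NA_real_, length(all_lin)), all_lin)
           else 100 * vapply(all_lin, function(l) sum(lab == l), numeric(1)) / n
    c(pct, n_assigned = n)
  }
  rows <- t(vapply(assignments, one, numeric(length(all_lin) + 1)))
  genome <- one(do.call(rbind, lapply(assignments, function(d)
    d[, c("label"), drop = FALSE])))
  out <- data.frame(chrom = c(names(assignments), "genome"),
                    rbind(rows, genome), row.names = NULL,
                    check.names = FALSE)
  out
}
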