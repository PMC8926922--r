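# Scaffold anchoring: order de novo scaffolds along a chromosome-level
# reference by each scaffold's longest alignment hit (PAF alignment block
# length), so anchored-mode association plots can be drawn.

#' Read a PAF alignment file
#'
#' Reads the 12 mandatory PAF columns (minimap2 dialect); optional SAM-style
#' tag columns are ignored. Lines with fewer than 12 fields are skipped with
#' a logged count.
#'
#' @param path path to a PAF file.
#' @return data.frame with columns `query`, `qlen`, `qstart`, `qend`,
#'   `strand`, `target`, `tlen`, `tstart`, `tend`, `n_match`, `block_len`,
#'   `mapq`; attribute `n_malformed`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 12L
  if (any(!ok))
    message(sprintf("%d malformed PAF line(s) skipped", sum(!ok)))
  rows <- lapply(fields[ok], function(f) f[1:12])
  m <- do.call(rbind, rows)
  out <- data.frame(query = m[, 1], qlen = as.numeric(m[, 2]),
                    qstart = as.numeric(m[, 3]), qend = as.numeric(m[, 4]),
                    strand = m[, 5], target = m[, 6],
                    tlen = as.numeric(m[, 7]), tstart = as.numeric(m[, 8]),
                    tend = as.numeric(m[, 9]), n_match = as.numeric(m[, 10]),
                    block_len = as.numeric(m[, 11]), mapq = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Anchor scaffolds by their longest alignment hit
#'
#' For each scaffold the PAF record with the largest alignment block length
#' wins; its target start becomes the anchor position. Ties are broken by
#' smaller target name, then smaller target start, so the result does not
#' depend on record order. Scaffolds named in `all_scaffolds` but absent
#' from the alignments are listed as unanchored.
#'
#' @param paf data.frame as produced by [read_paf()] or [internal_align()].
#' @param all_scaffolds optional character vector of every scaffold id.
#' @return An object of class `anchored_assembly`: `anchors` (data.frame
#'   `scaffold`, `chrom`, `position` (0-based target start), `hit_length`,
#'   `strand`), `unanchored`, `x_order` (scaffolds sorted by chromosome then
#'   anchor position).
#' @export
anchor_scaffolds <- function(paf, all_scaffolds = NULL) {
  stopifnot(all(c("query", "target", "tstart", "block_len", "strand") %in% names(paf)))
  if (nrow(paf) > 0) {
    ord <- order(paf$query, -paf$block_len, paf$target, paf$tstart)
    best <- paf[ord, , drop = FALSE]
    best <- best[!duplicated(best$query), , drop = FALSE]
    anchors <- data.frame(scaffold = best$query, chrom = best$target,
                          position = best$tstart, hit_length = best$block_len,
                          strand = best$strand, stringsAsFactors = FALSE)
  } else {
    anchors <- data.frame(scaffold = character(0), chrom = character(0),
                          position = numeric(0), hit_length = numeric(0),
                          strand = character(0))
  }
  anchors <- anchors[order(anchors$chrom, anchors$position, anchors$scaffold), ]
  rownames(anchors) <- NULL
  unanchored <- if (is.null(all_scaffolds)) character(0)
                else setdiff(all_scaffolds, anchors$scaffold)
  structure(list(anchors = anchors, unanchored = unanchored,
                 x_order = anchors$scaffold),
            class = "anchored_assembly")
}

#' @export
print.anchored_assembly <- function(x, ...) {
  cat(sprintf("<anchored_assembly> %d anchored, %d unanchored\n",
              nrow(x$anchors), length(x$unanchored)))
  invisible(x)
}

#' Exact-match internal aligner (desk-scale substitute)
#'
#' Seed-and-extend alignment reporting every maximal exact match of at least
#' `seed_length` bases between scaffolds and reference sequences, on both
#' strands, as PAF-equivalent records. Intended for synthetic or desk-scale
#' inputs so the anchoring stage needs no external aligner; real assemblies
#' should be aligned with minimap2 and loaded via [read_paf()].
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param reference named character vector of reference sequences.
#' @param seed_length minimum exact-match length reported (default 31).
#' @return data.frame in [read_paf()] layout (0-based half-open intervals;
#'   `n_match` = `block_len` = match length, `mapq` 255).
#' @export
internal_align <- function(scaffolds, reference, seed_length = 31) {
  stopifnot(!is.null(names(scaffolds)), !is.null(names(reference)))
  if (any(nchar(reference) < seed_length))
    stop("reference shorter than seed length")
  hits <- mem_align_cpp(as.character(scaffolds), as.character(reference),
                        as.integer(seed_length))
  data.frame(query = names(scaffolds)[hits$query_i],
             qlen = nchar(scaffolds)[hits$query_i],
             qstart = hits$qstart, qend = hits$qend,
             strand = hits$strand,
             target = names(reference)[hits$target_i],
             tlen = nchar(reference)[hits$target_i],
             tstart = hits$tstart, tend = hits$tend,
             n_match = hits$block_len, block_len = hits$block_len,
             mapq = 255, stringsAsFactors = FALSE)
}
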