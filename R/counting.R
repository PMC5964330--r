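# Read-level counting. Reads are given by their 5' position (0-based) and
# strand; each read is extended to the fragment length in the strand
# direction, and a fragment increments every window it overlaps by >= 1 bp.

# 0-based half-open fragment intervals from 5' positions
extend_fragments <- function(reads, fragment_len) {
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$start - fragment_len + 1)
  end <- ifelse(plus, reads$start + fragment_len, reads$start + 1)
  start <- pmax(0, start)
  data.frame(chrom = reads$chrom, start = start, end = end,
             sample_id = reads$sample_id, stringsAsFactors = FALSE)
}

overlaps_any <- function(frag, intervals) {
  hit <- logical(nrow(frag))
  for (ch in unique(frag$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    fi <- frag$chrom == ch
    if (!nrow(iv) || !any(fi)) next
    q <- IRanges::IRanges(frag$start[fi] + 1, frag$end[fi])
    s <- IRanges::IRanges(iv$start + 1, iv$end)
    hit[fi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Count extended reads into a window grid
#'
#' Reads are extended from their 5' end to \code{fragment_len} bp in the
#' strand direction. A read increments every window its fragment overlaps by
#' at least 1 bp. Reads on chromosomes outside the whitelist, or whose
#' fragment overlaps the blacklist, contribute nothing (they are also excluded
#' from the library size).
#'
#' @param reads data.frame with columns \code{chrom}, \code{start} (0-based 5'
#'   position), \code{strand}, \code{sample_id}.
#' @param grid A \code{window_grid} from \code{\link{tile_windows}}.
#' @param fragment_len Fragment extension length in bp (default 170).
#' @param chrom_whitelist Chromosomes to keep, or NULL for all.
#' @param blacklist Optional data.frame (chrom, start, end) of excluded
#'   regions.
#' @return A list of class \code{count_matrix}: \code{counts} (unique window x
#'   sample integer matrix), \code{windows} (window coordinates),
#'   \code{lib_sizes} (retained reads per sample), \code{n_dropped} (reads
#'   removed by the filters, per reason).
#' @export
count_reads <- function(reads, grid, fragment_len = 170,
                        chrom_whitelist = NULL, blacklist = NULL) {
  stopifnot(all(c("chrom", "start", "strand", "sample_id") %in% names(reads)))
  samples <- sort(unique(reads$sample_id))
  n0 <- nrow(reads)
  dropped <- c(whitelist = 0L, blacklist = 0L)
  if (!is.null(chrom_whitelist)) {
    keep <- reads$chrom %in% chrom_whitelist
    dropped["whitelist"] <- sum(!keep)
    reads <- reads[keep, , drop = FALSE]
  }
  frag <- extend_fragments(reads, fragment_len)
  if (!is.null(blacklist) && nrow(blacklist) && nrow(frag)) {
    bl <- overlaps_any(frag, blacklist)
    dropped["blacklist"] <- sum(bl)
    frag <- frag[!bl, , drop = FALSE]
  }
  uw <- unique_windows(grid)
  counts <- matrix(0L, nrow = nrow(uw), ncol = length(samples),
                   dimnames = list(uw$window_id, samples))
  for (ch in unique(uw$chrom)) {
    wi <- which(uw$chrom == ch)
    fr <- frag[frag$chrom == ch, , drop = FALSE]
    if (!nrow(fr)) next
    subj <- IRanges::IRanges(fr$start + 1, fr$end)
    qry <- IRanges::IRanges(uw$start[wi] + 1, uw$end[wi])
    hits <- IRanges::findOverlaps(qry, subj)
    if (length(hits)) {
      tab <- table(factor(S4Vectors::queryHits(hits), levels = seq_along(wi)),
                   factor(fr$sample_id[S4Vectors::subjectHits(hits)],
                          levels = samples))
      counts[wi, ] <- counts[wi, , drop = FALSE] + as.matrix(tab)
    }
  }
  lib <- table(factor(frag$sample_id, levels = samples))
  structure(list(counts = counts, windows = uw,
                 lib_sizes = setNames(as.numeric(lib), samples),
                 n_dropped = dropped, n_input_reads = n0),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d windows x %d samples (%s reads kept)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' Binned coverage over promoter regions
#'
#' Computes fragment coverage in fixed-size bins across each region and scales
#' it to RPKM (reads per kilobase of bin per million retained reads), the unit
#' used for TSS metaprofiles.
#'
#' @param reads Read table as in \code{\link{count_reads}} (single sample or
#'   pooled).
#' @param regions A \code{tss_regions} data.frame; all regions must have equal
#'   length.
#' @param fragment_len Fragment extension in bp.
#' @param bin_size Bin width in bp (default 10).
#' @param lib_size Library size used for RPKM scaling; defaults to
#'   \code{nrow(reads)}.
#' @return Numeric matrix genes x bins of RPKM values, rows named by gene_id.
#' @export
compute_coverage <- function(reads, regions, fragment_len = 170, bin_size = 10,
                             lib_size = nrow(reads)) {
  len <- unique(regions$end - regions$start)
  if (length(len) != 1)
    stop("regions must all have the same length for binned coverage")
  nbin <- len %/% bin_size
  frag <- extend_fragments(reads, fragment_len)
  out <- matrix(0, nrow(regions), nbin, dimnames = list(regions$gene_id, NULL))
  for (ch in unique(regions$chrom)) {
    fr <- frag[frag$chrom == ch, , drop = FALSE]
    ri <- which(regions$chrom == ch)
    if (!nrow(fr)) next
    subj <- IRanges::IRanges(fr$start + 1, fr$end)
    for (i in ri) {
      starts <- regions$start[i] + (seq_len(nbin) - 1) * bin_size
      qry <- IRanges::IRanges(starts + 1, starts + bin_size)
      out[i, ] <- IRanges::countOverlaps(qry, subj)
    }
  }
  out * 1e9 / (bin_size * lib_size)
}
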