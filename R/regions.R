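#' Build TSS-centered promoter regions
#'
#' One region of up to 2 * half_width bp is centered on each gene's TSS and
#' clipped at chromosome boundaries; clipped regions are flagged.
#'
#' @param annotation A \code{genome_annotation}.
#' @param half_width Half-width in bp (default 10000, giving 20-kb regions).
#' @return data.frame of class \code{tss_regions}: gene_id, chrom, start, end,
#'   strand, tss, clipped. Coordinates 0-based half-open.
#' @examples
#' ann <- genome_annotation(
#'   data.frame(gene_id = "g1", chrom = "chr1", tss = 50000, strand = "+"),
#'   chrom_sizes = c(chr1 = 1e6))
#' build_regions(ann, 10000)
#' @export
build_regions <- function(annotation, half_width = 10000) {
  stopifnot(inherits(annotation, "genome_annotation"), half_width > 0)
  g <- annotation$genes
  len <- annotation$chrom_sizes[g$chrom]
  start <- pmax(0, g$tss - half_width)
  end <- pmin(len, g$tss + half_width)
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = start, end = end, strand = g$strand,
                    tss = g$tss,
                    clipped = (end - start) < 2 * half_width,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tss_regions", "data.frame")
  out
}

#' Tile promoter regions into sliding windows
#'
#' Windows of the given width start every \code{spacing} bp from the region
#' start and are kept only when fully inside the region. A 20-kb region tiled
#' at 1000/100 yields 191 windows; at 150/50 it yields 398.
#'
#' @param regions A \code{tss_regions} data.frame.
#' @param width Window width in bp.
#' @param spacing Start-to-start spacing in bp.
#' @return data.frame of class \code{window_grid}: window_id, chrom, start,
#'   end, gene_id. A window overlapping two genes' regions appears once per
#'   gene (same window_id). Regions shorter than \code{width} receive zero
#'   windows and a warning.
#' @export
tile_windows <- function(regions, width, spacing) {
  stopifnot(width > 0, spacing > 0)
  too_short <- (regions$end - regions$start) < width
  if (any(too_short))
    warning(sum(too_short), " region(s) shorter than the window width ",
            "received no windows")
  pieces <- lapply(which(!too_short), function(i) {
    r <- regions[i, ]
    starts <- seq(r$start, r$end - width, by = spacing)
    data.frame(chrom = r$chrom, start = starts, end = starts + width,
               gene_id = r$gene_id, stringsAsFactors = FALSE)
  })
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               gene_id = character(0))
  out$window_id <- sprintf("%s:%d-%d", out$chrom, as.integer(out$start),
                           as.integer(out$end))
  out <- out[c("window_id", "chrom", "start", "end", "gene_id")]
  rownames(out) <- NULL
  class(out) <- c("window_grid", "data.frame")
  out
}

# unique genomic windows of a grid (drops the per-gene duplication)
unique_windows <- function(grid) {
  u <- grid[!duplicated(grid$window_id),
            c("window_id", "chrom", "start", "end")]
  rownames(u) <- NULL
  u
}
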