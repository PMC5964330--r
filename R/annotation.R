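#' Construct a genome annotation
#'
#' A genome annotation holds one TSS per gene together with chromosome
#' lengths. TSS coordinates are 0-based; strands are "+" or "-".
#'
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp. If
#'   NULL, lengths are inferred as max(tss) + 1e6 per chromosome.
#' @return An object of class \code{genome_annotation}.
#' @export
genome_annotation <- function(genes, chrom_sizes = NULL) {
  required <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("annotation is missing columns: ", paste(missing_cols, collapse = ", "))
  genes <- genes[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$tss <- as.numeric(genes$tss)
  genes$strand <- as.character(genes$strand)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in annotation: ", paste(unique(dup), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$tss < 0)) stop("tss must be >= 0")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$tss, genes$chrom, max) + 1e6
    chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  bad <- !(genes$chrom %in% names(chrom_sizes)) |
    genes$tss >= chrom_sizes[genes$chrom]
  if (any(bad))
    stop("tss outside chromosome bounds for gene(s): ",
         paste(head(genes$gene_id[bad], 5), collapse = ", "))
  structure(list(genes = genes, chrom_sizes = chrom_sizes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_sizes)))
  invisible(x)
}

#' Read a gene annotation from a tab-separated file
#'
#' Expects a header line naming at least \code{chrom}, \code{tss},
#' \code{strand} and \code{gene_id}. TSS coordinates are 0-based. Duplicate
#' gene ids are rejected.
#'
#' @param path Annotation TSV path.
#' @param chrom_sizes_path Optional two-column (chrom, length) TSV without
#'   header.
#' @return A \code{genome_annotation}.
#' @seealso \code{\link{write_annotation}}
#' @export
read_annotation <- function(path, chrom_sizes_path = NULL) {
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  if (any(is.na(tab$tss)))
    stop("malformed tss value at line ",
         which(is.na(tab$tss))[1] + 1L, " of ", path)
  sizes <- NULL
  if (!is.null(chrom_sizes_path)) {
    cs <- read.delim(chrom_sizes_path, header = FALSE,
                     stringsAsFactors = FALSE)
    sizes <- setNames(as.numeric(cs[[2]]), as.character(cs[[1]]))
  }
  genome_annotation(tab, sizes)
}

#' Write a gene annotation to a tab-separated file
#'
#' @param annotation A \code{genome_annotation}.
#' @param path Output TSV path.
#' @param chrom_sizes_path Optional path for the chromosome sizes table.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path, chrom_sizes_path = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  write_tsv(annotation$genes, path)
  if (!is.null(chrom_sizes_path)) {
    cs <- data.frame(chrom = names(annotation$chrom_sizes),
                     length = as.numeric(annotation$chrom_sizes))
    write.table(cs, chrom_sizes_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Reads BED3+ (0-based half-open). \code{track}, \code{browser} and comment
#' lines are skipped. Intervals with start >= end are rejected.
#'
#' @param path BED file path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  fields <- strsplit(lines, "\t")
  if (any(vapply(fields, length, 1L) < 3L))
    stop("BED line with fewer than 3 fields in ", path)
  out <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                    start = as.numeric(vapply(fields, `[`, "", 2L)),
                    end = as.numeric(vapply(fields, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start)) || any(is.na(out$end)))
    stop("non-numeric BED coordinates in ", path)
  bad <- out$start >= out$end
  if (any(bad))
    stop("BED interval with start >= end at data line ", which(bad)[1])
  out
}

# shared TSV helpers: header always written, never quoted, never rownames
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
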