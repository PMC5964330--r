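#' Pipeline configuration
#'
#' Collects the tunable parameters of the mark-calling pipeline with the
#' defaults used throughout: 20-kb promoter regions (half-width 10 kb),
#' 1000/100-bp windows for the broad marks (H3K27me3, H3K9me3) and 150/50-bp
#' windows for H3K4me3, a minimum of 20 reads per window summed over the
#' experiments, a 10-kb binned global background with a log2 fold-change
#' cutoff of 2, 170-bp fragment extension, and mark calls at FDR < 0.05.
#'
#' @param half_width Promoter region half-width in bp around the TSS.
#' @param windows Named list per mark of c(width, spacing) in bp.
#' @param min_total_count Minimum summed read count per window across all
#'   samples of the contrast for the window to be kept.
#' @param bg_bin_size Bin size in bp for the global background and for TMM
#'   normalization.
#' @param bg_min_log2fc Windows must exceed the background by more than this
#'   log2 fold-change (strict inequality).
#' @param fragment_len Read extension length in bp (5' end, strand-aware).
#' @param fdr_threshold A gene is marked when its region FDR is strictly below
#'   this value.
#' @param silent_threshold Genes with log2(mean RPKM + 1) strictly below this
#'   are silent.
#' @param min_mapq Minimum mapping quality for the optional alignment adapter.
#' @param pseudo_count Pseudo-count added to both rates in fold-change
#'   computations.
#' @param no_replicate_dispersion Fixed NB dispersion used when a contrast has
#'   no residual degrees of freedom.
#' @param chrom_whitelist Character vector of chromosomes to count on, or NULL
#'   for all.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return An object of class \code{pipeline_config} (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$windows$K4
#' @export
pipeline_config <- function(half_width = 10000,
                            windows = list(K4 = c(width = 150, spacing = 50),
                                           K27 = c(width = 1000, spacing = 100),
                                           K9 = c(width = 1000, spacing = 100)),
                            min_total_count = 20,
                            bg_bin_size = 10000,
                            bg_min_log2fc = 2,
                            fragment_len = 170,
                            fdr_threshold = 0.05,
                            silent_threshold = 1,
                            min_mapq = 5,
                            pseudo_count = 0.5,
                            no_replicate_dispersion = 0.05,
                            chrom_whitelist = NULL,
                            seed = 1L) {
  cfg <- list(half_width = half_width, windows = windows,
              min_total_count = min_total_count, bg_bin_size = bg_bin_size,
              bg_min_log2fc = bg_min_log2fc, fragment_len = fragment_len,
              fdr_threshold = fdr_threshold, silent_threshold = silent_threshold,
              min_mapq = min_mapq, pseudo_count = pseudo_count,
              no_replicate_dispersion = no_replicate_dispersion,
              chrom_whitelist = chrom_whitelist, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$half_width > 0, cfg$bg_bin_size > 0, cfg$fragment_len > 0,
            cfg$min_total_count >= 0, cfg$fdr_threshold > 0,
            cfg$fdr_threshold <= 1, cfg$pseudo_count >= 0,
            cfg$no_replicate_dispersion >= 0)
  for (m in names(cfg$windows)) {
    w <- cfg$windows[[m]]
    if (w[["width"]] <= 0 || w[["spacing"]] <= 0)
      stop("window width and spacing must be positive for mark ", m)
  }
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (m in names(x$windows))
    cat(sprintf("  %s windows: width %d bp, spacing %d bp\n",
                m, x$windows[[m]][["width"]], x$windows[[m]][["spacing"]]))
  cat(sprintf("  region half-width: %d bp; fragment: %d bp\n",
              x$half_width, x$fragment_len))
  cat(sprintf("  filters: >= %d reads/window; background log2FC > %g (%d-bp bins)\n",
              x$min_total_count, x$bg_min_log2fc, x$bg_bin_size))
  cat(sprintf("  mark call FDR < %g; silent log2(RPKM+1) < %g; seed %d\n",
              x$fdr_threshold, x$silent_threshold, x$seed))
  invisible(x)
}

# flat key=value serialization; unknown keys are errors on read (fail loud)
scalar_config_keys <- c("half_width", "min_total_count", "bg_bin_size",
                        "bg_min_log2fc", "fragment_len", "fdr_threshold",
                        "silent_threshold", "min_mapq", "pseudo_count",
                        "no_replicate_dispersion", "seed")

#' Write and read a pipeline configuration
#'
#' The on-disk format is a flat \code{key = value} text file. Window settings
#' are stored as \code{window.<mark>.width} / \code{window.<mark>.spacing};
#' the chromosome whitelist as a comma-separated list. Unknown keys raise an
#' error when read.
#'
#' @param cfg A \code{pipeline_config}.
#' @param path File path.
#' @return \code{read_config} returns a \code{pipeline_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lines <- character(0)
  for (k in scalar_config_keys)
    lines <- c(lines, sprintf("%s = %s", k, format(cfg[[k]], digits = 15)))
  for (m in names(cfg$windows)) {
    lines <- c(lines,
               sprintf("window.%s.width = %d", m, cfg$windows[[m]][["width"]]),
               sprintf("window.%s.spacing = %d", m, cfg$windows[[m]][["spacing"]]))
  }
  if (!is.null(cfg$chrom_whitelist))
    lines <- c(lines, sprintf("chrom_whitelist = %s",
                              paste(cfg$chrom_whitelist, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=[:space:]]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  cfg <- as.list(pipeline_config())
  win_keys <- grepl("^window\\.", keys)
  for (i in which(win_keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) != 3 || !parts[2] %in% names(cfg$windows) ||
        !parts[3] %in% c("width", "spacing"))
      stop("unknown config key: ", keys[i])
    cfg$windows[[parts[2]]][[parts[3]]] <- as.numeric(vals[i])
  }
  for (i in which(!win_keys)) {
    k <- keys[i]
    if (k == "chrom_whitelist") {
      cfg$chrom_whitelist <- strsplit(vals[i], ",")[[1]]
    } else if (k %in% scalar_config_keys) {
      cfg[[k]] <- as.numeric(vals[i])
    } else {
      stop("unknown config key: ", k)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}
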