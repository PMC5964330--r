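# Synthetic-data generators. Every generator takes an explicit integer seed
# and is bit-reproducible under it. Negative-binomial counts use the
# mean/dispersion parameterization with variance mu + phi * mu^2.

#' Default simulation settings
#'
#' The generator's study conditions: three marks with mark-specific window
#' geometry, 8-fold enrichment over input, NB dispersion 0.05, one pooled ChIP
#' sample and three input replicates per mark, and an input rate giving about
#' 20 reads per 1000-bp window.
#'
#' @param n_genes Number of genes.
#' @param fold_change Named fold-changes over input per mark (default 8 each).
#' @param dispersion NB dispersion phi (default 0.05).
#' @param input_rate Input reads per bp per sample (default 0.02, i.e. about
#'   20 per 1000-bp window).
#' @param n_chip,n_input Samples per group (defaults 1 and 3).
#' @param state_props Named per-state proportions (sum 1).
#' @param k4_sd Gaussian sd in bp of the TSS-centered H3K4me3 profile.
#' @param k27_sd Gaussian sd in bp of the TSS-centered H3K27me3 profile.
#' @return A list of settings.
#' @export
sim_config <- function(n_genes = 200,
                       fold_change = c(K4 = 8, K27 = 8, K9 = 8),
                       dispersion = 0.05,
                       input_rate = 0.02,
                       n_chip = 1, n_input = 3,
                       state_props = c("K27" = 0.08, "K4" = 0.40,
                                       "K4/K27" = 0.18, "K4/K9" = 0.04,
                                       "K4/K9/K27" = 0.05, "K9" = 0.03,
                                       "K9/K27" = 0.07, "None" = 0.15),
                       k4_sd = 500, k27_sd = 2000) {
  stopifnot(abs(sum(state_props) - 1) < 1e-8, dispersion >= 0,
            input_rate > 0)
  list(n_genes = n_genes, fold_change = fold_change, dispersion = dispersion,
       input_rate = input_rate, n_chip = n_chip, n_input = n_input,
       state_props = state_props[chromatin_states()], k4_sd = k4_sd,
       k27_sd = k27_sd)
}

#' Simulate a gene annotation with non-overlapping promoter regions
#'
#' Genes are laid out along synthetic chromosomes with a fixed start-to-start
#' spacing (default 25 kb, so 20-kb regions never overlap) and random strands.
#'
#' @param n_genes Number of genes (>= 1).
#' @param spacing TSS-to-TSS spacing in bp.
#' @param n_chrom Number of chromosomes.
#' @param half_width Promoter half-width used for the overlap flag.
#' @param chrom_size Optional fixed chromosome length; error if too small.
#' @param seed Integer seed.
#' @return list(annotation, regions, overlapping) where \code{overlapping}
#'   flags regions that overlap a neighbour (only when spacing < 2 *
#'   half_width).
#' @export
simulate_annotation <- function(n_genes, spacing = 25000, n_chrom = 4,
                                half_width = 10000, chrom_size = NULL,
                                seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(as.integer(seed))
  per_chrom <- ceiling(n_genes / n_chrom)
  margin <- half_width + 5000
  need <- margin + (per_chrom - 1) * spacing + margin
  if (!is.null(chrom_size) && chrom_size < need)
    stop("chromosome of ", chrom_size, " bp too small for ", per_chrom,
         " genes at spacing ", spacing)
  size <- if (is.null(chrom_size)) need else chrom_size
  chroms <- paste0("chr", seq_len(n_chrom))
  gene_chrom <- rep(chroms, each = per_chrom)[seq_len(n_genes)]
  gene_rank <- unlist(lapply(chroms, function(ch) seq_len(sum(gene_chrom == ch))))
  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                      chrom = gene_chrom,
                      tss = margin + (gene_rank - 1) * spacing,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      stringsAsFactors = FALSE)
  ann <- genome_annotation(genes, setNames(rep(size, n_chrom), chroms))
  regions <- build_regions(ann, half_width)
  overlapping <- rep(spacing < 2 * half_width, n_genes)
  list(annotation = ann, regions = regions, overlapping = overlapping)
}

#' Simulate chromatin-state labels
#'
#' @param gene_ids Gene ids.
#' @param state_props Named per-state proportions (default from
#'   \code{\link{sim_config}}).
#' @param seed Integer seed.
#' @return A \code{state_assignment}.
#' @export
simulate_states <- function(gene_ids, state_props = sim_config()$state_props,
                            seed = 1L) {
  set.seed(as.integer(seed))
  s <- sample(names(state_props), length(gene_ids), replace = TRUE,
              prob = state_props)
  marks <- state_to_marks(s)
  assign_states(data.frame(gene_id = gene_ids, K4 = marks$K4,
                           K27 = marks$K27, K9 = marks$K9,
                           stringsAsFactors = FALSE))
}

#' Simulate a chromatin-state transition between two cell types
#'
#' Given states in cell type A, draws states in cell type B from a
#' row-stochastic 8x8 kernel (default: stay probability \code{stay}, remainder
#' spread uniformly).
#'
#' @param states_a A \code{state_assignment}.
#' @param kernel Optional 8x8 row-stochastic matrix (rows/cols in
#'   \code{\link{chromatin_states}} order).
#' @param stay Diagonal mass of the default kernel.
#' @param seed Integer seed.
#' @return A \code{state_assignment} for cell type B.
#' @export
simulate_transition_states <- function(states_a, kernel = NULL, stay = 0.7,
                                       seed = 1L) {
  set.seed(as.integer(seed))
  sts <- chromatin_states()
  if (is.null(kernel)) {
    kernel <- matrix((1 - stay) / 7, 8, 8, dimnames = list(sts, sts))
    diag(kernel) <- stay
  }
  stopifnot(all(abs(rowSums(kernel) - 1) < 1e-8))
  sb <- vapply(as.character(states_a$state), function(s)
    sample(sts, 1, prob = kernel[s, ]), "")
  marks <- state_to_marks(sb)
  assign_states(data.frame(gene_id = states_a$gene_id, K4 = marks$K4,
                           K27 = marks$K27, K9 = marks$K9,
                           stringsAsFactors = FALSE))
}

# fold-change multiplier of mark `mark` at offset x (bp from TSS) for a gene
# in state `state`; shapes follow the observed geometry: K4 narrow and
# TSS-centered; K27 TSS-centered unless co-occurring with K9 (then covering
# the whole region); K9 broad, attenuated (half log-fold) when K4 is present.
profile_multiplier <- function(mark, state, x, cfg) {
  marks <- state_to_marks(state)
  fc <- cfg$fold_change[[mark]]
  if (mark == "K4") {
    if (!marks$K4) return(rep(1, length(x)))
    return(1 + (fc - 1) * exp(-x^2 / (2 * cfg$k4_sd^2)))
  }
  if (mark == "K27") {
    if (!marks$K27) return(rep(1, length(x)))
    if (marks$K9) return(rep(fc, length(x)))
    return(1 + (fc - 1) * exp(-x^2 / (2 * cfg$k27_sd^2)))
  }
  if (mark == "K9") {
    if (!marks$K9) return(rep(1, length(x)))
    eff <- if (marks$K4) 2^(log2(fc) / 2) else fc
    return(rep(eff, length(x)))
  }
  stop("unknown mark: ", mark)
}

rnb <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate ChIP and input window counts with planted chromatin states
#'
#' For every mark, input counts are NB around a uniform per-bp rate; ChIP
#' counts multiply the window mean by a state- and mark-specific fold-change
#' profile. Also emits disjoint genome-wide background bins (for the global
#' background filter and TMM) and 10-bp coverage tracks over the regions (for
#' metaprofiles).
#'
#' @param sim_ann Result of \code{\link{simulate_annotation}}.
#' @param states A \code{state_assignment} for these genes.
#' @param cfg Settings from \code{\link{sim_config}}.
#' @param pipeline_cfg A \code{pipeline_config} (window geometry, bin size).
#' @param coverage Also generate 10-bp coverage tracks (slower; default FALSE).
#' @param seed Integer seed.
#' @return list per mark (\code{K4}, \code{K27}, \code{K9}): \code{grid},
#'   \code{chip}, \code{input} (window x sample counts), \code{bin_counts}
#'   (bins x samples over the whole genome), \code{lib_sizes}, and optionally
#'   \code{coverage} (gene x bin RPKM of the pooled ChIP). Plus \code{truth}.
#' @export
simulate_chip_counts <- function(sim_ann, states, cfg = sim_config(),
                                 pipeline_cfg = pipeline_config(),
                                 coverage = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  regions <- sim_ann$regions
  ann <- sim_ann$annotation
  st <- setNames(as.character(states$state), states$gene_id)
  phi <- cfg$dispersion
  rate <- cfg$input_rate
  bin_size <- pipeline_cfg$bg_bin_size
  out <- list()
  for (mark in c("K4", "K27", "K9")) {
    w <- pipeline_cfg$windows[[mark]]
    grid <- tile_windows(regions, w[["width"]], w[["spacing"]])
    uw <- unique_windows(grid)
    gmap <- grid$gene_id[match(uw$window_id, grid$window_id)]
    tss <- regions$tss[match(gmap, regions$gene_id)]
    center <- (uw$start + uw$end) / 2
    mult <- vapply(seq_len(nrow(uw)), function(i)
      profile_multiplier(mark, st[[gmap[i]]], center[i] - tss[i], cfg),
      numeric(1))
    mu_in <- rate * (uw$end - uw$start)
    chip <- matrix(rnb(nrow(uw) * cfg$n_chip, rep(mu_in * mult, cfg$n_chip),
                       phi),
                   nrow(uw), cfg$n_chip,
                   dimnames = list(uw$window_id,
                                   paste0(mark, "_chip", seq_len(cfg$n_chip))))
    input <- matrix(rnb(nrow(uw) * cfg$n_input, rep(mu_in, cfg$n_input), phi),
                    nrow(uw), cfg$n_input,
                    dimnames = list(uw$window_id,
                                    paste0("input", seq_len(cfg$n_input))))
    bins <- genome_bins(ann, bin_size)
    extra <- region_bin_extra(regions, st, mark, cfg, bins, bin_size)
    mu_bin <- rate * (bins$end - bins$start)
    bin_counts <- cbind(
      matrix(rnb(nrow(bins) * cfg$n_chip,
                 rep(mu_bin + extra, cfg$n_chip), phi),
             nrow(bins), cfg$n_chip),
      matrix(rnb(nrow(bins) * cfg$n_input, rep(mu_bin, cfg$n_input), phi),
             nrow(bins), cfg$n_input))
    colnames(bin_counts) <- c(colnames(chip), colnames(input))
    lib_sizes <- colSums(bin_counts)
    entry <- list(grid = grid, chip = chip, input = input,
                  bin_counts = bin_counts, lib_sizes = lib_sizes)
    if (coverage)
      entry$coverage <- simulate_coverage(regions, st, mark, cfg)
    out[[mark]] <- entry
  }
  out$truth <- states
  out
}

genome_bins <- function(annotation, bin_size) {
  pieces <- lapply(names(annotation$chrom_sizes), function(ch) {
    len <- annotation$chrom_sizes[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# expected extra ChIP reads per background bin from enriched regions,
# distributed proportionally to bin/region overlap (flat approximation)
region_bin_extra <- function(regions, st, mark, cfg, bins, bin_size) {
  extra <- numeric(nrow(bins))
  for (i in seq_len(nrow(regions))) {
    state <- st[[regions$gene_id[i]]]
    xs <- seq(regions$start[i], regions$end[i] - 1, by = 100) + 50
    mult <- profile_multiplier(mark, state, xs - regions$tss[i], cfg)
    total_extra <- sum((mult - 1) * cfg$input_rate * 100)
    if (total_extra <= 0) next
    sel <- which(bins$chrom == regions$chrom[i] &
                   bins$end > regions$start[i] & bins$start < regions$end[i])
    ov <- pmin(bins$end[sel], regions$end[i]) -
      pmax(bins$start[sel], regions$start[i])
    extra[sel] <- extra[sel] + total_extra * ov / sum(ov)
  }
  extra
}

# expected-RPKM coverage tracks (10-bp bins) with multiplicative noise
simulate_coverage <- function(regions, st, mark, cfg, bin_size = 10,
                              noise_sd = 0.1) {
  len <- unique(regions$end - regions$start)
  stopifnot(length(len) == 1)
  nbin <- len %/% bin_size
  out <- matrix(0, nrow(regions), nbin,
                dimnames = list(regions$gene_id, NULL))
  for (i in seq_len(nrow(regions))) {
    xs <- regions$start[i] + (seq_len(nbin) - 0.5) * bin_size -
      regions$tss[i]
    mult <- profile_multiplier(mark, st[[regions$gene_id[i]]], xs, cfg)
    out[i, ] <- cfg$input_rate * bin_size * mult *
      exp(rnorm(nbin, 0, noise_sd))
  }
  out
}

#' Simulate an expression table with DE gene sets planted by state
#'
#' Per-gene log2(RPKM + 1) is normal around a state-specific mean (K4 highest,
#' bivalent intermediate, repressive-only and None lowest). Up/down regulated
#' gene sets are drawn by weighted sampling without replacement, with
#' per-state odds weights planting a chosen state enrichment.
#'
#' @param states A \code{state_assignment}.
#' @param state_means Named per-state means of log2(RPKM + 1).
#' @param sd Normal sd of log-expression around the state mean.
#' @param n_up,n_down Sizes of the regulated sets (0 to skip).
#' @param up_weights,down_weights Named per-state sampling odds (default 1;
#'   e.g. c("K4/K27" = 2.9) plants a 2.9-fold odds for bivalent genes among
#'   the upregulated set).
#' @param n_samples Expression replicates.
#' @param seed Integer seed.
#' @return list(rpkm (gene x sample), mean_rpkm, log_expr, lengths,
#'   lib_sizes, silent, sets = list(up, down), states).
#' @export
simulate_expression <- function(states,
                                state_means = c("K4" = 5, "K4/K27" = 3.5,
                                                "K4/K9" = 2.5, "K27" = 2,
                                                "K4/K9/K27" = 2,
                                                "K9/K27" = 0.9, "K9" = 0.8,
                                                "None" = 0.8),
                                sd = 0.8, n_up = 0, n_down = 0,
                                up_weights = NULL, down_weights = NULL,
                                n_samples = 3, seed = 1L) {
  set.seed(as.integer(seed))
  ids <- states$gene_id
  n <- length(ids)
  mu <- state_means[as.character(states$state)]
  log_expr <- matrix(pmax(0, rnorm(n * n_samples, mu, sd)), n, n_samples,
                     dimnames = list(ids, paste0("s", seq_len(n_samples))))
  rpkm <- 2^log_expr - 1
  mean_rpkm <- rowMeans(rpkm)
  weight_for <- function(w) {
    out <- rep(1, n)
    if (!is.null(w)) {
      idx <- as.character(states$state) %in% names(w)
      out[idx] <- w[as.character(states$state)[idx]]
    }
    out
  }
  # exact Fisher noncentral hypergeometric draw of the weighted-group count,
  # so the planted odds ratio is centered at the configured value
  rfnchyper <- function(K, M, size, odds) {
    support <- max(0, size - M):min(size, K)
    logd <- lchoose(K, support) + lchoose(M, size - support) +
      support * log(odds)
    sample(support, 1, prob = exp(logd - max(logd)))
  }
  draw <- function(size, w, exclude) {
    if (size == 0) return(character(0))
    pool <- setdiff(ids, exclude)
    if (size > length(pool)) stop("requested DE set larger than eligible genes")
    wts <- weight_for(w)[match(pool, ids)]
    uw <- unique(wts)
    if (length(uw) == 1) return(sample(pool, size))
    if (length(uw) == 2) {
      odds <- max(uw) / min(uw)
      heavy <- pool[wts == max(uw)]
      light <- pool[wts == min(uw)]
      a <- rfnchyper(length(heavy), length(light), size, odds)
      return(c(sample(heavy, a), sample(light, size - a)))
    }
    # > 2 distinct weights: sequential weighted sampling (approximate odds)
    sample(pool, size, prob = wts)
  }
  up <- draw(n_up, up_weights, character(0))
  down <- draw(n_down, down_weights, up)
  list(rpkm = rpkm, mean_rpkm = mean_rpkm,
       log_expr = log2(mean_rpkm + 1),
       lengths = setNames(rep(2000, n), ids),
       lib_sizes = setNames(rep(1e7, n_samples),
                            paste0("s", seq_len(n_samples))),
       silent = classify_silent(mean_rpkm),
       sets = list(up = up, down = down), states = states)
}

#' Simulate a single-nucleus expression matrix with planted QC outliers
#'
#' Inlier nuclei have sequencing depths spread over a bounded (uniform in log)
#' range; outliers are planted with depths far below the inlier spread, so the
#' low-tail MAD filter separates them cleanly.
#'
#' @param n_nuclei Total nuclei (default 98).
#' @param n_outliers Planted low-depth outliers (default 9).
#' @param n_genes Genes (default 2000).
#' @param seed Integer seed.
#' @return list(counts (gene x nucleus), metrics (for
#'   \code{\link{mad_qc_filter}}), truth_outlier (logical)).
#' @export
simulate_nuclei <- function(n_nuclei = 98, n_outliers = 9, n_genes = 2000,
                            seed = 1L) {
  stopifnot(n_outliers >= 0, n_outliers < n_nuclei)
  set.seed(as.integer(seed))
  outlier <- rep(FALSE, n_nuclei)
  if (n_outliers > 0)
    outlier[sample(n_nuclei, n_outliers)] <- TRUE
  depth <- ifelse(outlier, 500, round(2^runif(n_nuclei, log2(2e4), log2(2e5))))
  # heavy-tailed gene abundances: many rare genes, so the number of detected
  # genes rises smoothly with depth instead of saturating
  rel <- exp(rnorm(n_genes, 0, 2))
  rel <- rel / sum(rel)
  counts <- vapply(seq_len(n_nuclei), function(j)
    stats::rpois(n_genes, depth[j] * rel), numeric(n_genes))
  dimnames(counts) <- list(sprintf("gene%04d", seq_len(n_genes)),
                           sprintf("nuc%03d", seq_len(n_nuclei)))
  metrics <- data.frame(nucleus_id = colnames(counts),
                        log_libsize = log(colSums(counts)),
                        log_genes = log(colSums(counts > 0)),
                        stringsAsFactors = FALSE)
  list(counts = counts, metrics = metrics, truth_outlier = outlier)
}
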