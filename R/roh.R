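#' ROH caller configuration
#'
#' Defaults are the sliding-window settings of the classic SNP-array ROH
#' scan: 50-SNP windows with a per-variant hit-fraction threshold of 0.05,
#' no heterozygous call tolerated in a window, up to 5 missing calls per
#' window, a minimum segment length of 1,000 kb containing at least 20 SNPs
#' at an average density of at most 1 SNP per 150 kb, and segments split at
#' inter-SNP gaps above 1,000 kb.
#'
#' @param window_snps sliding-window size in SNPs.
#' @param window_threshold minimum fraction of overlapping windows that must
#'   be homozygous for a variant to be ROH-eligible.
#' @param min_length_kb minimum segment length (kb).
#' @param min_snps minimum SNPs per segment.
#' @param max_density_kb_per_snp maximum kb per SNP within a segment.
#' @param max_het_in_window heterozygous calls tolerated per window.
#' @param max_missing_in_window missing calls tolerated per window.
#' @param max_gap_kb maximum inter-SNP gap inside a segment (kb).
#' @return a list of class `roh_config`.
#' @export
roh_config <- function(window_snps = 50L, window_threshold = 0.05,
                       min_length_kb = 1000, min_snps = 20L,
                       max_density_kb_per_snp = 150,
                       max_het_in_window = 0L, max_missing_in_window = 5L,
                       max_gap_kb = 1000) {
  stopifnot(window_snps > 0, window_threshold > 0, window_threshold <= 1,
            min_length_kb > 0, min_snps > 0, max_density_kb_per_snp > 0,
            max_het_in_window >= 0, max_missing_in_window >= 0,
            max_gap_kb > 0)
  structure(list(
    window_snps = as.integer(window_snps),
    window_threshold = window_threshold,
    min_length_kb = min_length_kb, min_snps = as.integer(min_snps),
    max_density_kb_per_snp = max_density_kb_per_snp,
    max_het_in_window = as.integer(max_het_in_window),
    max_missing_in_window = as.integer(max_missing_in_window),
    max_gap_kb = max_gap_kb
  ), class = "roh_config")
}

# Candidate runs for one sample on one chromosome. g is the genotype vector
# (0/1/2/NA) at sorted positions pos. Returns a data.frame of segments that
# pass every filter.
roh_scan_chrom <- function(g, pos, cfg) {
  m <- length(g)
  w <- min(cfg$window_snps, m)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  # window j covers variants j .. j+w-1; homozygous if few hets/missings
  n_win <- m - w + 1L
  if (n_win < 1) return(NULL)
  cs_het <- c(0L, cumsum(het))
  cs_mis <- c(0L, cumsum(mis))
  win_het <- cs_het[(w + 1):(m + 1)] - cs_het[1:n_win]
  win_mis <- cs_mis[(w + 1):(m + 1)] - cs_mis[1:n_win]
  win_hom <- win_het <= cfg$max_het_in_window &
             win_mis <= cfg$max_missing_in_window
  # per-variant hit fraction over the windows that cover it
  cs_hom <- c(0L, cumsum(win_hom))
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(n_win, seq_len(m))
  n_cover <- hi - lo + 1L
  n_hit <- cs_hom[hi + 1L] - cs_hom[lo]
  eligible <- n_cover > 0 & (n_hit / n_cover) >= cfg$window_threshold
  # runs of eligible, non-heterozygous variants, split at large gaps
  in_run <- eligible & !het
  if (!any(in_run)) return(NULL)
  brk <- c(TRUE, diff(in_run) != 0)
  gap_split <- c(FALSE, diff(pos) > cfg$max_gap_kb * 1000)
  run_id <- cumsum(brk | gap_split)
  segs <- NULL
  for (r in unique(run_id[in_run])) {
    idx <- which(run_id == r & in_run)
    if (length(idx) < 2) next
    start_bp <- pos[idx[1]]; end_bp <- pos[idx[length(idx)]]
    n_snps <- length(idx)
    length_kb <- (end_bp - start_bp) / 1000
    if (length_kb < cfg$min_length_kb) next
    if (n_snps < cfg$min_snps) next
    if (length_kb / n_snps > cfg$max_density_kb_per_snp) next
    segs <- rbind(segs, data.frame(start_bp = start_bp, end_bp = end_bp,
                                   n_snps = n_snps, length_kb = length_kb))
  }
  segs
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH caller, per sample and chromosome: windows of
#' `window_snps` consecutive variants are scored homozygous when they hold
#' at most `max_het_in_window` heterozygous and `max_missing_in_window`
#' missing calls; each variant's hit fraction is the proportion of
#' overlapping windows scored homozygous, and variants at or above
#' `window_threshold` are ROH-eligible. Maximal runs of eligible
#' non-heterozygous variants — split at inter-SNP gaps above `max_gap_kb` —
#' become segments if they satisfy the length, SNP-count and density
#' filters. Segment bounds are the first/last SNP positions of the run.
#'
#' @param data a [gtdata] object (call-rate filtered; not MAF filtered).
#' @param cfg a [roh_config].
#' @return data.frame of class `roh_segments` with columns `sample_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_snps`, `length_kb`. Zero rows is
#'   a valid result.
#' @export
detect_roh <- function(data, cfg = roh_config()) {
  out <- NULL
  chroms <- unique(data$variants$chrom)
  for (i in seq_len(n_samples(data))) {
    for (chr in chroms) {
      jj <- which(data$variants$chrom == chr)
      segs <- roh_scan_chrom(data$geno[i, jj], data$variants$pos[jj], cfg)
      if (!is.null(segs)) {
        segs <- cbind(sample_id = data$samples$sample_id[i],
                      chromosome = chr, segs, stringsAsFactors = FALSE)
        out <- rbind(out, segs)
      }
    }
  }
  if (is.null(out))
    out <- data.frame(sample_id = character(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Autosomal genome length (kb) used for F_ROH
#'
#' The Sscrofa11.1 autosomal genome length, 2,265,770 kb.
#' @export
PIG_AUTOSOME_KB <- 2265770

#' F_ROH per sample with length-class decomposition
#'
#' `froh_total` is the summed ROH length divided by the autosomal genome
#' length; segments are decomposed into the 1-4 Mb, 4-8 Mb, 8-12 Mb and
#' > 12 Mb classes (lower bound inclusive, upper exclusive), whose shares
#' sum to the total exactly.
#'
#' @param segments a data.frame from [detect_roh()].
#' @param sample_ids sample ids to report (samples without segments get 0).
#' @param genome_length_kb autosomal genome length in kb.
#' @return data.frame: `sample_id`, `froh_total`, `froh_1_4`, `froh_4_8`,
#'   `froh_8_12`, `froh_gt_12`.
#' @export
froh <- function(segments, sample_ids,
                 genome_length_kb = PIG_AUTOSOME_KB) {
  cls_breaks <- c(0, 4000, 8000, 12000, Inf)   # kb; < 1 Mb never emitted
  rows <- lapply(sample_ids, function(s) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    cls <- cut(seg$length_kb, cls_breaks, right = FALSE,
               labels = c("froh_1_4", "froh_4_8", "froh_8_12", "froh_gt_12"))
    by_cls <- vapply(levels(cls), function(l)
      sum(seg$length_kb[cls == l]) / genome_length_kb, numeric(1))
    data.frame(sample_id = s, froh_total = sum(by_cls),
               t(by_cls), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Population-level F_ROH summary
#'
#' @param froh_table output of [froh()].
#' @param populations population label per sample, aligned with the table.
#' @return data.frame of per-population mean and standard deviation of
#'   `froh_total` and each length class, in percent.
#' @export
froh_population_summary <- function(froh_table, populations) {
  cols <- c("froh_total", "froh_1_4", "froh_4_8", "froh_8_12", "froh_gt_12")
  rows <- lapply(unique(populations), function(pop) {
    sub <- froh_table[populations == pop, cols, drop = FALSE]
    stats <- unlist(lapply(cols, function(cl)
      stats::setNames(c(mean(sub[[cl]]) * 100, stats::sd(sub[[cl]]) * 100),
                      paste0(cl, c("_mean_pct", "_sd_pct")))))
    data.frame(population = pop, t(stats), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generations since the common ancestor for an ROH length
#'
#' Autozygous segment lengths are exponential with mean 1/(2g) Morgans for a
#' common ancestor g generations back; at 1 cM per Mb, a segment of
#' `length_mb` megabases therefore points to `g = 100/(2 * length_mb)`
#' generations ago (e.g. 12 Mb segments indicate the last ~4.17
#' generations).
#'
#' @param length_mb segment length in Mb (> 0).
#' @return generations since the common ancestor.
#' @export
generations_from_length <- function(length_mb) {
  if (any(length_mb <= 0)) stop("segment length must be positive")
  100 / (2 * length_mb)
}
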