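#' Genotype-correlation linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the {0,1,2} genotype codes over
#' pairwise-complete samples (the Rogers-Huff composite-LD measure for
#' unphased genotypes). Requires at least three complete pairs and both
#' variants polymorphic among them.
#'
#' @param gi,gj integer genotype vectors over the same samples.
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 3) stop("undefined LD: fewer than 3 complete genotype pairs")
  x <- gi[ok]; y <- gj[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined LD: variant monomorphic among complete pairs")
  stats::cor(x, y)^2
}

#' Intra-chromosomal LD pairs within a distance limit
#'
#' Enumerates all pairs of variants on the same chromosome separated by at
#' most `max_distance_bp`, with their composite r-squared. Pairs whose LD is
#' undefined (monomorphic after missingness, or fewer than 3 complete pairs)
#' are skipped.
#'
#' @param data a [gtdata] object with sorted variants.
#' @param max_distance_bp maximum pair distance in bp.
#' @return data.frame with columns `variant_i`, `variant_j`, `chrom`,
#'   `distance_bp`, `r2`, `n_called`.
#' @export
ld_pairs <- function(data, max_distance_bp = 1e6) {
  g <- data$geno
  v <- data$variants
  out_i <- out_j <- integer(0)
  out_d <- integer(0); out_r2 <- out_n <- numeric(0)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    pos <- v$pos[idx]
    m <- length(idx)
    if (m < 2) next
    gc <- g[, idx, drop = FALSE]
    sds <- apply(gc, 2, stats::sd, na.rm = TRUE)
    hi <- findInterval(pos + max_distance_bp, pos)
    for (a in seq_len(m - 1)) {
      if (hi[a] <= a) next
      b <- seq(a + 1L, hi[a])
      r2 <- suppressWarnings(
        as.vector(stats::cor(gc[, a], gc[, b, drop = FALSE],
                             use = "pairwise.complete.obs"))^2)
      ncall <- colSums(!is.na(gc[, b, drop = FALSE]) & !is.na(gc[, a]))
      valid <- is.finite(r2) & ncall >= 3
      if (!any(valid)) next
      out_i <- c(out_i, idx[rep(a, sum(valid))])
      out_j <- c(out_j, idx[b[valid]])
      out_d <- c(out_d, pos[b[valid]] - pos[a])
      out_r2 <- c(out_r2, r2[valid])
      out_n <- c(out_n, ncall[valid])
    }
  }
  data.frame(
    variant_i = v$id[out_i], variant_j = v$id[out_j],
    chrom = v$chrom[out_i], distance_bp = out_d,
    r2 = out_r2, n_called = out_n,
    stringsAsFactors = FALSE
  )
}

#' Distance-binned LD decay curve
#'
#' Bins all intra-chromosomal pairs up to `max_distance_bp` by physical
#' distance and reports per-bin mean r-squared with pair counts, plus the
#' summary statistics of an LD panel: overall mean r-squared, mean pair
#' distance, and the largest bin midpoint at which mean r-squared still
#' exceeds 0.3.
#'
#' @param data a [gtdata] object.
#' @param max_distance_bp maximum pair distance (default 1 Mb).
#' @param bin_width_bp bin width (default 50 kb).
#' @return an object of class `ld_decay`: list with `bins` (data.frame
#'   `distance_lo_bp`, `distance_hi_bp`, `mean_r2`, `n_pairs`), `mean_r2`,
#'   `mean_distance_kb`, `dist_r2_above_0.3_kb`, `n_pairs`.
#' @export
ld_decay <- function(data, max_distance_bp = 1e6, bin_width_bp = 5e4) {
  pairs <- ld_pairs(data, max_distance_bp)
  breaks <- seq(0, max_distance_bp, by = bin_width_bp)
  if (breaks[length(breaks)] < max_distance_bp)
    breaks <- c(breaks, max_distance_bp)
  bin <- cut(pairs$distance_bp, breaks, include.lowest = FALSE)
  mean_r2 <- tapply(pairs$r2, bin, mean)
  n_pairs <- tapply(pairs$r2, bin, length)
  bins <- data.frame(
    distance_lo_bp = breaks[-length(breaks)],
    distance_hi_bp = breaks[-1],
    mean_r2 = as.numeric(mean_r2),
    n_pairs = ifelse(is.na(n_pairs), 0L, as.integer(n_pairs))
  )
  mid <- (bins$distance_lo_bp + bins$distance_hi_bp) / 2
  above <- which(!is.na(bins$mean_r2) & bins$mean_r2 > 0.3)
  structure(list(
    bins = bins,
    mean_r2 = mean(pairs$r2),
    mean_distance_kb = mean(pairs$distance_bp) / 1000,
    dist_r2_above_0.3_kb = if (length(above)) max(mid[above]) / 1000 else NA_real_,
    n_pairs = nrow(pairs)
  ), class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("LD decay: %d pairs, mean r2 %.3f at mean distance %.1f kb\n",
              x$n_pairs, x$mean_r2, x$mean_distance_kb))
  if (!is.na(x$dist_r2_above_0.3_kb))
    cat(sprintf("  largest distance with mean r2 > 0.3: %.1f kb\n",
                x$dist_r2_above_0.3_kb))
  invisible(x)
}

#' LD-based effective population size per past generation
#'
#' Implements the LD-recombination relation for unphased genotype panels:
#' a pair at recombination distance c Morgans reflects the effective size
#' about t = 1/(2c) generations ago, and after the sample-size correction
#' `r2_adj = mean(r2) - 1/n` the point estimate is
#' `Ne(t) = (1/(4c)) * (1/r2_adj - alpha)`. Physical distance maps to c via
#' a constant recombination rate (default 1 cM/Mb, so c = bp * 1e-8). For
#' each requested generation t, pairs with c in a relative bin of half-width
#' `bin_halfwidth` around 1/(2t) are pooled; empty bins and bins with
#' non-positive `r2_adj` are dropped with a warning.
#'
#' @param pairs data.frame from [ld_pairs()] (columns `distance_bp`, `r2`).
#' @param sample_n number of genotyped individuals behind the r2 values.
#' @param generations integer vector of target generations ago.
#' @param alpha mutation-correction constant (1 = none; 2.2 with mutation).
#' @param cm_per_mb recombination rate used to convert bp to Morgans.
#' @param bin_halfwidth relative half-width of the c bin around 1/(2t).
#' @return an object of class `ne_trajectory`: data.frame with columns
#'   `target_generation`, `t` (= 1/(2c) at the bin's realized mean c), `ne`,
#'   `mean_c_morgans`, `mean_r2_adj`, `n_pairs`, with `alpha` and `sample_n`
#'   attached as attributes.
#' @export
ne_from_ld <- function(pairs, sample_n, generations = 1:50, alpha = 1,
                       cm_per_mb = 1, bin_halfwidth = 0.2) {
  stopifnot(sample_n > 0, all(generations > 0))
  c_m <- pairs$distance_bp * cm_per_mb * 1e-8
  rows <- lapply(generations, function(t) {
    ct <- 1 / (2 * t)
    sel <- c_m >= ct * (1 - bin_halfwidth) & c_m <= ct * (1 + bin_halfwidth)
    if (!any(sel)) return(NULL)
    r2_adj <- mean(pairs$r2[sel]) - 1 / sample_n
    c_bin <- mean(c_m[sel])
    if (r2_adj <= 0) {
      warning("non-positive adjusted r2 at t = ", t, "; point dropped")
      return(NULL)
    }
    ne <- (1 / (4 * c_bin)) * (1 / r2_adj - alpha)
    # reported t honours t = 1/(2c) at the bin's realized mean c
    data.frame(target_generation = t, t = 1 / (2 * c_bin), ne = ne,
               mean_c_morgans = c_bin, mean_r2_adj = r2_adj,
               n_pairs = sum(sel))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(target_generation = numeric(0), t = numeric(0),
                      ne = numeric(0), mean_c_morgans = numeric(0),
                      mean_r2_adj = numeric(0), n_pairs = integer(0))
  attr(out, "alpha") <- alpha
  attr(out, "sample_n") <- sample_n
  class(out) <- c("ne_trajectory", "data.frame")
  out
}
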