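#' PCA-regression outlier scan
#'
#' The PCA-based selection scan: each variant's standardized genotype vector
#' is regressed on the first `K` principal-component score vectors (scores
#' are orthogonal, so per-PC simple regressions apply); the z-scores
#' (coefficient over standard error) are summarized by a robust Mahalanobis
#' distance across variants, with location by coordinate-wise medians, scale
#' by MAD, a sign-based (quadrant) robust correlation, and a small shrinkage
#' of the correlation toward the identity for stable inversion. The genomic
#' inflation factor `lambda_gc = median(d2)/qchisq(0.5, K)` rescales the
#' distances; p-values are upper-tail chi-squared with K degrees of freedom
#' and q-values follow Benjamini-Hochberg. Variants flagged at `q <= alpha`.
#'
#' The scan is usually run on the dense MAF-filtered panel while the PCs
#' come from wherever the structure was estimated; by default the PCA is
#' computed on `data` itself.
#'
#' @param data a [gtdata] object (MAF filtered; no monomorphic variants).
#' @param K number of principal components (default 3).
#' @param alpha BH false-discovery-rate level.
#' @param scores optional samples-by-K PC score matrix (e.g. from a pruned
#'   panel's [gt_pca()]); default uses `gt_pca(data, K)$scores`.
#' @param shrinkage shrinkage weight toward the identity correlation.
#' @return data.frame of class `scan_result`: per variant `id`, `chrom`,
#'   `pos`, z-score columns `z1..zK`, `d2`, `p_value`, `q_value`,
#'   `flagged`; `lambda_gc` is attached as an attribute.
#' @export
pcadapt_scan <- function(data, K = 3L, alpha = 0.05, scores = NULL,
                         shrinkage = 0.05) {
  n <- n_samples(data)
  if (K >= n) stop("K must be below the number of samples")
  if (is.null(scores)) scores <- gt_pca(data, K)$scores
  scores <- scores[, seq_len(K), drop = FALSE]
  u <- scale(scores, center = TRUE, scale = FALSE)
  unorm2 <- colSums(u^2)
  x <- scale_genotypes(data$geno)
  keep <- apply(x, 2, stats::sd) > 0
  if (any(!keep)) warning(sum(!keep), " zero-variance variant(s) excluded")
  xk <- x[, keep, drop = FALSE]
  bt <- crossprod(u, xk) / unorm2            # K x m coefficients
  fitted <- u %*% bt
  rss <- colSums((xk - fitted)^2)
  df <- n - K - 1
  sigma2 <- rss / df
  se <- sqrt(outer(1 / unorm2, sigma2))      # K x m
  z <- t(bt / se)                            # m x K
  d2 <- robust_mahalanobis(z, shrinkage)
  gif <- gif_pvalues(d2, K)
  lambda <- gif$lambda
  p <- gif$p
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    id = data$variants$id[keep], chrom = data$variants$chrom[keep],
    pos = data$variants$pos[keep], stringsAsFactors = FALSE
  )
  colnames(z) <- paste0("z", seq_len(K))
  res <- cbind(res, z)
  res$d2 <- d2
  res$p_value <- p
  res$q_value <- q
  res$flagged <- q <= alpha
  attr(res, "lambda_gc") <- lambda
  attr(res, "K") <- K
  attr(res, "alpha") <- alpha
  class(res) <- c("scan_result", "data.frame")
  res
}

# Genomic-inflation rescaling: lambda = median(d2) / chi-squared median, and
# upper-tail chi-squared p-values of d2 / lambda. A degenerate (constant)
# distance distribution carries no ranking information: every variant sits at
# the distribution's median, so p = 0.5 throughout.
gif_pvalues <- function(d2, K) {
  med <- stats::median(d2)
  chimed <- stats::qchisq(0.5, df = K)
  if (!is.finite(med) || med <= 0 || diff(range(d2)) == 0) {
    return(list(lambda = if (med > 0) med / chimed else 1,
                p = rep(0.5, length(d2))))
  }
  lambda <- med / chimed
  list(lambda = lambda,
       p = stats::pchisq(d2 / lambda, df = K, lower.tail = FALSE))
}

# Robust Mahalanobis distance of rows of z: median/MAD standardization,
# quadrant (sign) correlation mapped through sin(pi/2 * .), shrunk toward
# the identity so the matrix stays invertible.
robust_mahalanobis <- function(z, shrinkage = 0.05) {
  K <- ncol(z)
  med <- apply(z, 2, stats::median)
  s <- apply(z, 2, stats::mad)
  s[s == 0] <- 1
  w <- sweep(sweep(z, 2, med), 2, s, "/")
  if (K == 1) return(as.vector(w^2))
  sg <- sign(w)
  r <- sin(pi / 2 * crossprod(sg) / nrow(w))
  diag(r) <- 1
  r <- (1 - shrinkage) * r + shrinkage * diag(K)
  ri <- solve(r)
  rowSums((w %*% ri) * w)
}

#' Flag variants by an F_ST threshold
#'
#' Strict-inequality flagging of high-differentiation variants
#' (`fst > threshold`; the conventional high-differentiation cut is 0.5).
#'
#' @param fst numeric per-marker F_ST (NA allowed).
#' @param threshold exclusive threshold.
#' @return logical flags (NA fst is not flagged).
#' @export
fst_flags <- function(fst, threshold = 0.5) {
  !is.na(fst) & fst > threshold
}

#' Candidate windows around flagged variants
#'
#' A window of `flank_bp` upstream and downstream of each flagged variant,
#' clamped at zero, emitted in 0-based half-open BED convention: a variant
#' at position p anchors `[max(0, p - flank), p + flank)`.
#' Overlapping or adjacent windows on a chromosome merge, concatenating
#' their anchors. Merging is idempotent and order-invariant.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `id` of the
#'   flagged variants.
#' @param flank_bp flank size (default 500 kb).
#' @return data.frame with `chrom`, `start_bp` (0-based), `end_bp`
#'   (exclusive), `anchors` (comma-joined variant ids).
#' @export
candidate_windows <- function(variants, flank_bp = 5e5) {
  if (nrow(variants) == 0)
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), anchors = character(0)))
  v <- variants[order(chrom_rank(variants$chrom), variants$pos), ,
                drop = FALSE]
  start <- pmax(0, v$pos - flank_bp)
  end <- v$pos + flank_bp
  out <- NULL
  cur <- NULL
  for (i in seq_len(nrow(v))) {
    if (!is.null(cur) && cur$chrom == v$chrom[i] && start[i] <= cur$end_bp) {
      cur$end_bp <- max(cur$end_bp, end[i])
      cur$anchors <- paste(cur$anchors, v$id[i], sep = ",")
    } else {
      if (!is.null(cur))
        out <- rbind(out, as.data.frame(cur, stringsAsFactors = FALSE))
      cur <- list(chrom = v$chrom[i], start_bp = start[i], end_bp = end[i],
                  anchors = v$id[i])
    }
  }
  out <- rbind(out, as.data.frame(cur, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write candidate windows as a BED file
#'
#' @param windows output of [candidate_windows()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(windows, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", windows$chrom,
                   as.integer(windows$start_bp), as.integer(windows$end_bp),
                   windows$anchors)
  write_text_lines(lines, path)
  invisible(path)
}
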