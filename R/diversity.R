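#' Minor-allele-frequency spectrum
#'
#' Per-variant MAF over non-missing calls, binned with the conventional
#' SNP-array cut-points: fixed (MAF = 0), (0, 0.05), [0.05, 0.1),
#' [0.1, 0.2), and [0.2, 0.5].
#'
#' @param data a [gtdata] object.
#' @return list with `maf` (per-variant vector), `maf_mean`, and `spectrum`
#'   (named counts over the five bins; variants with no calls are excluded).
#' @export
maf_spectrum <- function(data) {
  maf <- variant_maf(data)
  ok <- !is.na(maf)
  m <- maf[ok]
  spectrum <- c(
    fixed = sum(m == 0),
    "lt_0.05" = sum(m > 0 & m < 0.05),
    "lt_0.1" = sum(m >= 0.05 & m < 0.1),
    "lt_0.2" = sum(m >= 0.1 & m < 0.2),
    "ge_0.2" = sum(m >= 0.2)
  )
  list(maf = maf, maf_mean = mean(m), spectrum = spectrum)
}

#' Observed/expected homozygosity, F_IS and per-sample F_HOM
#'
#' For one population: observed homozygosity `ho` is the fraction of
#' homozygous genotypes over all called (sample, variant) cells; expected
#' homozygosity `he` is the mean over variants of
#' `1 - 2p(1-p) * 2n/(2n-1)` — the unbiased small-sample estimator, with `p`
#' the sample allele frequency and `n` the called sample count at the
#' variant; `f_is = 1 - (1 - ho)/(1 - he)`, the heterozygosity-ratio form.
#' Per-sample excess homozygosity `f_hom = (O - E)/(L - E)`, with `O` the
#' sample's observed homozygous count, `E` its expected homozygous count
#' under Hardy-Weinberg over its called variants, and `L` its called-variant
#' count.
#'
#' @param data a [gtdata] object for a single population (>= 2 samples).
#' @return list with `n_samples`, `ho`, `he`, `f_is`, `f_hom_per_sample`
#'   (named numeric).
#' @export
homozygosity_and_fis <- function(data) {
  g <- data$geno
  if (nrow(g) < 2)
    stop("expected homozygosity undefined for a population of 1 sample")
  called <- !is.na(g)
  hom <- g == 0L | g == 2L
  ho <- sum(hom, na.rm = TRUE) / sum(called)
  n <- colSums(called)
  p <- colMeans(g, na.rm = TRUE) / 2
  usable <- n >= 2
  he_v <- 1 - 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
  he <- mean(he_v[usable])
  f_is <- 1 - (1 - ho) / (1 - he)
  # per-sample excess homozygosity over that sample's called variants
  e_hom <- 1 - 2 * p * (1 - p)   # plug-in HWE expectation per variant
  f_hom <- vapply(seq_len(nrow(g)), function(i) {
    ci <- called[i, ] & usable
    L <- sum(ci)
    if (L == 0) return(NA_real_)
    O <- sum(hom[i, ci], na.rm = TRUE)
    E <- sum(e_hom[ci])
    if (L == E) return(NA_real_)
    (O - E) / (L - E)
  }, numeric(1))
  names(f_hom) <- data$samples$sample_id
  list(n_samples = nrow(g), ho = ho, he = he, f_is = f_is,
       f_hom_per_sample = f_hom)
}

#' Per-population diversity summary table
#'
#' Applies [maf_spectrum()] and [homozygosity_and_fis()] within each
#' population label.
#'
#' @param data a [gtdata] object with >= 2 samples per population.
#' @return data.frame with one row per population: `population`,
#'   `n_samples`, `maf_mean`, `ho`, `he`, `f_is`, `f_hom_mean`.
#' @export
diversity_summary <- function(data) {
  pops <- unique(data$samples$population)
  rows <- lapply(pops, function(pop) {
    sub <- subset_gtdata(data, samples = which(data$samples$population == pop))
    sp <- maf_spectrum(sub)
    hz <- homozygosity_and_fis(sub)
    data.frame(population = pop, n_samples = hz$n_samples,
               maf_mean = sp$maf_mean, ho = hz$ho, he = hz$he,
               f_is = hz$f_is, f_hom_mean = mean(hz$f_hom_per_sample,
                                                 na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Weir-Cockerham (1984) two-level variance components for one biallelic
# variant. freq/het/n are per-population allele frequency of the counted
# allele, heterozygote proportion, and called sample count. Returns c(a,b,c).
wc_components <- function(freq, het, n) {
  keep <- n >= 2 & !is.na(freq)
  freq <- freq[keep]; het <- het[keep]; n <- n[keep]
  r <- length(n)
  if (r < 2) return(c(NA_real_, NA_real_, NA_real_))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * freq) / (r * nbar)
  s2 <- sum(n * (freq - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * het) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a, b, cc)
}

#' Per-marker Weir-Cockerham F_ST
#'
#' The two-level Weir-Cockerham (1984) estimator per biallelic variant:
#' variance components `a` (among populations), `b` (among individuals
#' within populations) and `c` (within individuals); per-marker
#' `fst = a/(a+b+c)`, and the global mean as the ratio of sums
#' `sum(a)/sum(a+b+c)`. Variants monomorphic across all populations (or
#' callable in fewer than two populations with >= 2 samples) have undefined
#' F_ST and are excluded from the mean.
#'
#' @param data a [gtdata] object.
#' @param populations population label per sample (defaults to the dataset's
#'   labels).
#' @return list with `per_marker` (data.frame: `id`, `chrom`, `pos`, `a`,
#'   `b`, `c`, `fst`) and `mean_fst` (ratio of sums).
#' @export
per_marker_fst <- function(data, populations = data$samples$population) {
  g <- data$geno
  pops <- unique(populations)
  if (length(pops) < 2) stop("per-marker F_ST needs >= 2 populations")
  idx <- lapply(pops, function(p) which(populations == p))
  m <- ncol(g)
  comp <- matrix(NA_real_, m, 3)
  for (j in seq_len(m)) {
    gj <- g[, j]
    n <- vapply(idx, function(i) sum(!is.na(gj[i])), numeric(1))
    freq <- vapply(idx, function(i) mean(gj[i], na.rm = TRUE) / 2, numeric(1))
    het <- vapply(idx, function(i) mean(gj[i] == 1L, na.rm = TRUE), numeric(1))
    fok <- freq[!is.na(freq)]
    if (all(fok == 0) || all(fok == 1)) next   # monomorphic overall
    comp[j, ] <- wc_components(freq, het, n)
  }
  denom <- rowSums(comp)
  fst <- ifelse(is.na(denom) | denom == 0, NA_real_, comp[, 1] / denom)
  ok <- !is.na(fst)
  per_marker <- data.frame(
    id = data$variants$id, chrom = data$variants$chrom,
    pos = data$variants$pos,
    a = comp[, 1], b = comp[, 2], c = comp[, 3], fst = fst,
    stringsAsFactors = FALSE
  )
  mean_fst <- sum(comp[ok, 1]) / sum(denom[ok])
  list(per_marker = per_marker, mean_fst = mean_fst)
}
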