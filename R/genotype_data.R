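#' Genotype dataset container
#'
#' A `gtdata` object holds a diploid, biallelic, autosomal SNP dataset:
#' an `n_samples x n_variants` integer matrix of genotype codes counting
#' copies of the "counted" allele (`allele_b`), with `NA` for missing calls,
#' plus sample metadata (id, population label) and a variant table sorted by
#' (chromosome, position).
#'
#' Genotype codes follow the minor-allele convention: `allele_b` is the less
#' frequent allele at read time (ties broken to the lexicographically later
#' character), so the per-variant MAF is simply `mean(calls) / 2`.
#' Monomorphic variants have `allele_b = NA` and all calls 0.
#'
#' @param geno integer matrix (samples x variants) with entries in
#'   `c(0L, 1L, 2L, NA)`.
#' @param samples data.frame with columns `sample_id`, `population`.
#' @param variants data.frame with columns `chrom`, `id`, `cm`, `pos`,
#'   `allele_a`, `allele_b` (allele_b may be `NA` for monomorphic variants).
#' @return An object of class `gtdata`.
#' @export
gtdata <- function(geno, samples, variants) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(
    nrow(geno) == nrow(samples),
    ncol(geno) == nrow(variants),
    all(c("sample_id", "population") %in% names(samples)),
    all(c("chrom", "id", "pos") %in% names(variants))
  )
  bad <- !(geno %in% c(0L, 1L, 2L)) & !is.na(geno)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(variants$cm)) variants$cm <- 0
  if (is.null(variants$allele_a)) variants$allele_a <- NA_character_
  if (is.null(variants$allele_b)) variants$allele_b <- NA_character_
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in dataset")
  o <- order(chrom_rank(variants$chrom), variants$pos)
  if (any(o != seq_along(o))) {
    variants <- variants[o, , drop = FALSE]
    geno <- geno[, o, drop = FALSE]
  }
  dup <- duplicated(variants[, c("chrom", "pos")])
  if (any(dup))
    stop("duplicated (chromosome, position) in variant table: ",
         paste(variants$id[dup][1], collapse = ", "))
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$id
  rownames(samples) <- NULL
  rownames(variants) <- NULL
  structure(list(geno = geno, samples = samples, variants = variants),
            class = "gtdata")
}

# order chromosomes numerically where possible, lexicographically otherwise
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  if (all(!is.na(num))) return(num)
  match(chrom, unique(sort(as.character(chrom))))
}

#' @export
print.gtdata <- function(x, ...) {
  cat(sprintf("gtdata: %d samples x %d variants, %d chromosome(s), %d population(s)\n",
              n_samples(x), n_variants(x),
              length(unique(x$variants$chrom)),
              length(unique(x$samples$population))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
summary.gtdata <- function(object, ...) {
  maf <- variant_maf(object)
  res <- list(
    n_samples = n_samples(object),
    n_variants = n_variants(object),
    populations = table(object$samples$population),
    call_rate_variant = mean(1 - colMeans(is.na(object$geno))),
    call_rate_sample = mean(1 - rowMeans(is.na(object$geno))),
    maf_mean = mean(maf, na.rm = TRUE)
  )
  class(res) <- "summary.gtdata"
  res
}

#' @export
print.summary.gtdata <- function(x, ...) {
  cat(sprintf("%d samples x %d variants\n", x$n_samples, x$n_variants))
  cat("populations:\n")
  print(x$populations)
  cat(sprintf("mean variant call rate %.4f, mean sample call rate %.4f, mean MAF %.4f\n",
              x$call_rate_variant, x$call_rate_sample, x$maf_mean))
  invisible(x)
}

#' Number of samples / variants in a gtdata object
#' @param x a `gtdata` object.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$geno)

#' Per-variant allele frequency and MAF
#'
#' `variant_freq()` returns the frequency of the counted allele (`allele_b`)
#' over non-missing calls; `variant_maf()` folds it to `min(p, 1 - p)`.
#'
#' @param x a `gtdata` object.
#' @return numeric vector of length `n_variants(x)` (NaN where no calls).
#' @export
variant_freq <- function(x) colMeans(x$geno, na.rm = TRUE) / 2

#' @rdname variant_freq
#' @export
variant_maf <- function(x) {
  p <- variant_freq(x)
  pmin(p, 1 - p)
}

#' Subset a genotype dataset
#'
#' @param x a `gtdata` object.
#' @param samples logical/integer/character index over samples (optional).
#' @param variants logical/integer/character index over variants (optional).
#' @return a `gtdata` object.
#' @export
subset_gtdata <- function(x, samples = NULL, variants = NULL) {
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, x$samples$sample_id)
    x$geno <- x$geno[samples, , drop = FALSE]
    x$samples <- x$samples[samples, , drop = FALSE]
    rownames(x$samples) <- NULL
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, x$variants$id)
    x$geno <- x$geno[, variants, drop = FALSE]
    x$variants <- x$variants[variants, , drop = FALSE]
    rownames(x$variants) <- NULL
  }
  x
}

#' Canonicalize allele coding to the minor-allele convention
#'
#' Recodes each variant so that the counted allele (`allele_b`) is the less
#' frequent allele among observed calls, breaking ties toward the
#' lexicographically later character, and drops the `allele_b` label where the
#' variant is monomorphic. This is exactly the coding [read_ped_map()]
#' produces, so canonical datasets round-trip through PED/MAP unchanged.
#'
#' @param x a `gtdata` object.
#' @return a `gtdata` object in canonical coding.
#' @export
canonicalize_coding <- function(x) {
  g <- x$geno
  nb <- colSums(g, na.rm = TRUE)                       # copies of allele_b
  na <- 2L * colSums(!is.na(g)) - nb                   # copies of allele_a
  a1 <- x$variants$allele_a
  a2 <- x$variants$allele_b
  swap <- nb > na
  tie <- nb == na & !is.na(a1) & !is.na(a2) & a2 < a1
  swap <- swap | tie
  if (any(swap)) {
    g[, swap] <- 2L - g[, swap]
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  mono <- colSums(g > 0, na.rm = TRUE) == 0
  a2[mono] <- NA_character_
  x$geno <- g
  x$variants$allele_a <- a1
  x$variants$allele_b <- a2
  x
}
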