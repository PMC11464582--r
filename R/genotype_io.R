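#' Read genotypes from PED/MAP text files
#'
#' Parses the classic whitespace-delimited PED/MAP pair. MAP rows carry
#' (chromosome, id, cM, bp); PED rows carry six pedigree fields followed by
#' two allele characters per variant. `"0"` or `"N"` denotes a missing allele;
#' a half-missing genotype (one allele missing) becomes a missing call. The
#' PED family-ID column is taken as the population label.
#'
#' The counted allele (`allele_b`) at each variant is the less frequent
#' observed allele, ties broken to the lexicographically later character, so
#' `MAF = mean(calls) / 2`. Variants whose chromosome is not in
#' `autosomes` (when given) are dropped at read time, which excludes sex
#' chromosomes, mitochondrial markers and anything else off the whitelist.
#'
#' @param ped path (optionally gzipped) or connection to the PED file.
#' @param map path (optionally gzipped) or connection to the MAP file.
#' @param autosomes optional character vector of chromosome labels to retain;
#'   `NULL` keeps everything.
#' @return a [gtdata] object.
#' @export
read_ped_map <- function(ped, map, autosomes = NULL) {
  map_lines <- read_text_lines(map)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4))
    stop("MAP format error at line ", which(nf != 4)[1],
         ": expected 4 fields, found ", nf[nf != 4][1])
  mf <- do.call(rbind, map_fields)
  variants <- data.frame(
    chrom = mf[, 1], id = mf[, 2],
    cm = as.numeric(mf[, 3]), pos = as.integer(mf[, 4]),
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, nrow(variants))
  if (!is.null(autosomes)) keep <- variants$chrom %in% as.character(autosomes)

  ped_lines <- read_text_lines(ped)
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  m <- nrow(variants)
  expected <- 6L + 2L * m
  nf <- lengths(ped_fields)
  if (any(nf != expected))
    stop("PED format error at line ", which(nf != expected)[1],
         ": expected ", expected, " fields, found ", nf[nf != expected][1])
  pf <- do.call(rbind, ped_fields)
  samples <- data.frame(
    sample_id = pf[, 2], population = pf[, 1],
    stringsAsFactors = FALSE
  )
  al <- pf[, -(1:6), drop = FALSE]
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  a1[a1 %in% c("0", "N")] <- NA
  a2[a2 %in% c("0", "N")] <- NA
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA
  a2[half] <- NA

  variants <- variants[keep, , drop = FALSE]
  a1 <- a1[, keep, drop = FALSE]
  a2 <- a2[, keep, drop = FALSE]
  m <- nrow(variants)

  geno <- matrix(NA_integer_, nrow(samples), m)
  allele_a <- allele_b <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    tab <- table(obs[!is.na(obs)])
    if (length(tab) > 2)
      stop("triallelic variant ", variants$id[j], ": alleles ",
           paste(names(tab), collapse = ", "))
    if (length(tab) == 0) next
    if (length(tab) == 1) {
      allele_a[j] <- names(tab)
      geno[, j] <- ifelse(is.na(a1[, j]), NA_integer_, 0L)
    } else {
      nm <- names(tab)
      cnt <- as.integer(tab)
      # counted allele = minor; tie -> lexicographically later character
      b <- if (cnt[1] < cnt[2]) nm[1]
           else if (cnt[2] < cnt[1]) nm[2]
           else max(nm)
      a <- setdiff(nm, b)
      allele_a[j] <- a
      allele_b[j] <- b
      geno[, j] <- (a1[, j] == b) + (a2[, j] == b)
    }
  }
  variants$allele_a <- allele_a
  variants$allele_b <- allele_b
  gtdata(geno, samples, variants)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_ped_map()]: codes 0/1/2 become `a a`, `a b`, `b b` and
#' missing calls `0 0`. Population labels go to the PED family-ID column.
#' Paths ending in `.gz` are written gzip-compressed.
#'
#' @param x a [gtdata] object.
#' @param ped,map output paths.
#' @return invisibly, the input `x`.
#' @export
write_ped_map <- function(x, ped, map) {
  v <- x$variants
  map_lines <- sprintf("%s\t%s\t%s\t%d", v$chrom, v$id,
                       format(v$cm, trim = TRUE), v$pos)
  a <- v$allele_a
  b <- ifelse(is.na(v$allele_b), v$allele_a, v$allele_b)
  a[is.na(a)] <- "A"; b[is.na(b)] <- "A"   # fully-missing variant placeholder
  n <- n_samples(x)
  g <- x$geno
  out <- character(n)
  for (i in seq_len(n)) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, b, a))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, b, a))
    out[i] <- paste(c(x$samples$population[i], x$samples$sample_id[i],
                      "0", "0", "0", "-9", rbind(x1, x2)), collapse = " ")
  }
  write_text_lines(map_lines, map)
  write_text_lines(out, ped)
  invisible(x)
}

# Reconcile one shared variant's allele pairs between two datasets.
# Returns list(action = "drop" | "ok", flipped = TRUE/FALSE,
#              invert = TRUE/FALSE (right codes become 2 - code),
#              allele_a, allele_b (merged labels)).
# Alleles may be NA when a dataset sees the variant as monomorphic.
reconcile_alleles <- function(la, lb, ra, rb) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  is_pal <- function(a, b) !is.na(a) && !is.na(b) && unname(comp[a]) == b
  # palindromic pairs (A/T, C/G): strand not inferable -> drop
  if (is_pal(la, lb) || is_pal(ra, rb))
    return(list(action = "drop"))
  lset <- stats::na.omit(c(la, lb))
  rset <- stats::na.omit(c(ra, rb))
  if (length(rset) == 0 || length(lset) == 0) {
    # one side fully missing/unobserved: nothing to reconcile
    aa <- if (length(lset)) la else ra
    bb <- if (length(lset)) lb else rb
    return(list(action = "ok", flipped = FALSE, invert = FALSE,
                allele_a = aa, allele_b = bb))
  }
  orient <- function(ra, rb, flipped) {
    # same-strand orientation of right's (ra, rb) against left's (la, lb)
    if (length(union(lset, c(ra, rb)[!is.na(c(ra, rb))])) > 2)
      return(list(action = "drop"))
    aa <- la; bb <- lb
    invert <- FALSE
    if (is.na(bb)) {
      # left monomorphic for la: merged second allele from the right pair
      extra <- setdiff(c(ra, rb)[!is.na(c(ra, rb))], la)
      if (length(extra)) bb <- extra[1]
    }
    # right codes currently count rb (or, when rb is NA, 0 = two copies of ra)
    if (is.na(rb)) {
      if (!is.na(bb) && ra == bb) invert <- TRUE
    } else {
      if (!is.na(bb) && rb == bb) invert <- FALSE
      else if (rb == aa) invert <- TRUE
      else if (is.na(bb)) invert <- FALSE       # both monomorphic, disjoint: unreachable
    }
    list(action = "ok", flipped = flipped, invert = invert,
         allele_a = aa, allele_b = bb)
  }
  # prefer the same-strand reading; fall back to the complement (flip)
  if (length(union(lset, rset)) <= 2)
    return(orient(ra, rb, flipped = FALSE))
  fa <- unname(comp[ra]); fb <- if (is.na(rb)) NA_character_ else unname(comp[rb])
  if (length(union(lset, stats::na.omit(c(fa, fb)))) <= 2) {
    res <- orient(fa, fb, flipped = TRUE)
    return(res)
  }
  list(action = "drop")
}

#' Merge two genotype datasets on shared positions
#'
#' Keeps only variants shared by (chromosome, position). Where the right
#' dataset's allele pair is the strand complement of the left's it is flipped
#' (and counted in the report); palindromic A/T and C/G variants are dropped
#' because strand cannot be inferred, as are variants with irreconcilable
#' alleles. When the same `sample_id` occurs in both inputs the duplicates
#' act as a merge control: their genotype concordance over shared variants is
#' reported and the right-hand copies are dropped from the merged dataset.
#'
#' @param left,right [gtdata] objects on the same coordinate convention.
#' @return list with elements `data` (merged [gtdata], canonical minor-allele
#'   coding) and `report` (list: `n_common_variants`, `n_flipped`,
#'   `n_dropped_incompatible`, `concordance_on_control`).
#' @export
merge_datasets <- function(left, right) {
  lkey <- paste(left$variants$chrom, left$variants$pos)
  rkey <- paste(right$variants$chrom, right$variants$pos)
  common <- intersect(lkey, rkey)
  if (length(common) == 0) stop("empty intersection: no shared variants")
  li <- match(common, lkey)
  ri <- match(common, rkey)
  lv <- left$variants[li, , drop = FALSE]
  rv <- right$variants[ri, , drop = FALSE]
  rg <- right$geno[, ri, drop = FALSE]

  n_flipped <- 0L
  drop <- logical(length(common))
  for (j in seq_along(common)) {
    rec <- reconcile_alleles(lv$allele_a[j], lv$allele_b[j],
                             rv$allele_a[j], rv$allele_b[j])
    if (rec$action == "drop") { drop[j] <- TRUE; next }
    if (rec$flipped) n_flipped <- n_flipped + 1L
    if (rec$invert) rg[, j] <- 2L - rg[, j]
    lv$allele_a[j] <- rec$allele_a
    lv$allele_b[j] <- rec$allele_b
  }
  n_dropped <- sum(drop)

  keep <- !drop
  lvk <- lv[keep, , drop = FALSE]
  lg <- left$geno[, li[keep], drop = FALSE]
  rgk <- rg[, keep, drop = FALSE]

  # merge control: duplicated sample ids
  dup <- intersect(left$samples$sample_id, right$samples$sample_id)
  concordance <- 1.0
  if (length(dup) > 0) {
    a <- lg[match(dup, left$samples$sample_id), , drop = FALSE]
    b <- rgk[match(dup, right$samples$sample_id), , drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    concordance <- if (any(ok)) mean(a[ok] == b[ok]) else 1.0
  }
  rkeep <- !(right$samples$sample_id %in% dup)
  geno <- rbind(lg, rgk[rkeep, , drop = FALSE])
  samples <- rbind(left$samples[, c("sample_id", "population")],
                   right$samples[rkeep, c("sample_id", "population")])
  merged <- canonicalize_coding(gtdata(geno, samples, lvk))
  report <- list(
    n_common_variants = length(common),
    n_flipped = n_flipped,
    n_dropped_incompatible = n_dropped,
    concordance_on_control = concordance
  )
  list(data = merged, report = report)
}

# --- small text helpers -----------------------------------------------------

read_text_lines <- function(src) {
  if (inherits(src, "connection")) return(readLines(src, warn = FALSE))
  con <- if (grepl("\\.gz$", src)) gzfile(src, "rt") else file(src, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_text_lines <- function(lines, dest) {
  if (inherits(dest, "connection")) { writeLines(lines, dest); return(invisible()) }
  con <- if (grepl("\\.gz$", dest)) gzfile(dest, "wt") else file(dest, "wt")
  on.exit(close(con))
  writeLines(lines, con)
}
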