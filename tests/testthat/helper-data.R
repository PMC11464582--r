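# Small in-code fixtures shared across the suite.

# Build a gtdata object from a genotype matrix with evenly spaced variants.
make_gt <- function(geno, populations = rep("POP1", nrow(geno)),
                    chrom = "1", spacing_bp = 1e5, start_bp = 1e5,
                    allele_a = "A", allele_b = "G") {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  gtdata(
    geno,
    samples = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                         population = populations,
                         stringsAsFactors = FALSE),
    variants = data.frame(chrom = rep(chrom, m),
                          id = sprintf("v%03d", seq_len(m)),
                          cm = 0,
                          pos = as.integer(start_bp + spacing_bp * (seq_len(m) - 1)),
                          allele_a = allele_a, allele_b = allele_b,
                          stringsAsFactors = FALSE)
  )
}

# Write PED/MAP text from raw character lines and read it back.
read_from_lines <- function(ped_lines, map_lines, ...) {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  read_ped_map(ped, map, ...)
}

# Independent textbook Weir-Cockerham (1984) per-variant components:
# direct transcription of the published formulas, kept free of the package's
# internals so it can serve as an oracle.
oracle_wc <- function(geno, pops) {
  u <- unique(pops)
  r <- length(u)
  out <- matrix(NA_real_, ncol(geno), 3)
  for (j in seq_len(ncol(geno))) {
    n <- p <- h <- numeric(r)
    for (i in seq_len(r)) {
      g <- geno[pops == u[i], j]
      g <- g[!is.na(g)]
      n[i] <- length(g)
      p[i] <- mean(g) / 2
      h[i] <- mean(g == 1)
    }
    if (any(n < 2)) next
    if (all(p %in% c(0, 1))) next
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) * s2 / r - (2 * nbar - 1) * hbar / (4 * nbar))
    cc <- hbar / 2
    out[j, ] <- c(a, b, cc)
  }
  out
}

# Textbook Benjamini-Hochberg step-up: reject the p-values at or below the
# largest p_(k) with p_(k) <= k * alpha / m.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Exhaustive ROH reference scan: every maximal non-heterozygous run is
# tested directly against the segment filters, with the same window-based
# eligibility trim applied by brute force.
oracle_roh <- function(data, cfg) {
  out <- NULL
  for (i in seq_len(n_samples(data))) {
    for (chr in unique(data$variants$chrom)) {
      jj <- which(data$variants$chrom == chr)
      g <- data$geno[i, jj]
      pos <- data$variants$pos[jj]
      m <- length(g)
      w <- min(cfg$window_snps, m)
      if (m < w) next
      hom_win <- vapply(seq_len(m - w + 1), function(s) {
        win <- g[s:(s + w - 1)]
        sum(win == 1L, na.rm = TRUE) <= cfg$max_het_in_window &&
          sum(is.na(win)) <= cfg$max_missing_in_window
      }, logical(1))
      elig <- vapply(seq_len(m), function(v) {
        ws <- max(1, v - w + 1):min(length(hom_win), v)
        mean(hom_win[ws]) >= cfg$window_threshold
      }, logical(1))
      ok <- elig & !(g == 1L & !is.na(g))
      run <- 0
      start <- NA
      for (v in seq_len(m + 1)) {
        gap_break <- v > 1 && v <= m && (pos[v] - pos[v - 1]) > cfg$max_gap_kb * 1000
        if (v <= m && ok[v] && !(run > 0 && gap_break)) {
          if (run == 0) start <- v
          run <- run + 1
        } else {
          if (run > 0) {
            end <- start + run - 1
            len_kb <- (pos[end] - pos[start]) / 1000
            if (len_kb >= cfg$min_length_kb && run >= cfg$min_snps &&
                len_kb / run <= cfg$max_density_kb_per_snp)
              out <- rbind(out, data.frame(
                sample_id = data$samples$sample_id[i], chromosome = chr,
                start_bp = pos[start], end_bp = pos[end],
                n_snps = run, length_kb = len_kb,
                stringsAsFactors = FALSE))
          }
          run <- 0
          if (v <= m && ok[v]) { start <- v; run <- 1 }
        }
      }
    }
  }
  out
}
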