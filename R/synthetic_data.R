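#' Simulate genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn Uniform(0.05, 0.95); each
#' population's deme frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral p, with F the target F_ST (F = 0 gives identical deme
#' frequencies); genotypes are Binomial(2, deme frequency). Selected
#' variants can be given an elevated F (outlier loci), demes can receive a
#' within-deme inbreeding coefficient (genotypes drawn with allelic
#' correlation `inbreeding_f`), and uniform missingness can be applied.
#' Everything is a pure function of the configuration and seed.
#'
#' @param n_populations number of demes.
#' @param n_samples_per_pop diploid samples per deme (recycled).
#' @param n_variants total variant count.
#' @param target_fst Balding-Nichols differentiation parameter in [0, 1).
#' @param outlier_idx indices of variants simulated at `outlier_fst`.
#' @param outlier_fst elevated F for the outlier variants.
#' @param inbreeding_f within-deme inbreeding coefficient in [0, 1).
#' @param missing_rate uniform missing-call rate.
#' @param n_chromosomes variants are split evenly over this many chromosomes.
#' @param chromosome_length_bp chromosome length for position placement.
#' @param seed RNG seed.
#' @return list with `data` (a [gtdata] in canonical coding) and `truth`
#'   (list: `ancestral_freq`, `deme_freq` (deme x variant, counted-allele
#'   scale of the emitted coding), `outlier_idx`).
#' @export
simulate_balding_nichols <- function(n_populations = 2,
                                     n_samples_per_pop = 50,
                                     n_variants = 5000,
                                     target_fst = 0.15,
                                     outlier_idx = integer(0),
                                     outlier_fst = 0.8,
                                     inbreeding_f = 0,
                                     missing_rate = 0,
                                     n_chromosomes = 1,
                                     chromosome_length_bp = 1e8,
                                     seed = 1L) {
  stopifnot(target_fst >= 0, target_fst < 1)
  set.seed(seed)
  npop <- n_populations
  nper <- rep_len(n_samples_per_pop, npop)
  m <- n_variants
  p_anc <- stats::runif(m, 0.05, 0.95)
  fvec <- rep(target_fst, m)
  fvec[outlier_idx] <- outlier_fst
  deme_freq <- matrix(NA_real_, npop, m)
  for (d in seq_len(npop)) {
    f0 <- fvec == 0
    deme_freq[d, f0] <- p_anc[f0]
    if (any(!f0)) {
      a <- p_anc[!f0] * (1 - fvec[!f0]) / fvec[!f0]
      b <- (1 - p_anc[!f0]) * (1 - fvec[!f0]) / fvec[!f0]
      deme_freq[d, !f0] <- stats::rbeta(sum(!f0), a, b)
    }
  }
  n <- sum(nper)
  geno <- matrix(NA_integer_, n, m)
  row <- 0L
  for (d in seq_len(npop)) {
    for (i in seq_len(nper[d])) {
      row <- row + 1L
      pf <- deme_freq[d, ]
      if (inbreeding_f > 0) {
        # correlated allele draws: P(hom-alt) = p^2 + F p(1-p), etc.
        a1 <- stats::rbinom(m, 1, pf)
        same <- stats::runif(m) < inbreeding_f
        a2 <- ifelse(same, a1, stats::rbinom(m, 1, pf))
        geno[row, ] <- a1 + a2
      } else {
        geno[row, ] <- stats::rbinom(m, 2, pf)
      }
    }
  }
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  dat <- assemble_gtdata(geno, nper, m, n_chromosomes, chromosome_length_bp)
  # canonical coding: mirror any code swap in the truth frequencies
  swapped <- coding_swap_mask(dat)
  dat <- canonicalize_coding(dat)
  deme_freq[, swapped] <- 1 - deme_freq[, swapped]
  p_anc[swapped] <- 1 - p_anc[swapped]
  list(data = dat,
       truth = list(ancestral_freq = p_anc, deme_freq = deme_freq,
                    outlier_idx = outlier_idx))
}

# which variants canonicalize_coding() will recode (counted allele not minor)
coding_swap_mask <- function(x) {
  g <- x$geno
  nb <- colSums(g, na.rm = TRUE)
  na <- 2L * colSums(!is.na(g)) - nb
  a1 <- x$variants$allele_a; a2 <- x$variants$allele_b
  nb > na | (nb == na & !is.na(a1) & !is.na(a2) & a2 < a1)
}

assemble_gtdata <- function(geno, nper, m, n_chromosomes,
                            chromosome_length_bp,
                            pop_names = paste0("POP", seq_along(nper))) {
  n <- sum(nper)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    population = rep(pop_names, nper),
    stringsAsFactors = FALSE
  )
  per_chr <- diff(round(seq(0, m, length.out = n_chromosomes + 1)))
  chrom <- rep(as.character(seq_len(n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(chromosome_length_bp, k))))
  variants <- data.frame(
    chrom = chrom, id = sprintf("snp%05d", seq_len(m)),
    cm = 0, pos = as.integer(pos),
    allele_a = "A", allele_b = "G",
    stringsAsFactors = FALSE
  )
  gtdata(geno, samples, variants)
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete-generation diploid forward simulation from standing variation:
#' haplotypes are initialized in linkage equilibrium at Uniform(0.1, 0.9)
#' frequencies (no new mutation), each generation draws random mating pairs
#' according to the population-size history, and gametes recombine with
#' Poisson crossovers at `recombination_cm_per_mb`. The final generation is
#' sampled as unphased genotypes.
#'
#' @param ne_history data.frame/list with columns `generation` (1 = first
#'   simulated generation) and `n` (diploid population size); sizes apply
#'   from their generation onward. A single number gives a constant size.
#' @param n_generations generations to simulate.
#' @param n_chromosomes,chromosome_length_bp,n_variants_per_chrom genome
#'   layout; variant positions are uniform per chromosome.
#' @param sample_n diploid individuals sampled at the end.
#' @param recombination_cm_per_mb recombination rate (1 cM/Mb default).
#' @param min_maf variants below this MAF in the sample are dropped
#'   (monomorphic variants are unusable downstream); 0 keeps everything
#'   polymorphic in the sample.
#' @param seed RNG seed.
#' @return a [gtdata] object in canonical coding.
#' @export
simulate_wright_fisher <- function(ne_history = 50,
                                   n_generations = 100,
                                   n_chromosomes = 20,
                                   chromosome_length_bp = 1e6,
                                   n_variants_per_chrom = 100,
                                   sample_n = 30,
                                   recombination_cm_per_mb = 1,
                                   min_maf = 0.05,
                                   seed = 1L) {
  set.seed(seed)
  if (is.numeric(ne_history) && length(ne_history) == 1)
    ne_history <- data.frame(generation = 1, n = ne_history)
  ne_history <- as.data.frame(ne_history)
  if (any(ne_history$n < 2)) stop("population size must be at least 2")
  size_at <- function(t) {
    i <- max(which(ne_history$generation <= t))
    ne_history$n[i]
  }
  L_morgans <- chromosome_length_bp / 1e6 * recombination_cm_per_mb / 100
  mpc <- n_variants_per_chrom
  pos <- lapply(seq_len(n_chromosomes), function(ch)
    sort(sample.int(chromosome_length_bp, mpc)))
  n0 <- size_at(1)
  # haplotype matrices: (2N) x m per chromosome, 0/1 alleles
  haps <- lapply(seq_len(n_chromosomes), function(ch) {
    p0 <- stats::runif(mpc, 0.1, 0.9)
    matrix(stats::rbinom(2 * n0 * mpc, 1, rep(p0, each = 2 * n0)),
           nrow = 2 * n0, ncol = mpc)
  })
  n_cur <- n0
  for (t in seq_len(n_generations)) {
    n_next <- size_at(t)
    mothers <- sample.int(n_cur, n_next, replace = TRUE)
    fathers <- sample.int(n_cur, n_next, replace = TRUE)
    for (ch in seq_len(n_chromosomes)) {
      h <- haps[[ch]]
      pchr <- pos[[ch]]
      newh <- matrix(0L, 2 * n_next, mpc)
      parent <- rbind(mothers, fathers)  # 2 x n_next
      n_x <- stats::rpois(2 * n_next, L_morgans)
      which_h <- sample.int(2, 2 * n_next, replace = TRUE)
      for (gam in seq_len(2 * n_next)) {
        par <- parent[((gam - 1) %% 2) + 1, ((gam - 1) %/% 2) + 1]
        h1 <- h[2 * par - 1, ]; h2 <- h[2 * par, ]
        if (which_h[gam] == 2) { tmp <- h1; h1 <- h2; h2 <- tmp }
        if (n_x[gam] == 0) {
          newh[gam, ] <- h1
        } else {
          xpos <- sort(stats::runif(n_x[gam], 0, chromosome_length_bp))
          seg <- findInterval(pchr, xpos)
          newh[gam, ] <- ifelse(seg %% 2 == 0, h1, h2)
        }
      }
      haps[[ch]] <- newh
    }
    n_cur <- n_next
  }
  take <- sample.int(n_cur, min(sample_n, n_cur))
  geno <- do.call(cbind, lapply(seq_len(n_chromosomes), function(ch) {
    h <- haps[[ch]]
    h[2 * take - 1, , drop = FALSE] + h[2 * take, , drop = FALSE]
  }))
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_along(take)),
    population = "POP1", stringsAsFactors = FALSE
  )
  variants <- data.frame(
    chrom = rep(as.character(seq_len(n_chromosomes)), each = mpc),
    id = sprintf("snp%05d", seq_len(n_chromosomes * mpc)),
    cm = 0, pos = as.integer(unlist(pos)),
    allele_a = "A", allele_b = "G", stringsAsFactors = FALSE
  )
  dat <- canonicalize_coding(gtdata(geno, samples, variants))
  maf <- variant_maf(dat)
  subset_gtdata(dat, variants = which(!is.na(maf) & maf > min_maf))
}

#' Implant autozygous segments into a dataset
#'
#' Within each implant interval the sample's genotypes become homozygous:
#' heterozygotes collapse to a random homozygote (seeded), homozygotes are
#' untouched. Overlapping implants for one sample are merged with a
#' warning. The implant list is returned alongside as truth.
#'
#' @param data a [gtdata] object.
#' @param implants data.frame with columns `sample_id`, `chrom`,
#'   `start_bp`, `end_bp`.
#' @param seed RNG seed for collapsing heterozygotes.
#' @return list with `data` (modified [gtdata]) and `truth` (the merged
#'   implant table).
#' @export
implant_roh <- function(data, implants, seed = 1L) {
  set.seed(seed)
  if (nrow(implants) == 0) return(list(data = data, truth = implants))
  merged <- NULL
  for (s in unique(implants$sample_id)) {
    for (ch in unique(implants$chrom[implants$sample_id == s])) {
      sub <- implants[implants$sample_id == s & implants$chrom == ch, ,
                      drop = FALSE]
      sub <- sub[order(sub$start_bp), , drop = FALSE]
      i <- 1
      while (i < nrow(sub)) {
        if (sub$start_bp[i + 1] <= sub$end_bp[i]) {
          warning("overlapping implants merged for sample ", s)
          sub$end_bp[i] <- max(sub$end_bp[i], sub$end_bp[i + 1])
          sub <- sub[-(i + 1), , drop = FALSE]
        } else i <- i + 1
      }
      merged <- rbind(merged, sub)
    }
  }
  g <- data$geno
  for (r in seq_len(nrow(merged))) {
    i <- match(merged$sample_id[r], data$samples$sample_id)
    jj <- which(data$variants$chrom == merged$chrom[r] &
                data$variants$pos >= merged$start_bp[r] &
                data$variants$pos <= merged$end_bp[r])
    gi <- g[i, jj]
    het <- !is.na(gi) & gi == 1L
    gi[het] <- 2L * stats::rbinom(sum(het), 1, 0.5)
    g[i, jj] <- gi
  }
  data$geno <- g
  list(data = data, truth = merged)
}

#' Simulate admixed genotypes from source frequencies
#'
#' Each admixed sample's genotype at each variant is Binomial(2, q . f),
#' with `f` the column of source-deme allele frequencies and `q` the
#' sample's ancestry row. The truth Q is retained alongside.
#'
#' @param deme_freq k x m matrix of source allele frequencies (e.g. the
#'   `truth$deme_freq` of [simulate_balding_nichols()]).
#' @param q_truth n x k ancestry matrix; rows must sum to 1.
#' @param missing_rate uniform missing-call rate.
#' @param n_chromosomes,chromosome_length_bp genome layout for positions.
#' @param seed RNG seed.
#' @return list with `data` (a [gtdata], canonical coding) and `truth`
#'   (list `q`, `deme_freq` on the emitted coding's counted-allele scale).
#' @export
mix_admixture <- function(deme_freq, q_truth, missing_rate = 0,
                          n_chromosomes = 1, chromosome_length_bp = 1e8,
                          seed = 1L) {
  set.seed(seed)
  if (any(abs(rowSums(q_truth) - 1) > 1e-8))
    stop("q_truth rows must sum to 1")
  n <- nrow(q_truth); m <- ncol(deme_freq)
  p <- q_truth %*% deme_freq
  geno <- matrix(stats::rbinom(n * m, 2, p), n, m)
  if (missing_rate > 0)
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  dat <- assemble_gtdata(geno, n, m, n_chromosomes, chromosome_length_bp,
                         pop_names = "ADMIXED")
  swapped <- coding_swap_mask(dat)
  dat <- canonicalize_coding(dat)
  deme_freq[, swapped] <- 1 - deme_freq[, swapped]
  list(data = dat, truth = list(q = q_truth, deme_freq = deme_freq))
}
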