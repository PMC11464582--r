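# Fixtures use ~20 kb SNP spacing so that >= 1 Mb segments hold >= 50 SNPs,
# the sliding-window size; at array densities much below that the
# zero-heterozygote window rule cannot certify a window at all.
roh_background <- function(n = 4, seed = 101) {
  simulate_balding_nichols(n_populations = 1, n_samples_per_pop = n,
                           n_variants = 1500, target_fst = 0,
                           n_chromosomes = 3, chromosome_length_bp = 1e7,
                           seed = seed)$data
}

test_that("a fully heterozygous sample yields zero segments", {
  d <- make_gt(matrix(1L, 2, 300), spacing_bp = 2e4)
  expect_equal(nrow(detect_roh(d)), 0)
})

# Index bounds of the maximal non-heterozygous run containing an implant:
# the caller's truth, since chance-homozygous background SNPs flanking the
# implant belong to the same run.
true_run_bounds <- function(data, sample_id, chrom, start_bp, end_bp) {
  jj <- which(data$variants$chrom == chrom)
  g <- data$geno[match(sample_id, data$samples$sample_id), jj]
  pos <- data$variants$pos[jj]
  inside <- which(pos >= start_bp & pos <= end_bp)
  lo <- min(inside); hi <- max(inside)
  het <- !is.na(g) & g == 1L
  while (lo > 1 && !het[lo - 1]) lo <- lo - 1
  while (hi < length(g) && !het[hi + 1]) hi <- hi + 1
  c(lo, hi)
}

test_that("an implanted 2 Mb run is recovered within window resolution", {
  d <- roh_background()
  imp <- data.frame(sample_id = "S001", chrom = "1",
                    start_bp = 2e6, end_bp = 4e6)
  r <- implant_roh(d, imp, seed = 9)
  segs <- detect_roh(r$data)
  segs <- segs[segs$sample_id == "S001" & segs$chromosome == "1", ]
  expect_equal(nrow(segs), 1)
  # boundary tolerance: the hit-fraction rule trims up to
  # ceil(threshold * window) = 3 SNPs at each edge of the true run
  run <- true_run_bounds(r$data, "S001", "1", 2e6, 4e6)
  chr_pos <- d$variants$pos[d$variants$chrom == "1"]
  expect_lte(abs(match(segs$start_bp, chr_pos) - run[1]), 3)
  expect_lte(abs(match(segs$end_bp, chr_pos) - run[2]), 3)
})

test_that("sub-minimum implants yield zero calls", {
  d <- roh_background(seed = 102)
  imp <- data.frame(sample_id = "S002", chrom = "2",
                    start_bp = 2e6, end_bp = 2.8e6)   # 800 kb < 1000 kb
  r <- implant_roh(d, imp, seed = 10)
  segs <- detect_roh(r$data)
  expect_equal(nrow(segs[segs$sample_id == "S002", ]), 0)
})

test_that("the caller equals the exhaustive reference scan", {
  cfg <- roh_config()
  for (seed in c(201, 202)) {
    d <- roh_background(n = 3, seed = seed)
    imp <- data.frame(sample_id = c("S001", "S002"),
                      chrom = c("1", "3"),
                      start_bp = c(1e6, 4e6), end_bp = c(3.5e6, 7e6))
    r <- implant_roh(d, imp, seed = seed)
    got <- detect_roh(r$data, cfg)
    want <- oracle_roh(r$data, cfg)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$sample_id, got$chromosome, got$start_bp), ]
      want <- want[order(want$sample_id, want$chromosome, want$start_bp), ]
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("emitted segments satisfy every segment invariant", {
  d <- roh_background(seed = 103)
  imp <- data.frame(sample_id = c("S001", "S001"), chrom = c("1", "2"),
                    start_bp = c(1e6, 5e6), end_bp = c(4e6, 9e6))
  segs <- detect_roh(implant_roh(d, imp, seed = 3)$data)
  cfg <- roh_config()
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$end_bp > segs$start_bp))
  expect_equal(segs$length_kb, (segs$end_bp - segs$start_bp) / 1000)
  expect_true(all(segs$n_snps >= cfg$min_snps))
  expect_true(all(segs$length_kb >= cfg$min_length_kb))
  expect_true(all(segs$length_kb / segs$n_snps <= cfg$max_density_kb_per_snp))
})

test_that("raising the minimum length never increases the segment count", {
  d <- roh_background(seed = 104)
  imp <- data.frame(sample_id = c("S001", "S002"), chrom = c("1", "2"),
                    start_bp = c(1e6, 2e6), end_bp = c(2.6e6, 6e6))
  dd <- implant_roh(d, imp, seed = 4)$data
  counts <- vapply(c(1000, 2000, 3000, 5000), function(L)
    nrow(detect_roh(dd, roh_config(min_length_kb = L))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("F_ROH arithmetic and class decomposition are exact", {
  empty <- froh(data.frame(sample_id = character(0), length_kb = numeric(0)),
                c("S01", "S02"))
  expect_equal(empty$froh_total, c(0, 0))

  segs <- data.frame(sample_id = "S01", chromosome = "1",
                     start_bp = 0, end_bp = 22657700,
                     n_snps = 500, length_kb = 22657.7)
  fr <- froh(segs, "S01")
  expect_equal(fr$froh_total, 0.01)
  expect_equal(fr$froh_gt_12, 0.01)     # 22.7 Mb falls in the > 12 Mb class

  # class bounds are lower-inclusive: exactly 4 Mb belongs to 4-8 Mb
  segs2 <- data.frame(sample_id = "S01", chromosome = "1",
                      start_bp = 0, end_bp = 4e6, n_snps = 100,
                      length_kb = 4000)
  fr2 <- froh(segs2, "S01")
  expect_equal(fr2$froh_4_8, 4000 / PIG_AUTOSOME_KB)
  expect_equal(fr2$froh_1_4, 0)

  # decomposition sums to the total exactly
  set.seed(6)
  segs3 <- data.frame(sample_id = "S01", chromosome = "1",
                      start_bp = 0, end_bp = 0, n_snps = 50,
                      length_kb = runif(20, 1000, 20000))
  fr3 <- froh(segs3, "S01")
  expect_equal(fr3$froh_total,
               fr3$froh_1_4 + fr3$froh_4_8 + fr3$froh_8_12 + fr3$froh_gt_12)
})

test_that("implanted genome-wide autozygosity is recovered by F_ROH", {
  # 10% of a 30 Mb genome implanted as one 3 Mb segment per sample; the
  # 50-SNP window needs segments comfortably above its own span (~1 Mb at
  # this density) to certify them
  d <- roh_background(n = 6, seed = 105)
  imp <- data.frame(sample_id = d$samples$sample_id, chrom = "1",
                    start_bp = 2e6, end_bp = 5e6)
  r <- implant_roh(d, imp, seed = 11)
  segs <- detect_roh(r$data)
  fr <- froh(segs, d$samples$sample_id, genome_length_kb = 3e4)
  expect_lt(abs(mean(fr$froh_total) - 0.10), 0.015)
})

test_that("segment length maps to generations since the common ancestor", {
  expect_equal(generations_from_length(12), 100 / 24)
  expect_equal(round(generations_from_length(12), 2), 4.17)
  expect_equal(generations_from_length(50), 1)
  expect_equal(generations_from_length(1), 50)
  expect_error(generations_from_length(0), "positive")
})
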