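test_that("generators are pure functions of their seed", {
  a <- simulate_balding_nichols(n_samples_per_pop = 10, n_variants = 100,
                                seed = 5)
  b <- simulate_balding_nichols(n_samples_per_pop = 10, n_variants = 100,
                                seed = 5)
  expect_identical(a$data$geno, b$data$geno)
  expect_identical(a$truth$deme_freq, b$truth$deme_freq)

  w1 <- simulate_wright_fisher(ne_history = 30, n_generations = 10,
                               n_chromosomes = 2, n_variants_per_chrom = 40,
                               sample_n = 10, seed = 9)
  w2 <- simulate_wright_fisher(ne_history = 30, n_generations = 10,
                               n_chromosomes = 2, n_variants_per_chrom = 40,
                               sample_n = 10, seed = 9)
  expect_identical(w1$geno, w2$geno)

  q <- diag(2)
  m1 <- mix_admixture(matrix(c(0.2, 0.8), 2, 50), rbind(q, q), seed = 4)
  m2 <- mix_admixture(matrix(c(0.2, 0.8), 2, 50), rbind(q, q), seed = 4)
  expect_identical(m1$data$geno, m2$data$geno)
})

test_that("Balding-Nichols differentiates demes as parameterized", {
  null <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 40,
                                   n_variants = 1500, target_fst = 0,
                                   seed = 6)
  expect_lt(abs(per_marker_fst(null$data)$mean_fst), 0.01)
  # all demes share the ancestral frequency at F = 0
  expect_equal(null$truth$deme_freq[1, ], null$truth$deme_freq[2, ])

  sim <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 50,
                                  n_variants = 5000, target_fst = 0.15,
                                  seed = 7)
  expect_lt(abs(per_marker_fst(sim$data)$mean_fst - 0.15), 0.02)

  # missingness hits close to its nominal rate
  mr <- simulate_balding_nichols(n_samples_per_pop = 30, n_variants = 500,
                                 missing_rate = 0.1, seed = 8)
  expect_lt(abs(mean(is.na(mr$data$geno)) - 0.1), 0.01)
})

test_that("generated datasets round-trip through PED/MAP unchanged", {
  sim <- simulate_balding_nichols(n_populations = 3, n_samples_per_pop = 6,
                                  n_variants = 90, target_fst = 0.2,
                                  missing_rate = 0.05, n_chromosomes = 2,
                                  seed = 9)
  ped <- tempfile(); map <- tempfile()
  write_ped_map(sim$data, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(unname(back$geno), unname(sim$data$geno))

  wf <- simulate_wright_fisher(ne_history = 20, n_generations = 15,
                               n_chromosomes = 2, n_variants_per_chrom = 50,
                               sample_n = 12, seed = 10)
  write_ped_map(wf, ped, map)
  expect_identical(unname(read_ped_map(ped, map)$geno), unname(wf$geno))
})

test_that("truth deme frequencies live on the emitted coding", {
  sim <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 60,
                                  n_variants = 400, target_fst = 0.1,
                                  seed = 11)
  # per-deme observed frequencies track the truth
  for (d in 1:2) {
    obs <- colMeans(sim$data$geno[sim$data$samples$population ==
                                    paste0("POP", d), ]) / 2
    expect_lt(mean(abs(obs - sim$truth$deme_freq[d, ])), 0.05)
  }
})

test_that("Wright-Fisher LD reflects recombination", {
  # zero-recombination chromosome keeps drifted LD; a recombining one decays
  free <- simulate_wright_fisher(ne_history = 40, n_generations = 60,
                                 n_chromosomes = 4, n_variants_per_chrom = 60,
                                 recombination_cm_per_mb = 100,
                                 sample_n = 25, seed = 12)
  tight <- simulate_wright_fisher(ne_history = 40, n_generations = 60,
                                  n_chromosomes = 4, n_variants_per_chrom = 60,
                                  recombination_cm_per_mb = 0,
                                  sample_n = 25, seed = 12)
  r2_free <- mean(ld_pairs(free, 1e6)$r2)
  r2_tight <- mean(ld_pairs(tight, 1e6)$r2)
  expect_gt(r2_tight, r2_free)
  expect_error(simulate_wright_fisher(ne_history = 1), "at least 2")
})

test_that("ROH implanting is exact, merging overlaps, identity when empty", {
  d <- simulate_balding_nichols(n_samples_per_pop = 3, n_variants = 400,
                                n_chromosomes = 1,
                                chromosome_length_bp = 1e7, seed = 13)$data
  # whole-chromosome implant leaves no heterozygote
  r <- implant_roh(d, data.frame(sample_id = "S001", chrom = "1",
                                 start_bp = 0, end_bp = 1e7), seed = 2)
  expect_false(any(r$data$geno[1, ] == 1L, na.rm = TRUE))
  # untouched samples identical
  expect_identical(r$data$geno[2:3, ], d$geno[2:3, ])
  # homozygotes inside the interval keep their genotype
  hom <- which(d$geno[1, ] != 1L)
  expect_identical(r$data$geno[1, hom], d$geno[1, hom])

  # empty implant list is the identity
  r0 <- implant_roh(d, data.frame(sample_id = character(0),
                                  chrom = character(0), start_bp = numeric(0),
                                  end_bp = numeric(0)))
  expect_identical(r0$data$geno, d$geno)

  # overlapping implants merge with a warning
  expect_warning(
    rm2 <- implant_roh(d, data.frame(sample_id = "S002", chrom = "1",
                                     start_bp = c(1e6, 2e6),
                                     end_bp = c(3e6, 5e6)), seed = 3),
    "overlapping")
  expect_equal(nrow(rm2$truth), 1)
  expect_equal(rm2$truth$end_bp, 5e6)
})

test_that("admixture mixing honours the ancestry rows", {
  src <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 2,
                                  n_variants = 1500, target_fst = 0.3,
                                  seed = 14)
  q <- rbind(diag(2)[rep(1, 10), ], diag(2)[rep(2, 10), ])
  mx <- mix_admixture(src$truth$deme_freq, q, seed = 15)
  # pure rows draw from their own deme frequency
  for (d in 1:2) {
    rows <- which(q[, d] == 1)
    obs <- colMeans(mx$data$geno[rows, ]) / 2
    expect_lt(mean(abs(obs - mx$truth$deme_freq[d, ])), 0.12)
  }
  expect_error(mix_admixture(src$truth$deme_freq, q * 2, seed = 1),
               "sum to 1")
})
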