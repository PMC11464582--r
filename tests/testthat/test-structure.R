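test_that("PCA separates duplicated groups and matches a dense eigensolver", {
  # two groups of exactly duplicated individuals: PC1 carries all variance
  set.seed(21)
  proto <- rbind(rbinom(100, 2, 0.5), rbinom(100, 2, 0.5))
  g <- proto[rep(1:2, each = 5), ]
  g <- g[, apply(g, 2, var) > 0]
  p <- gt_pca(make_gt(g), n_components = 3)
  expect_gt(p$pct_variance[1], 0.999)
  expect_equal(length(unique(round(p$scores[, 1], 9))), 2)

  # oracle: full eigendecomposition of the standardized covariance
  set.seed(22)
  g2 <- matrix(rbinom(30 * 150, 2, 0.4), 30, 150)
  g2 <- g2[, apply(g2, 2, var) > 0]
  d2 <- make_gt(g2)
  p2 <- gt_pca(d2, n_components = 5)
  pfreq <- colMeans(g2) / 2
  x <- sweep(sweep(g2, 2, 2 * pfreq), 2, sqrt(2 * pfreq * (1 - pfreq)), "/")
  eig <- eigen(tcrossprod(x) / ncol(x), symmetric = TRUE)
  for (k in 1:5) {
    want <- eig$vectors[, k] * sqrt(max(eig$values[k], 0))
    got <- p2$scores[, k]
    expect_lt(min(max(abs(got - want)), max(abs(got + want))), 1e-8)
  }
  expect_true(all(diff(p2$pct_variance) <= 1e-12))
  expect_true(all(p2$pct_variance >= 0))
  expect_lte(sum(p2$pct_variance), 1 + 1e-12)
})

test_that("PCA clusters simulated populations and rejects monomorphic input", {
  sim <- simulate_balding_nichols(n_populations = 3, n_samples_per_pop = 20,
                                  n_variants = 2000, target_fst = 0.15,
                                  seed = 23)
  d <- filter_maf(sim$data, 0.01)$data
  p <- gt_pca(d, 2)
  # silhouette of population labels on PC1-PC2
  xy <- p$scores[, 1:2]
  labs <- d$samples$population
  dd <- as.matrix(dist(xy))
  sil <- vapply(seq_len(nrow(xy)), function(i) {
    a <- mean(dd[i, labs == labs[i]][-which(which(labs == labs[i]) == i)])
    b <- min(vapply(setdiff(unique(labs), labs[i]), function(l)
      mean(dd[i, labs == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  mono <- make_gt(cbind(c(0L, 0L, 0L), c(0L, 1L, 2L)))
  expect_error(gt_pca(mono), "MAF filter")
})

test_that("IBS matrix matches the exhaustive per-variant tally", {
  expect_equal(unname(ibs_matrix(make_gt(rbind(c(0L, 1L, 2L),
                                               c(0L, 1L, 2L))))[1, 2]), 1)
  expect_equal(unname(ibs_matrix(make_gt(rbind(rep(0L, 5),
                                               rep(2L, 5))))[1, 2]), 0)
  set.seed(24)
  g <- matrix(sample(c(0:2, NA), 6 * 50, replace = TRUE,
                     prob = c(.35, .3, .3, .05)), 6, 50)
  ibs <- ibs_matrix(make_gt(g))
  for (i in 1:5) for (j in (i + 1):6) {
    ok <- !is.na(g[i, ]) & !is.na(g[j, ])
    expect_equal(unname(ibs[i, j]),
                 mean((2 - abs(g[i, ok] - g[j, ok])) / 2), tolerance = 1e-12)
  }
})

test_that("nearest neighbours rank duplicates first and sort ascending", {
  set.seed(25)
  g <- matrix(sample(0:2, 8 * 100, replace = TRUE), 8, 100)
  g[2, ] <- g[1, ]                       # planted duplicate pair
  ibs <- ibs_matrix(make_gt(g))
  nn <- nearest_neighbors(ibs, k = 3)
  expect_equal(nn$neighbor[nn$sample_id == "S01" & nn$rank == 1], "S02")
  expect_equal(nn$neighbor[nn$sample_id == "S02" & nn$rank == 1], "S01")
  expect_equal(nn$ibs_distance[nn$sample_id == "S01" & nn$rank == 1], 0)
  for (s in unique(nn$sample_id))
    expect_true(!is.unsorted(nn$ibs_distance[nn$sample_id == s]))
  expect_error(nearest_neighbors(ibs[1:3, 1:3], k = 5), "k\\+1")
})

test_that("pairwise F_ST algebra: Slatkin linearization and Nm", {
  expect_equal(nm_from_fst(0.2), 1.0)
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(0.5 / (1 - 0.5), 1.0)     # slatkin at 0.5
  sim <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 25,
                                  n_variants = 800, target_fst = 0.2,
                                  seed = 26)
  pf <- pairwise_fst(sim$data, n_permutations = 99, seed = 5)
  f <- pf$fst[1, 2]
  expect_equal(pf$slatkin[1, 2], f / (1 - f))
  expect_equal(pf$nm[1, 2], ((1 / f) - 1) / 4)
  expect_true(isSymmetric(pf$fst))
  expect_equal(unname(diag(pf$fst)), c(0, 0))
  expect_lt(pf$p_value[1, 2], 0.05)      # real differentiation is detected
})

test_that("a split single deme shows null F_ST and non-significant p", {
  sim <- simulate_balding_nichols(n_populations = 1, n_samples_per_pop = 40,
                                  n_variants = 600, target_fst = 0, seed = 27)
  d <- sim$data
  d$samples$population <- rep(c("A", "B"), 20)
  pf <- pairwise_fst(d, populations = d$samples$population,
                     n_permutations = 199, seed = 7)
  expect_lt(abs(pf$fst[1, 2]), 0.01)
  expect_gt(pf$p_value[1, 2], 0.05)
})

test_that("Nei distance matches hand computation and its audit properties", {
  # p_x = (1, 0), p_y = (0.5, 0.5): D = -ln(0.5 / sqrt(0.5)) = 0.3466
  x <- make_gt(matrix(c(0L, 0L, 1L, 1L), 4, 1),
               populations = c("X", "X", "Y", "Y"))
  d <- nei_distance(x)
  expect_equal(unname(d["X", "Y"]), -log(0.5 / sqrt(0.5)), tolerance = 1e-9)
  expect_equal(unname(d["X", "Y"]), 0.3466, tolerance = 1e-4)
  sim <- simulate_balding_nichols(n_populations = 3, n_samples_per_pop = 10,
                                  n_variants = 300, target_fst = 0.2,
                                  seed = 28)
  nd <- nei_distance(sim$data)
  expect_true(isSymmetric(nd))
  expect_equal(unname(diag(nd)), rep(0, 3))
  expect_true(all(nd >= 0))
})

test_that("neighbour joining recovers closed forms and additive trees", {
  # 3 taxa: closed-form branch lengths
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj <- nj_tree(dm)
  tr <- nj$tree
  pd <- ape::cophenetic.phylo(tr)
  expect_equal(pd["a", "b"], 3, tolerance = 1e-9)
  expect_equal(pd["a", "c"], 4, tolerance = 1e-9)
  expect_equal(pd["b", "c"], 5, tolerance = 1e-9)

  # random additive trees round-trip through their path-length matrices
  set.seed(29)
  for (rep in 1:20) {
    ntax <- sample(4:8, 1)
    true_tree <- ape::rtree(ntax, rooted = FALSE,
                            br = function(n) runif(n, 0.5, 2))
    dm2 <- ape::cophenetic.phylo(true_tree)
    nj2 <- nj_tree(dm2)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), nj2$tree)[1], 0)
    pd2 <- ape::cophenetic.phylo(nj2$tree)[rownames(dm2), colnames(dm2)]
    expect_equal(unname(pd2), unname(dm2), tolerance = 1e-8)
  }
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3 taxa")
})

test_that("clamped NJ trees contain no negative branch lengths", {
  set.seed(30)
  sim <- simulate_balding_nichols(n_populations = 4, n_samples_per_pop = 6,
                                  n_variants = 150, target_fst = 0.05,
                                  seed = 31)
  nd <- nei_distance(sim$data)
  nj <- nj_tree(nd)
  expect_true(all(nj$tree$edge.length >= 0))
  expect_setequal(nj$tree$tip.label, rownames(nd))
})

test_that("kNN network components follow population separation", {
  sim <- simulate_balding_nichols(n_populations = 2, n_samples_per_pop = 10,
                                  n_variants = 1500, target_fst = 0.4,
                                  seed = 32)
  ibs <- ibs_matrix(sim$data)
  net <- knn_network(1 - ibs, k = 2, populations = sim$data$samples$population)
  expect_equal(max(net$components), 2)
  memb <- split(names(net$components), net$components)
  pops <- lapply(memb, function(ids)
    unique(sim$data$samples$population[match(ids, sim$data$samples$sample_id)]))
  expect_true(all(lengths(pops) == 1))

  # complete graph at k = n-1; no self loops ever
  net2 <- knn_network(1 - ibs, k = nrow(ibs) - 1)
  expect_equal(max(net2$components), 1)
  expect_true(all(net2$edges$from != net2$edges$to))
  expect_error(knn_network(1 - ibs, k = nrow(ibs)), "below")
})
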