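#' Principal component analysis of standardized genotypes
#'
#' Genotypes are centered by 2p and scaled by sqrt(2p(1-p)) per variant
#' (p = counted-allele frequency); missing calls become 0 after centering
#' (mean imputation). The sample-by-sample covariance of the standardized
#' matrix is eigendecomposed; percentage of variance is eigenvalue over
#' trace.
#'
#' @param data a [gtdata] object without monomorphic variants (prune and
#'   MAF-filter first).
#' @param n_components number of components to retain.
#' @return list of class `gt_pca`: `scores` (samples x components,
#'   eigenvectors scaled by sqrt(eigenvalue)), `eigenvectors`,
#'   `eigenvalues` (all non-negative ones), `pct_variance`,
#'   `n_imputed` (missing cells imputed).
#' @export
gt_pca <- function(data, n_components = 10L) {
  p <- variant_freq(data)
  if (any(p == 0 | p == 1))
    stop("monomorphic variants present: apply a MAF filter before PCA")
  x <- scale_genotypes(data$geno, p)
  n_imputed <- sum(is.na(data$geno))
  cov <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  k <- min(n_components, length(vals))
  pct <- vals / sum(vals)
  scores <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(scores) <- data$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = scores,
    eigenvectors = eig$vectors[, seq_len(k), drop = FALSE],
    eigenvalues = vals,
    pct_variance = pct[seq_len(k)],
    n_imputed = n_imputed
  ), class = "gt_pca")
}

scale_genotypes <- function(g, p = colMeans(g, na.rm = TRUE) / 2) {
  x <- sweep(g, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  x
}

#' @export
print.gt_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("PCA of %d samples; first %d components explain %s of variance\n",
              nrow(x$scores), k,
              paste(sprintf("%.2f%%", 100 * x$pct_variance), collapse = ", ")))
  invisible(x)
}

#' Identity-by-state matrix
#'
#' Pairwise IBS proportion: the mean over pairwise-complete variants of
#' `(2 - |g_i - g_j|)/2`. Distance is `1 - IBS`.
#'
#' @param data a [gtdata] object.
#' @return symmetric samples-by-samples matrix of IBS proportions.
#' @export
ibs_matrix <- function(data) {
  g <- data$geno
  n <- nrow(g)
  ibs <- matrix(1, n, n, dimnames = list(data$samples$sample_id,
                                         data$samples$sample_id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok))
        stop("no complete variants between samples ",
             data$samples$sample_id[i], " and ", data$samples$sample_id[j])
      v <- mean((2 - abs(g[i, ok] - g[j, ok])) / 2)
      ibs[i, j] <- ibs[j, i] <- v
    }
  }
  ibs
}

#' Nearest neighbours by IBS distance
#'
#' Per sample, the `k` smallest IBS distances (`1 - IBS`), ties broken by
#' lexicographic sample id.
#'
#' @param ibs symmetric IBS matrix from [ibs_matrix()].
#' @param k number of neighbours (needs >= k+1 samples).
#' @return data.frame: `sample_id`, `rank`, `neighbor`, `ibs_distance`,
#'   sorted by increasing distance within sample.
#' @export
nearest_neighbors <- function(ibs, k = 5L) {
  n <- nrow(ibs)
  if (n < k + 1) stop("need at least k+1 samples")
  ids <- rownames(ibs)
  rows <- lapply(seq_len(n), function(i) {
    d <- 1 - ibs[i, -i]
    nb <- names(d)[order(d, names(d))][seq_len(k)]
    data.frame(sample_id = ids[i], rank = seq_len(k), neighbor = nb,
               ibs_distance = unname(d[nb]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise population F_ST with Slatkin linearization and Nm
#'
#' For each population pair: ratio-of-sums Weir-Cockerham F_ST over the
#' variants polymorphic within the pair; Slatkin's linearization
#' `fst/(1 - fst)`; the island-model migrant number
#' `Nm = ((1/fst) - 1)/4` (reported as `Inf` with a warning where
#' `fst <= 0`); and a permutation p-value obtained by shuffling the pair's
#' population labels.
#'
#' @param data a [gtdata] object.
#' @param populations population label per sample.
#' @param n_permutations label permutations for the p-value (0 disables).
#' @param seed RNG seed for the permutations.
#' @return list of class `pairwise_fst`: `populations`, symmetric matrices
#'   `fst`, `slatkin`, `nm`, `p_value`.
#' @export
pairwise_fst <- function(data, populations = data$samples$population,
                         n_permutations = 1000L, seed = 1L) {
  pops <- unique(populations)
  np <- length(pops)
  if (np < 2) stop("need >= 2 populations")
  fst <- slk <- nm <- pv <- matrix(NA_real_, np, np,
                                   dimnames = list(pops, pops))
  diag(fst) <- 0; diag(slk) <- 0
  for (a in seq_len(np - 1)) {
    for (b in seq((a + 1), np)) {
      sel <- populations %in% pops[c(a, b)]
      sub <- subset_gtdata(data, samples = which(sel))
      labs <- populations[sel]
      obs <- pair_fst_value(sub$geno, labs)
      fst[a, b] <- fst[b, a] <- obs
      slk[a, b] <- slk[b, a] <- obs / (1 - obs)
      if (obs > 0) {
        nm[a, b] <- nm[b, a] <- ((1 / obs) - 1) / 4
      } else {
        warning("non-positive F_ST for pair ", pops[a], "-", pops[b],
                "; Nm reported as Inf")
        nm[a, b] <- nm[b, a] <- Inf
      }
      if (n_permutations > 0) {
        set.seed(seed + a * 1000L + b)
        perm <- replicate(n_permutations,
                          pair_fst_value(sub$geno, sample(labs)))
        p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
        pv[a, b] <- pv[b, a] <- p
      }
    }
  }
  structure(list(populations = pops, fst = fst, slatkin = slk,
                 nm = nm, p_value = pv), class = "pairwise_fst")
}

# ratio-of-sums W&C F_ST for a two-population genotype matrix
pair_fst_value <- function(g, labs) {
  u <- unique(labs)
  i1 <- labs == u[1]; i2 <- labs == u[2]
  suma <- sumd <- 0
  for (j in seq_len(ncol(g))) {
    gj <- g[, j]
    n <- c(sum(!is.na(gj[i1])), sum(!is.na(gj[i2])))
    freq <- c(mean(gj[i1], na.rm = TRUE), mean(gj[i2], na.rm = TRUE)) / 2
    if (anyNA(freq) || all(freq == 0) || all(freq == 1)) next
    het <- c(mean(gj[i1] == 1L, na.rm = TRUE), mean(gj[i2] == 1L, na.rm = TRUE))
    comp <- wc_components(freq, het, n)
    if (anyNA(comp)) next
    suma <- suma + comp[1]
    sumd <- sumd + sum(comp)
  }
  if (sumd == 0) return(NA_real_)
  suma / sumd
}

#' Migrant number from F_ST
#'
#' The island-model relation `Nm = ((1/fst) - 1)/4`.
#'
#' @param fst F_ST value(s) in (0, 1].
#' @return number of migrants per generation.
#' @export
nm_from_fst <- function(fst) ((1 / fst) - 1) / 4

#' Nei (1972) standard genetic distance between populations
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))`, with `Jx` the mean over variants of the
#' sum of squared allele frequencies in population x, and `Jxy` the mean of
#' the cross-products, both alleles summed per variant. Variants with an
#' undefined frequency in either population are excluded pairwise; a zero
#' `Jxy` yields an infinite distance capped at `ceiling`.
#'
#' @param data a [gtdata] object.
#' @param populations population label per sample.
#' @param ceiling cap for infinite distances.
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_distance <- function(data, populations = data$samples$population,
                         ceiling = 50) {
  pops <- unique(populations)
  freq <- vapply(pops, function(pop) {
    colMeans(data$geno[populations == pop, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(n_variants(data)))
  freq <- matrix(freq, ncol = length(pops),
                 dimnames = list(NULL, pops))
  np <- length(pops)
  d <- matrix(0, np, np, dimnames = list(pops, pops))
  for (a in seq_len(np - 1)) {
    for (b in seq(a + 1, np)) {
      px <- freq[, a]; py <- freq[, b]
      ok <- !is.na(px) & !is.na(py)
      jx <- mean(px[ok]^2 + (1 - px[ok])^2)
      jy <- mean(py[ok]^2 + (1 - py[ok])^2)
      jxy <- mean(px[ok] * py[ok] + (1 - px[ok]) * (1 - py[ok]))
      if (jxy == 0) {
        warning("zero Jxy between ", pops[a], " and ", pops[b],
                "; distance capped at ", ceiling)
        v <- ceiling
      } else {
        v <- min(-log(jxy / sqrt(jx * jy)), ceiling)
      }
      d[a, b] <- d[b, a] <- v
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]) with negative branch
#' lengths clamped to zero and the excess moved to the sister branch at the
#' same node, serialized as Newick.
#'
#' @param distance symmetric distance matrix with labels.
#' @param labels optional taxon labels (defaults to matrix dimnames).
#' @return list with `tree` ([ape::phylo]) and `newick` (text).
#' @export
nj_tree <- function(distance, labels = rownames(distance)) {
  if (nrow(distance) < 3) stop("neighbour joining needs >= 3 taxa")
  if (any(!is.finite(distance))) stop("distances must be finite")
  dimnames(distance) <- list(labels, labels)
  tree <- ape::nj(stats::as.dist(distance))
  # clamp negative branches: move the deficit onto the sister edge
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sisters <- setdiff(which(tree$edge[, 1] == parent), e)
    excess <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sisters))
      tree$edge.length[sisters[1]] <- tree$edge.length[sisters[1]] + excess
    else break
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  list(tree = tree, newick = ape::write.tree(tree))
}

#' k-nearest-neighbour network over a distance matrix
#'
#' Directed k-nearest-neighbour edges symmetrized to an undirected graph
#' with population labels as node attributes; connected components are
#' reported (via igraph).
#'
#' @param distance symmetric distance matrix with sample ids as dimnames.
#' @param k neighbours per node (k < number of samples).
#' @param populations optional population label per sample.
#' @return list with `edges` (data.frame `from`, `to`, `distance`),
#'   `graph` (igraph object), `components` (membership vector).
#' @export
knn_network <- function(distance, k = 5L, populations = NULL) {
  n <- nrow(distance)
  if (k >= n) stop("k must be below the number of samples")
  ids <- rownames(distance)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  edges <- NULL
  for (i in seq_len(n)) {
    d <- distance[i, -i]
    nb <- order(d, names(d))[seq_len(k)]
    nb_ids <- colnames(distance)[-i][nb]
    edges <- rbind(edges, data.frame(from = ids[i], to = nb_ids,
                                     distance = unname(d[nb]),
                                     stringsAsFactors = FALSE))
  }
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to), paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(populations))
    igraph::V(g)$population <- populations[match(igraph::V(g)$name, ids)]
  comps <- igraph::components(g)$membership
  list(edges = edges, graph = g, components = comps)
}
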