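#' Maximum-likelihood admixture model
#'
#' Fits the k-component binomial admixture model: each genotype
#' `g_ij ~ Binomial(2, p_ij)` with `p_ij = sum_k q_ik f_kj`, `Q` the
#' sample-by-k ancestry proportions (rows on the simplex) and `F` the
#' k-by-variant ancestral allele frequencies. Optimization is by the
#' multiplicative EM updates, which never decrease the log-likelihood;
#' multiple seeded restarts guard against local optima and the
#' best-likelihood fit is returned. Missing genotypes are skipped. `F` is
#' clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param data a [gtdata] object (MAF-filtered, LD-pruned).
#' @param k number of ancestral components (>= 1).
#' @param seed RNG seed; restart r uses `seed + r - 1`.
#' @param tol stop when the relative log-likelihood change drops below this.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts random restarts.
#' @return object of class `admixture_fit`: `k`, `q`, `f`, `loglik`,
#'   `loglik_trace`, `n_iterations`, `converged`, `seed`.
#' @export
fit_admixture <- function(data, k, seed = 1L, tol = 1e-6, max_iter = 2000L,
                          n_restarts = 5L) {
  g <- data$geno
  if (k > nrow(g)) stop("k must not exceed the number of samples")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- admixture_em(g, k, seed = seed + r - 1L, tol = tol,
                        max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$seed <- seed
  rownames(best$q) <- data$samples$sample_id
  colnames(best$f) <- data$variants$id
  class(best) <- "admixture_fit"
  best
}

admixture_em <- function(g, k, seed, tol, max_iter) {
  n <- nrow(g); m <- ncol(g)
  set.seed(seed)
  w <- !is.na(g)
  g0 <- g; g0[!w] <- 0L
  gw <- g0 * w                 # copies of counted allele (0 where missing)
  hw <- (2L - g0) * w          # copies of the other allele
  mcall <- rowSums(w)
  # Dirichlet(1) rows for Q, uniform F
  q <- matrix(stats::rexp(n * k), n, k)
  q <- q / rowSums(q)
  f <- matrix(stats::runif(k * m, 0.05, 0.95), k, m)
  eps <- 1e-6
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    p <- q %*% f
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- sum(gw * log(p) + hw * log1p(-p))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    a <- gw / p                # n x m
    b <- hw / (1 - p)
    ta <- crossprod(q, a)      # k x m
    tb <- crossprod(q, b)
    f_new <- (f * ta) / (f * ta + (1 - f) * tb)
    f_new[!is.finite(f_new)] <- 0.5
    q_new <- q * (a %*% t(f) + b %*% t(1 - f)) / (2 * mcall)
    q_new <- q_new / rowSums(q_new)
    f <- pmin(pmax(f_new, eps), 1 - eps)
    q <- q_new
  }
  list(k = k, q = q, f = f, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, n_iterations = it, converged = converged)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: k = %d, loglik = %.2f, %d iterations (%s)\n",
              x$k, x$loglik, x$n_iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Cross-validation error for an admixture model
#'
#' Genotype-entry hold-out: per fold, `mask_fraction` of the non-missing
#' entries is masked (seeded), the model refit on the remainder, and the
#' masked entries scored by mean binomial deviance between the observed
#' genotype and the predicted dose `2 * p_hat`; the fold scores are
#' averaged. Identical seeds and inputs give identical masking and error.
#'
#' @param data a [gtdata] object.
#' @param k number of ancestral components.
#' @param n_folds number of folds.
#' @param mask_fraction fraction of non-missing entries masked per fold.
#' @param seed RNG seed.
#' @param ... passed to [fit_admixture()] (e.g. `max_iter`, `n_restarts`).
#' @return mean held-out binomial deviance (>= 0).
#' @export
cv_error <- function(data, k, n_folds = 5L, mask_fraction = 0.1, seed = 1L,
                     ...) {
  g <- data$geno
  obs_idx <- which(!is.na(g))
  errs <- numeric(n_folds)
  for (fold in seq_len(n_folds)) {
    set.seed(seed * 1000L + fold)
    mask <- sample(obs_idx, round(mask_fraction * length(obs_idx)))
    gm <- g
    gm[mask] <- NA_integer_
    masked_data <- data
    masked_data$geno <- gm
    fit <- fit_admixture(masked_data, k, seed = seed * 1000L + fold, ...)
    p <- fit$q %*% fit$f
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    gobs <- g[mask]
    phat <- p[mask]
    # binomial deviance between observed count and fitted probability
    sat <- ifelse(gobs == 0 | gobs == 2, 0,
                  gobs * log(gobs / 2) + (2 - gobs) * log(1 - gobs / 2))
    dev <- -2 * (gobs * log(phat) + (2 - gobs) * log(1 - phat) - sat)
    errs[fold] <- mean(dev)
  }
  mean(errs)
}

#' Scan k by cross-validation
#'
#' @param data a [gtdata] object.
#' @param k_range integer vector of k values (the classic scan is 2..15).
#' @param ... passed to [cv_error()].
#' @return data.frame with columns `k` and `cv_error`.
#' @export
cv_scan <- function(data, k_range = 2:15, ...) {
  data.frame(k = k_range,
             cv_error = vapply(k_range, function(k) cv_error(data, k, ...),
                               numeric(1)))
}

#' Align ancestral-component labels between two fits
#'
#' Cluster labels are arbitrary across runs; this returns the column
#' permutation of `fit_b` that best matches `fit_a`, maximizing the summed
#' correlation of matched Q columns. The assignment is exhaustive for
#' k <= 8 and greedy above.
#'
#' @param fit_a,fit_b `admixture_fit` objects with equal k.
#' @return integer permutation `perm` such that `fit_b$q[, perm]` aligns
#'   with `fit_a$q`.
#' @export
align_labels <- function(fit_a, fit_b) {
  stopifnot(fit_a$k == fit_b$k)
  k <- fit_a$k
  if (k == 1) return(1L)
  score <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    s <- suppressWarnings(stats::cor(fit_a$q[, a], fit_b$q[, b]))
    score[a, b] <- if (is.na(s)) 0 else s
  }
  if (k <= 8) {
    perms <- permutations_of(k)
    vals <- vapply(perms, function(p)
      sum(score[cbind(seq_len(k), p)]), numeric(1))
    perms[[which.max(vals)]]
  } else {
    perm <- integer(k)
    used <- logical(k)
    for (a in order(-apply(score, 1, max))) {
      b <- which.max(ifelse(used, -Inf, score[a, ]))
      perm[a] <- b
      used[b] <- TRUE
    }
    perm
  }
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}
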