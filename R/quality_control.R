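#' Quality-control configuration
#'
#' Bundles the thresholds of the data-reduction path. Defaults are the
#' standard SNP-array settings for small conservation-nucleus panels:
#' variant and sample call rate must exceed 0.95 (variants filtered first,
#' then samples on the surviving variants), MAF must exceed 0.05 where the
#' MAF filter is enabled, and LD pruning uses 50-SNP windows advanced by
#' 10 SNPs at an r-squared ceiling of 0.20 (the `--indep-pairwise 50 10 0.2`
#' convention). All thresholds are exclusive (`> threshold` is kept).
#'
#' @param variant_call_rate_min minimum (exclusive) per-variant call rate.
#' @param sample_call_rate_min minimum (exclusive) per-sample call rate.
#' @param maf_min minimum (exclusive) minor allele frequency; `NA` disables
#'   the MAF filter (the ROH path uses call-rate-filtered, non-MAF-filtered
#'   data).
#' @param prune_window_snps LD-pruning window size in SNPs.
#' @param prune_step_snps SNPs by which the window advances.
#' @param prune_r2_max maximum tolerated pairwise r-squared within a window.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(variant_call_rate_min = 0.95,
                      sample_call_rate_min = 0.95,
                      maf_min = 0.05,
                      prune_window_snps = 50L,
                      prune_step_snps = 10L,
                      prune_r2_max = 0.20) {
  stopifnot(
    variant_call_rate_min >= 0, variant_call_rate_min <= 1,
    sample_call_rate_min >= 0, sample_call_rate_min <= 1,
    is.na(maf_min) || (maf_min >= 0 && maf_min <= 1),
    prune_window_snps > prune_step_snps, prune_step_snps > 0,
    prune_r2_max >= 0, prune_r2_max <= 1
  )
  structure(list(
    variant_call_rate_min = variant_call_rate_min,
    sample_call_rate_min = sample_call_rate_min,
    maf_min = maf_min,
    prune_window_snps = as.integer(prune_window_snps),
    prune_step_snps = as.integer(prune_step_snps),
    prune_r2_max = prune_r2_max
  ), class = "qc_config")
}

qc_report <- function(before, after, removed_variants, removed_samples,
                      stage_order) {
  list(
    n_variants_in = n_variants(before), n_variants_out = n_variants(after),
    n_samples_in = n_samples(before), n_samples_out = n_samples(after),
    removed_variants = removed_variants, removed_samples = removed_samples,
    stage_order = stage_order
  )
}

#' Call-rate filtering (variants first, then samples)
#'
#' Removes variants whose call rate is at or below
#' `cfg$variant_call_rate_min`, then removes samples whose call rate —
#' computed on the surviving variants — is at or below
#' `cfg$sample_call_rate_min`. The order matters and is recorded in the
#' report's `stage_order`.
#'
#' @param data a [gtdata] object.
#' @param cfg a [qc_config].
#' @return list with `data` (filtered [gtdata]) and `report`.
#' @export
filter_call_rate <- function(data, cfg = qc_config()) {
  cr_v <- colMeans(!is.na(data$geno))
  keep_v <- cr_v > cfg$variant_call_rate_min
  if (!any(keep_v)) stop("empty dataset: all variants fail the call-rate filter")
  removed_v <- data$variants$id[!keep_v]
  out <- subset_gtdata(data, variants = which(keep_v))
  cr_s <- rowMeans(!is.na(out$geno))
  keep_s <- cr_s > cfg$sample_call_rate_min
  removed_s <- out$samples$sample_id[!keep_s]
  out <- subset_gtdata(out, samples = which(keep_s))
  list(data = out,
       report = qc_report(data, out, removed_v, removed_s,
                          c("variant_call_rate", "sample_call_rate")))
}

#' MAF filtering
#'
#' Removes variants whose minor allele frequency, computed over non-missing
#' calls across all samples, is at or below `maf_min` (strict `>` retains).
#'
#' @param data a [gtdata] object.
#' @param maf_min exclusive MAF threshold.
#' @return list with `data` and `report`.
#' @export
filter_maf <- function(data, maf_min = 0.05) {
  maf <- variant_maf(data)
  keep <- !is.na(maf) & maf > maf_min
  if (!any(keep)) warning("MAF filter removed every variant")
  removed <- data$variants$id[!keep]
  out <- subset_gtdata(data, variants = which(keep))
  list(data = out, report = qc_report(data, out, removed, character(0), "maf"))
}

#' Windowed LD pruning
#'
#' Greedy per-chromosome pruning: in each window of
#' `cfg$prune_window_snps` consecutive surviving variants, while any pair has
#' r-squared above `cfg$prune_r2_max`, the member of the worst offending pair
#' with the lower MAF is removed (tie: the later position); the window then
#' advances by `cfg$prune_step_snps` surviving variants, and whole passes
#' repeat until no removal occurs. r-squared is the squared genotype
#' correlation of [genotype_r2()]. Output retains the original variant order.
#'
#' @param data a [gtdata] object with variants sorted by position.
#' @param cfg a [qc_config].
#' @return list with `data` and `report`.
#' @export
ld_prune <- function(data, cfg = qc_config()) {
  keep <- rep(TRUE, n_variants(data))
  maf <- variant_maf(data)
  g <- data$geno
  chroms <- data$variants$chrom
  for (chr in unique(chroms)) {
    idx_all <- which(chroms == chr)
    repeat {
      removed_any <- FALSE
      live <- idx_all[keep[idx_all]]
      if (length(live) < 2) break
      starts <- seq(1L, length(live), by = cfg$prune_step_snps)
      for (s in starts) {
        win <- live[s:min(s + cfg$prune_window_snps - 1L, length(live))]
        win <- win[keep[win]]
        repeat {
          if (length(win) < 2) break
          r2 <- suppressWarnings(
            stats::cor(g[, win, drop = FALSE],
                       use = "pairwise.complete.obs")^2)
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          if (r2[worst[1], worst[2]] <= cfg$prune_r2_max) break
          pair <- win[c(worst[1], worst[2])]
          drop_v <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
                    else if (maf[pair[2]] < maf[pair[1]]) pair[2]
                    else pair[which.max(data$variants$pos[pair])]
          keep[drop_v] <- FALSE
          win <- setdiff(win, drop_v)
          removed_any <- TRUE
        }
      }
      if (!removed_any) break
    }
  }
  removed <- data$variants$id[!keep]
  out <- subset_gtdata(data, variants = which(keep))
  list(data = out,
       report = qc_report(data, out, removed, character(0), "ld_prune"))
}

#' Serialize a QC report as tab-separated text
#'
#' @param report a report list from the filtering functions.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(
    sprintf("stage_order\t%s", paste(report$stage_order, collapse = ",")),
    sprintf("n_variants_in\t%d", report$n_variants_in),
    sprintf("n_variants_out\t%d", report$n_variants_out),
    sprintf("n_samples_in\t%d", report$n_samples_in),
    sprintf("n_samples_out\t%d", report$n_samples_out),
    sprintf("removed_variants\t%s", paste(report$removed_variants, collapse = ",")),
    sprintf("removed_samples\t%s", paste(report$removed_samples, collapse = ","))
  )
  write_text_lines(lines, path)
  invisible(path)
}
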