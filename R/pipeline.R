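#' Default pipeline configuration
#'
#' All thresholds default to the standard SNP-array analysis settings:
#' call rate > 0.95 (variants then samples), MAF > 0.05, LD pruning
#' 50/10/0.2, the [roh_config()] block, LD decay to 1 Mb at 1 cM/Mb, Ne for
#' generations 1..50, admixture k range 2..15 with 5-fold entry-mask CV,
#' scan K = 3 at BH alpha 0.05, F_ST flag threshold 0.5, 500 kb flanks.
#'
#' @param ped,map input genotype paths.
#' @param merge_ped,merge_map optional second dataset merged before QC.
#' @param out_dir output directory for tables and the manifest.
#' @param seed global seed; per-stage seeds derive from it.
#' @param autosomes optional chromosome whitelist for reading.
#' @param qc a [qc_config()].
#' @param roh a [roh_config()]; `NULL` skips the ROH stage.
#' @param genome_length_kb autosomal genome length for F_ROH.
#' @param ne_generations generations for the Ne trajectory.
#' @param ne_alpha mutation-correction constant for Ne.
#' @param admixture_k k values scanned by CV (`NULL` skips admixture).
#' @param scan_K,scan_alpha outlier-scan PC count and BH level.
#' @param fst_threshold per-marker F_ST flag threshold.
#' @param flank_bp candidate-window flank.
#' @param n_permutations pairwise-F_ST permutations.
#' @return a list of class `run_config`.
#' @export
run_config <- function(ped, map, merge_ped = NULL, merge_map = NULL,
                       out_dir = "popgenpipe_out", seed = 1L,
                       autosomes = NULL,
                       qc = qc_config(), roh = roh_config(),
                       genome_length_kb = PIG_AUTOSOME_KB,
                       ne_generations = 1:50, ne_alpha = 1,
                       admixture_k = 2:6, scan_K = 3L, scan_alpha = 0.05,
                       fst_threshold = 0.5, flank_bp = 5e5,
                       n_permutations = 200L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the nested `qc`
#' and `roh` maps mirror [qc_config()] and [roh_config()].
#'
#' @param path YAML file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$roh)) args$roh <- do.call(roh_config, y$roh)
  if (!is.null(y$admixture_k)) args$admixture_k <- as.integer(y$admixture_k)
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — read (and optionally merge), call-rate
#' QC, per-population diversity and LD/Ne on the call-rate-filtered data,
#' ROH on the same (non-MAF-filtered) data, then MAF filter + LD pruning
#' and the multi-population stages (PCA, IBS/neighbours, pairwise F_ST,
#' Nei/NJ, kNN network, admixture CV, outlier scan with candidate windows)
#' — writing each stage's tables under `cfg$out_dir` together with a JSON
#' manifest (seed, stage status, row counts, timings). A stage failure
#' aborts with the stage name; the partial manifest is still written.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly (list).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = list())
  t_all <- Sys.time()
  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      write_manifest(manifest, cfg)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(
      status = "ok",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    ), res$info)
    res$value
  }

  data <- stage("read", function() {
    d <- read_ped_map(cfg$ped, cfg$map, autosomes = cfg$autosomes)
    if (!is.null(cfg$merge_ped)) {
      d2 <- read_ped_map(cfg$merge_ped, cfg$merge_map,
                         autosomes = cfg$autosomes)
      mg <- merge_datasets(d, d2)
      list(value = mg$data,
           info = c(list(n_samples = n_samples(mg$data),
                         n_variants = n_variants(mg$data)), mg$report))
    } else {
      list(value = d, info = list(n_samples = n_samples(d),
                                  n_variants = n_variants(d)))
    }
  })

  data <- stage("qc_call_rate", function() {
    res <- filter_call_rate(data, cfg$qc)
    write_qc_report(res$report, file.path(cfg$out_dir, "qc_call_rate.tsv"))
    list(value = res$data,
         info = list(n_samples = n_samples(res$data),
                     n_variants = n_variants(res$data)))
  })

  pops <- unique(data$samples$population)

  stage("diversity", function() {
    div <- diversity_summary(data)
    write_tsv(div, file.path(cfg$out_dir, "diversity.tsv"))
    list(value = NULL, info = list(n_populations = nrow(div)))
  })

  stage("ld_ne", function() {
    rows <- 0L
    for (pop in pops) {
      sub <- subset_gtdata(data, samples = which(data$samples$population == pop))
      maf <- variant_maf(sub)
      sub <- subset_gtdata(sub, variants = which(!is.na(maf) & maf > 0))
      pairs <- ld_pairs(sub, 1e6)
      if (nrow(pairs) == 0) next
      curve <- ld_decay(sub)
      write_tsv(curve$bins,
                file.path(cfg$out_dir, paste0("ld_decay_", pop, ".tsv")))
      ne <- ne_from_ld(pairs, sample_n = n_samples(sub),
                       generations = cfg$ne_generations, alpha = cfg$ne_alpha)
      write_tsv(as.data.frame(ne),
                file.path(cfg$out_dir, paste0("ne_", pop, ".tsv")))
      rows <- rows + nrow(ne)
    }
    list(value = NULL, info = list(n_ne_points = rows))
  })

  if (!is.null(cfg$roh)) {
    stage("roh", function() {
      segs <- detect_roh(data, cfg$roh)
      write_tsv(segs, file.path(cfg$out_dir, "roh_segments.tsv"))
      fr <- froh(segs, data$samples$sample_id, cfg$genome_length_kb)
      write_tsv(fr, file.path(cfg$out_dir, "froh.tsv"))
      write_tsv(froh_population_summary(fr, data$samples$population),
                file.path(cfg$out_dir, "froh_by_population.tsv"))
      list(value = NULL, info = list(n_segments = nrow(segs)))
    })
  } else {
    manifest$stages[["roh"]] <- list(status = "skipped")
  }

  maf_data <- stage("qc_maf", function() {
    res <- filter_maf(data, cfg$qc$maf_min)
    list(value = res$data, info = list(n_variants = n_variants(res$data)))
  })

  pruned <- stage("ld_prune", function() {
    res <- ld_prune(maf_data, cfg$qc)
    list(value = res$data, info = list(n_variants = n_variants(res$data)))
  })

  pca <- stage("pca", function() {
    p <- gt_pca(pruned, n_components = min(10L, n_samples(pruned) - 1L))
    write_tsv(data.frame(sample_id = rownames(p$scores),
                         population = pruned$samples$population,
                         p$scores),
              file.path(cfg$out_dir, "pca_scores.tsv"))
    list(value = p,
         info = list(pct_variance = round(p$pct_variance[1:3], 4)))
  })

  stage("structure", function() {
    ibs <- ibs_matrix(pruned)
    nn <- nearest_neighbors(ibs, k = min(5L, n_samples(pruned) - 1L))
    write_tsv(nn, file.path(cfg$out_dir, "nearest_neighbors.tsv"))
    info <- list()
    if (length(pops) >= 2) {
      pf <- pairwise_fst(pruned, n_permutations = cfg$n_permutations,
                         seed = cfg$seed)
      utils::write.table(pf$fst, file.path(cfg$out_dir, "pairwise_fst.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(pf$nm, file.path(cfg$out_dir, "pairwise_nm.tsv"),
                         sep = "\t", quote = FALSE)
      nei <- nei_distance(pruned)
      utils::write.table(nei, file.path(cfg$out_dir, "nei_distance.tsv"),
                         sep = "\t", quote = FALSE)
      if (length(pops) >= 3) {
        nj <- nj_tree(nei)
        write_text_lines(nj$newick, file.path(cfg$out_dir, "nj_tree.nwk"))
      }
      net <- knn_network(1 - ibs, k = min(5L, n_samples(pruned) - 1L),
                         populations = pruned$samples$population)
      write_tsv(net$edges, file.path(cfg$out_dir, "knn_edges.tsv"))
      info$n_components <- max(net$components)
    }
    list(value = NULL, info = info)
  })

  if (!is.null(cfg$admixture_k)) {
    stage("admixture", function() {
      cv <- cv_scan(pruned, cfg$admixture_k, seed = cfg$seed,
                    max_iter = 300L, n_restarts = 2L)
      write_tsv(cv, file.path(cfg$out_dir, "admixture_cv.tsv"))
      best_k <- cv$k[which.min(cv$cv_error)]
      fit <- fit_admixture(pruned, best_k, seed = cfg$seed)
      q <- data.frame(sample_id = rownames(fit$q),
                      population = pruned$samples$population, fit$q)
      write_tsv(q, file.path(cfg$out_dir,
                             paste0("admixture_q_k", best_k, ".tsv")))
      list(value = NULL, info = list(best_k = best_k,
                                     loglik = round(fit$loglik, 2)))
    })
  } else {
    manifest$stages[["admixture"]] <- list(status = "skipped")
  }

  stage("selection_scan", function() {
    scan <- pcadapt_scan(maf_data, K = cfg$scan_K, alpha = cfg$scan_alpha,
                         scores = pca$scores)
    fst <- per_marker_fst(maf_data)
    fl <- fst_flags(fst$per_marker$fst, cfg$fst_threshold)
    tab <- merge(as.data.frame(scan),
                 fst$per_marker[, c("id", "fst")], by = "id", sort = FALSE)
    tab$flagged_fst <- fst_flags(tab$fst, cfg$fst_threshold)
    write_tsv(tab, file.path(cfg$out_dir, "selection_scan.tsv"))
    anchors <- tab[tab$flagged | tab$flagged_fst, c("chrom", "pos", "id")]
    win <- candidate_windows(anchors, cfg$flank_bp)
    write_bed(win, file.path(cfg$out_dir, "candidate_windows.bed"))
    list(value = NULL,
         info = list(lambda_gc = round(attr(scan, "lambda_gc"), 3),
                     n_flagged_pcadapt = sum(tab$flagged),
                     n_flagged_fst = sum(fl, na.rm = TRUE),
                     n_windows = nrow(win)))
  })

  manifest$total_seconds <-
    round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 2)
  write_manifest(manifest, cfg)
  invisible(manifest)
}

write_manifest <- function(manifest, cfg) {
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
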