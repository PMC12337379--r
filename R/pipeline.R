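#' Evaluate DMR recovery against the planted truth
#'
#' Interval-level sensitivity (fraction of planted intervals matched by a
#' called segment at Jaccard >= `jaccard`) and base-level precision
#' (fraction of called bases lying inside planted intervals).
#'
#' @param segs Called segment table (`chrom`, `start`, `end`).
#' @param truth A `synthetic_truth` from [simulate_cohort()].
#' @param jaccard Interval-match threshold (default 0.5).
#' @return List with `sensitivity`, `base_precision`, `n_planted`,
#'   `n_called` and a per-interval table of best Jaccard indices.
#' @export
evaluate_recovery <- function(segs, truth, jaccard = 0.5) {
  planted <- rbind(truth$planted_hyper[, .(chrom, start, end)],
                   truth$planted_hypo[, .(chrom, start, end)])
  best <- numeric(nrow(planted))
  if (nrow(segs) > 0L) {
    for (i in seq_len(nrow(planted))) {
      cand <- segs[chrom == planted$chrom[i]]
      if (nrow(cand) == 0L) next
      inter <- pmax(0, pmin(cand$end, planted$end[i]) -
                      pmax(cand$start, planted$start[i]))
      uni <- (cand$end - cand$start) +
        (planted$end[i] - planted$start[i]) - inter
      best[i] <- max(inter / uni)
    }
  }
  base_precision <- NA_real_
  if (nrow(segs) > 0L) {
    called <- reduce(GRanges(segs$chrom,
                             IRanges(segs$start + 1L, segs$end)))
    pl <- reduce(GRanges(planted$chrom,
                         IRanges(planted$start + 1L, planted$end)))
    inter <- GenomicRanges::intersect(called, pl)
    base_precision <- sum(width(inter)) / sum(width(called))
  }
  list(sensitivity = mean(best >= jaccard),
       base_precision = base_precision,
       n_planted = nrow(planted), n_called = nrow(segs),
       per_interval = data.table(planted, best_jaccard = best))
}

# deterministic per-stage substream seeds below 2^31
.stage_seed <- function(seed, stage) {
  stages <- c("annotation", "cohort", "pathways", "randomize", "gsea",
              "cnv", "segment_null")
  i <- match(stage, stages)
  as.integer((as.numeric(seed) * 1009 + i * 101) %% (2^31 - 1)) + 1L
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains every stage on a synthetic cohort: simulation (methylomes,
#' annotation, pathways, truth ledger), HMM segmentation, DMR selection,
#' the two null models, context/repeat/metaplot annotation, preranked
#' GSEA, copy-number burden and cohort discrimination. All randomness
#' derives from `seed` through fixed per-stage substreams, so a rerun
#' with the same arguments writes byte-identical outputs; a run manifest
#' (seed, full configuration, package version, output checksums) is
#' written alongside.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param cfg A [sim_config()].
#' @param params An [hmm_params()].
#' @param filt A [filter_config()].
#' @param alpha Mann-Whitney selection threshold.
#' @param n_perm_labels Label permutations for the null pipeline
#'   (default 50).
#' @param n_segment_sets Random segment sets for the GSEA null
#'   (default 50).
#' @param gsea_n_perm GSEA permutations (default 1000).
#' @param bin_size CNV bin width in bp.
#' @param stages Character vector of stages to run, or `"all"`. Stages:
#'   `simulate`, `dmr`, `select`, `randomize`, `context`, `gsea`, `cnv`,
#'   `discriminate`.
#' @return Invisibly, a list with the main in-memory results (`ann`,
#'   `truth`, `cm`, `segments`, `selection`, `recovery`, `label_null`,
#'   `segment_null`, `context`, `gsea`, `cnv`, `discriminate`).
#' @export
run_pipeline <- function(outdir, seed = 1L, cfg = sim_config(),
                         params = hmm_params(), filt = filter_config(),
                         alpha = 0.05, n_perm_labels = 50L,
                         n_segment_sets = 50L, gsea_n_perm = 1000L,
                         bin_size = 500e3, stages = "all") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c("simulate", "dmr", "select", "randomize", "context",
                  "gsea", "cnv", "discriminate")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0L)
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  res <- list()

  # -- simulate ------------------------------------------------------------
  ann <- simulate_annotation(cfg, .stage_seed(seed, "annotation"))
  sim <- simulate_cohort(cfg, ann, .stage_seed(seed, "cohort"))
  pw <- simulate_pathways(cfg, ann, sim$truth, .stage_seed(seed, "pathways"))
  truth <- sim$truth
  truth$enriched_pathway <- list(name = pw$enriched,
                                 planted_overlap = pw$planted_overlap)
  res$ann <- ann; res$truth <- truth; res$pathways <- pw$sets
  if ("simulate" %in% stages) {
    bdir <- file.path(outdir, "bedmethyl")
    dir.create(bdir, showWarnings = FALSE)
    for (m in sim$methylomes)
      write_bedmethyl(m, file.path(bdir, paste0(m$sample_id, ".bedmethyl")))
    write_sample_sheet(truth$samples, file.path(outdir, "sample_sheet.tsv"))
    write_bed(ann$genes[, .(chrom, start, end, name = gene_id, score = 0L,
                            strand)], file.path(outdir, "genes.bed"))
    write_bed(ann$repeats, file.path(outdir, "repeats.bed"))
    write_gmt(pw$sets, file.path(outdir, "pathways.gmt"))
    .write_json(list(
      planted_hyper = truth$planted_hyper,
      planted_hypo = truth$planted_hypo,
      global_hypo_shift = truth$global_hypo_shift,
      samples = truth$samples, planted_cnv = truth$planted_cnv,
      enriched_pathway = truth$enriched_pathway),
      file.path(outdir, "truth.json"))
  }

  cm <- build_cohort_matrix(sim$methylomes)
  res$cm <- cm

  # -- dmr -----------------------------------------------------------------
  ev <- pool_evidence(cm, eps = params$eps)
  segs <- viterbi_segment(ev, params)
  res$segments <- segs
  if ("dmr" %in% stages)
    fwrite(segs, file.path(outdir, "segments.tsv"), sep = "\t")

  # -- select --------------------------------------------------------------
  sel <- select_dmrs(segs, cm, filt, alpha)
  res$selection <- sel
  res$recovery <- evaluate_recovery(sel$table[selected == TRUE], truth)
  if ("select" %in% stages) {
    fwrite(sel$table, file.path(outdir, "dmr_table.tsv"), sep = "\t")
    sc <- data.table(segment_id = rownames(sel$scores), sel$scores)
    fwrite(sc, file.path(outdir, "dmr_scores.tsv"), sep = "\t")
    .write_json(c(sel$summary,
                  list(recovery_sensitivity = res$recovery$sensitivity,
                       recovery_base_precision = res$recovery$base_precision)),
                file.path(outdir, "dmr_summary.json"))
  }

  selected <- sel$table[selected == TRUE]
  pool <- filter_segments(segs, filt)
  calls_pool <- classify_context(pool, ann)

  # -- randomize -----------------------------------------------------------
  if ("randomize" %in% stages) {
    ln <- permute_label_null(cm, n_perm = n_perm_labels,
                             seed = .stage_seed(seed, "randomize"),
                             params = params, cfg = filt, alpha = alpha)
    res$label_null <- ln
    fwrite(data.table(permutation = seq_along(ln$null_counts),
                      n_selected = ln$null_counts),
           file.path(outdir, "label_null_counts.tsv"), sep = "\t")
    k <- max(1L, round(0.05 * nrow(pool)))
    sn <- random_segment_gsea_null(pool, calls_pool, k = k,
                                   pathways = pw$sets,
                                   n_sets = n_segment_sets,
                                   n_perm = gsea_n_perm,
                                   seed = .stage_seed(seed, "segment_null"))
    res$segment_null <- sn
    .write_json(list(true_count = ln$true_count,
                     null_median = ln$null_median,
                     null_max = ln$null_max,
                     segment_sets_k = k,
                     segment_null_median = sn$median,
                     segment_null_max = sn$max),
                file.path(outdir, "null_summary.json"))
  }

  # -- context -------------------------------------------------------------
  calls <- classify_context(selected, ann)
  enr <- if (nrow(selected) > 0L &&
               length(unique(selected$direction)) == 2L)
    context_enrichment(calls$class, selected$direction) else NULL
  res$context <- list(calls = calls, enrichment = enr,
                      repeat_fraction = repeat_content(selected,
                                                       ann$repeats))
  if ("context" %in% stages) {
    ctab <- copy(calls)
    ctab[, repeat_fraction := res$context$repeat_fraction]
    fwrite(ctab, file.path(outdir, "context_calls.tsv"), sep = "\t")
    if (!is.null(enr))
      .write_json(list(table = as.data.frame.matrix(enr$table),
                       chisq = enr$chisq, df = enr$df,
                       p_value = enr$p_value,
                       promoter_or = enr$promoter_or),
                  file.path(outdir, "context_enrichment.json"))
    cu <- coverage_uniformity(sim$methylomes[[1L]], ann$repeats)
    .write_json(cu, file.path(outdir, "coverage_uniformity.json"))
    for (d in intersect(c("hyper", "hypo"), unique(selected$direction))) {
      mp <- metaplot(selected[direction == d], cm)
      fwrite(mp, file.path(outdir, paste0("metaplot_", d, ".tsv")),
             sep = "\t")
    }
  }

  # -- gsea ----------------------------------------------------------------
  deltas <- aggregate_gene_deltas(selected, calls)
  gres <- NULL
  if (nrow(deltas) > 0L) {
    ranked <- setNames(deltas$delta, deltas$gene_id)
    gres <- gsea_preranked(ranked, pw$sets, n_perm = gsea_n_perm,
                           seed = .stage_seed(seed, "gsea"))
  }
  res$gsea <- list(deltas = deltas, results = gres)
  if ("gsea" %in% stages && !is.null(gres))
    fwrite(gres, file.path(outdir, "gsea_results.tsv"), sep = "\t")

  # -- cnv -----------------------------------------------------------------
  bins <- make_bins(cfg$chrom_sizes, bin_size)
  counts <- simulate_cnv_counts(cfg, truth, bins,
                                .stage_seed(seed, "cnv"))
  prof <- cnv_call(cnv_normalize(counts, bins,
                                 groups = truth$samples$group))
  burden <- cnv_burden(prof)
  grp <- truth$samples$group
  bc_cmp <- compare_burden(burden[grp == "BC"], burden[grp == "nonBC"])
  res$cnv <- list(profile = prof, burden = burden, comparison = bc_cmp)
  if ("cnv" %in% stages) {
    out <- data.table(bins, counts)
    fwrite(out, file.path(outdir, "cnv_counts.tsv"), sep = "\t")
    fwrite(data.table(bins, round(prof$log2_ratio, 4)),
           file.path(outdir, "cnv_log2_ratio.tsv"), sep = "\t")
    .write_json(list(burden_pct = as.list(burden),
                     median_bc = bc_cmp$median_a,
                     median_nonbc = bc_cmp$median_b,
                     p_value = bc_cmp$p_value),
                file.path(outdir, "cnv_burden.json"))
  }

  # -- discriminate --------------------------------------------------------
  disc <- NULL
  if (nrow(selected) >= 2L) {
    ssel <- sel$scores[sel$table$selected, , drop = FALSE]
    pca <- dmr_pca(ssel)
    hc <- dmr_hclust(ssel, groups = grp)
    disc <- list(pca = pca, hclust = hc)
    if ("discriminate" %in% stages) {
      co <- data.table(sample_id = rownames(pca$coords),
                       round(pca$coords[, seq_len(min(4L, ncol(pca$coords))),
                                        drop = FALSE], 6))
      fwrite(co, file.path(outdir, "pca_coords.tsv"), sep = "\t")
      writeLines(hc$newick, file.path(outdir, "hclust.nwk"))
      fwrite(data.table(sample_id = names(hc$clusters),
                        cluster = hc$clusters, group = grp),
             file.path(outdir, "clusters.tsv"), sep = "\t")
    }
  }
  res$discriminate <- disc

  # -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, files))
  .write_json(list(
    seed = seed,
    stages = stages,
    config = cfg[setdiff(names(cfg), "cnv_intervals")],
    cnv_intervals = as.data.frame(cfg$cnv_intervals),
    hmm_params = unclass(params),
    filter_config = unclass(filt),
    alpha = alpha,
    package_version = as.character(utils::packageVersion("uromethylome")),
    checksums = as.list(setNames(unname(sums), files))),
    file.path(outdir, "manifest.json"))
  invisible(res)
}
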