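#' Configuration for the synthetic urinary-methylome generator
#'
#' Returns the full set of generator parameters with defaults emulating the
#' cohort the analysis is designed for: 13 bladder-cancer (BC) and 8
#' non-cancer urine samples, per-sample tumour DNA fractions spanning a
#' realistic range, promoter-biased hypermethylation and intergenic/
#' repeat-biased hypomethylation blocks, mild global tumour
#' hypomethylation, clonal arm-scale copy-number events, and 50 pathway
#' gene sets with one planted enriched pathway. The default genome is a
#' desk-scale two-chromosome layout; every field can be overridden.
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    # cohort
    n_bc = 13L, n_nonbc = 8L,
    tf_range = c(0.3, 0.65),        # BC tumour fractions, uniform
    tiers = "high",                  # "high" (all samples) or "mixed"
    depth_high = 20, depth_low = 3,  # mean valid-call depth per tier
    # genome layout
    chrom_sizes = c(chr1 = 10e6, chr2 = 10e6),
    n_genes = 200L,
    gene_length_range = c(10e3, 30e3),
    exons_per_gene = c(4L, 8L),
    cpg_bg_spacing = 150,            # mean bp between background CpGs
    cpg_island_spacing = 40,         # mean bp between island CpGs
    island_halfwidth = 1000L,        # CpG island extent around each TSS
    promoter_window = 3000L,         # promoter = TSS +/- this many bp
    repeat_fraction = 0.52,          # target repeat share of intergenic bp
    repeat_len_range = c(200, 2000),
    # methylation model
    baseline_promoter = 0.1,
    baseline_background = 0.8,
    baseline_conc = 60,              # Beta concentration of the baseline jitter
    global_hypo_shift = 0.05,        # tumour background drop outside promoters
    noise_sd = 0.3,                  # per-sample per-region logit jitter
    noise_region_bp = 5000L,
    # planted differential regions (hypo majority, as in tumour genomes)
    n_hyper = 20L, hyper_level = 0.85, hyper_promoter_frac = 0.7,
    hyper_len_range = c(1000, 2500),
    n_hypo = 50L, hypo_level = 0.1, hypo_intergenic_frac = 0.7,
    hypo_len_range = c(2500, 5000),
    min_cpgs_planted = 10L,
    # copy number: clonal events shared by all BC samples
    cnv_intervals = data.table(chrom = "chr1", start = 0L, end = 4e6,
                               copy = 4L),
    cnv_reads_per_mb = 400,
    # pathways
    n_pathways = 50L, pathway_size_range = c(10L, 30L),
    enriched_frac = 0.6, enriched_size = 20L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$n_bc >= 1L, cfg$n_nonbc >= 1L,
            all(cfg$tf_range >= 0), all(cfg$tf_range <= 1),
            cfg$baseline_promoter >= 0, cfg$baseline_background <= 1,
            cfg$global_hypo_shift >= 0, cfg$global_hypo_shift < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome annotation
#'
#' Generates a compact genome with non-overlapping genes (each with a
#' TSS-proximal CpG island of elevated CpG density), exon structure,
#' and repeat intervals tiling roughly half of intergenic space.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed; when given the output is fully
#'   reproducible.
#' @return A `genome_annotation`: list with `chrom_sizes`, `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`), `exons`,
#'   `repeats`, `cpg` (site coordinates used by [simulate_cohort()]) and
#'   `promoter_window`.
#' @export
simulate_annotation <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(cfg$chrom_sizes)
  n_per <- table(factor(
    rep(chroms, length.out = cfg$n_genes), levels = chroms))

  genes_l <- list(); exons_l <- list(); reps_l <- list(); cpg_l <- list()
  gid <- 0L
  for (ch in chroms) {
    size <- cfg$chrom_sizes[[ch]]
    ng <- as.integer(n_per[[ch]])
    if (ng > 0L) {
      slot <- size / ng
      glen <- runif(ng, cfg$gene_length_range[1L], cfg$gene_length_range[2L])
      if (any(glen + 2 * cfg$promoter_window + 2000 > slot))
        stop("chromosome too small for requested gene count/length")
      margin <- cfg$promoter_window + 1000
      gstart <- floor((seq_len(ng) - 1L) * slot + margin +
                        runif(ng, 0, slot - glen - 2 * margin))
      gend <- floor(gstart + glen)
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      tss <- ifelse(strand == "+", gstart, gend)
      ids <- sprintf("gene_%04d", gid + seq_len(ng))
      gid <- gid + ng
      genes_l[[ch]] <- data.table(gene_id = ids, chrom = ch,
                                  start = as.integer(gstart),
                                  end = as.integer(gend),
                                  strand = strand, tss = as.integer(tss))
      # exons: one per equal-width chunk of the gene span
      ex <- lapply(seq_len(ng), function(i) {
        k <- sample(cfg$exons_per_gene[1L]:cfg$exons_per_gene[2L], 1L)
        w <- (gend[i] - gstart[i]) / k
        es <- floor(gstart[i] + (seq_len(k) - 1L) * w)
        ee <- pmin(floor(es + runif(k, 100, 400)), gend[i])
        data.table(gene_id = ids[i], chrom = ch, start = as.integer(es),
                   end = as.integer(ee))
      })
      exons_l[[ch]] <- rbindlist(ex)
    }
    # repeats tile intergenic gaps
    gaps <- .interval_complement(genes_l[[ch]], size, ch)
    reps_l[[ch]] <- .tile_repeats(gaps, cfg)
    # CpG sites: background + islands around each TSS
    nbg <- ceiling(size / cfg$cpg_bg_spacing * 1.3)
    bg <- cumsum(2L + stats::rgeom(nbg, 1 / cfg$cpg_bg_spacing))
    bg <- bg[bg < size - 1L]
    isl <- integer(0)
    if (ng > 0L) {
      isl <- unlist(lapply(genes_l[[ch]]$tss, function(t0) {
        nn <- ceiling(2 * cfg$island_halfwidth / cfg$cpg_island_spacing * 1.5)
        p <- t0 - cfg$island_halfwidth +
          cumsum(2L + stats::rgeom(nn, 1 / cfg$cpg_island_spacing))
        p[p < t0 + cfg$island_halfwidth & p > 0 & p < size - 1L]
      }))
    }
    cpg_l[[ch]] <- data.table(chrom = ch,
                              pos = sort(unique(c(bg, as.integer(isl)))))
  }
  ann <- list(chrom_sizes = cfg$chrom_sizes,
              genes = rbindlist(genes_l),
              exons = rbindlist(exons_l),
              repeats = rbindlist(reps_l),
              cpg = rbindlist(cpg_l),
              promoter_window = cfg$promoter_window)
  class(ann) <- "genome_annotation"
  ann
}

# complement of gene spans within [0, size)
.interval_complement <- function(genes, size, ch) {
  if (is.null(genes) || nrow(genes) == 0L)
    return(data.table(chrom = ch, start = 0L, end = as.integer(size)))
  g <- genes[order(start)]
  gs <- c(0L, g$end)
  ge <- c(g$start, as.integer(size))
  keep <- ge > gs
  data.table(chrom = ch, start = gs[keep], end = ge[keep])
}

.tile_repeats <- function(gaps, cfg) {
  out <- list()
  f <- cfg$repeat_fraction
  for (i in seq_len(nrow(gaps))) {
    pos <- gaps$start[i]
    ends <- gaps$end[i]
    while (pos < ends - cfg$repeat_len_range[1L]) {
      len <- runif(1, cfg$repeat_len_range[1L], cfg$repeat_len_range[2L])
      gap <- len * (1 - f) / f * stats::rexp(1)
      rs <- floor(pos + gap / 2)
      re <- min(floor(rs + len), ends)
      if (re > rs)
        out[[length(out) + 1L]] <- data.table(
          chrom = gaps$chrom[i], start = as.integer(rs), end = as.integer(re))
      pos <- re + gap / 2
    }
  }
  rbindlist(out)
}

#' Simulate a two-group urinary-methylome cohort with known truth
#'
#' Plants promoter-biased hypermethylation intervals and intergenic/
#' repeat-biased hypomethylation intervals into a tumour methylation
#' profile, applies a mild global hypomethylation shift outside promoters,
#' and mixes tumour and normal profiles per sample according to its tumour
#' fraction: the expected methylation fraction at site i in sample s is
#' `tf_s * pT_i + (1 - tf_s) * pN_i`, jittered on the logit scale per
#' sample and region. Coverage is Poisson around the sample's tier depth
#' and modified counts are binomial.
#'
#' @param cfg A [sim_config()].
#' @param ann A `genome_annotation` from [simulate_annotation()].
#' @param seed Optional integer seed.
#' @return List with `methylomes` (list of [sample_methylome()]) and
#'   `truth` (class `synthetic_truth`): planted intervals with target
#'   levels, per-sample tumour fractions, the global shift, and the planted
#'   copy-number events.
#' @export
simulate_cohort <- function(cfg, ann, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpg <- ann$cpg
  n <- nrow(cpg)

  # promoter membership (TSS +/- promoter_window) and island membership
  prom <- .in_intervals(cpg, .promoter_intervals(ann))
  island <- .in_intervals(cpg, data.table(
    chrom = ann$genes$chrom,
    start = pmax(0L, ann$genes$tss - cfg$island_halfwidth),
    end = ann$genes$tss + cfg$island_halfwidth))

  # planted intervals
  planted <- .plant_intervals(cfg, ann)
  hyper <- planted$hyper; hypo <- planted$hypo

  # baseline (normal) profile: low in islands, high elsewhere, Beta jitter;
  # planted hyper intervals sit on low-methylation (island/shore-like)
  # baseline so the planted gain is a real effect wherever it is placed
  in_hyper_pre <- .in_intervals(cpg, hyper)
  m0 <- ifelse(island | in_hyper_pre, cfg$baseline_promoter,
               cfg$baseline_background)
  pN <- rbeta(n, m0 * cfg$baseline_conc, (1 - m0) * cfg$baseline_conc)
  pN <- pmin(pmax(pN, 0.02), 0.98)

  # tumour profile: global hypomethylation outside promoters, then planted
  pT <- pN
  pT[!prom] <- pmax(pT[!prom] - cfg$global_hypo_shift, 0.02)
  in_hyper <- .in_intervals(cpg, hyper)
  in_hypo <- .in_intervals(cpg, hypo)
  pT[in_hyper] <- cfg$hyper_level
  pT[in_hypo] <- cfg$hypo_level

  # noise regions: planted intervals get their own id, rest fixed tiles
  region <- paste0(cpg$chrom, ":", cpg$pos %/% cfg$noise_region_bp)
  region[in_hyper] <- paste0("hyper", .which_interval(cpg, hyper))[in_hyper]
  region[in_hypo] <- paste0("hypo", .which_interval(cpg, hypo))[in_hypo]
  region <- factor(region)

  # samples
  samples <- .sample_sheet(cfg)
  methylomes <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    tf <- samples$tumour_fraction[s]
    depth <- if (samples$tier[s] == "high") cfg$depth_high else cfg$depth_low
    pmix <- tf * pT + (1 - tf) * pN
    eps <- rnorm(nlevels(region), 0, cfg$noise_sd)
    p <- plogis(qlogis(pmin(pmax(pmix, 1e-4), 1 - 1e-4)) +
                  eps[as.integer(region)])
    n_valid <- rpois(n, depth)
    n_mod <- rbinom(n, n_valid, p)
    keep <- n_valid > 0L
    rec <- data.table(chrom = cpg$chrom[keep], start = cpg$pos[keep],
                      end = cpg$pos[keep] + 1L, strand = ".",
                      n_mod = n_mod[keep], n_valid = n_valid[keep])
    methylomes[[s]] <- sample_methylome(
      rec, samples$sample_id[s], samples$group[s], samples$tier[s], tf)
  }

  truth <- structure(list(
    planted_hyper = hyper, planted_hypo = hypo,
    global_hypo_shift = cfg$global_hypo_shift,
    samples = samples,
    planted_cnv = as.data.table(cfg$cnv_intervals),
    enriched_pathway = NULL), class = "synthetic_truth")
  list(methylomes = methylomes, truth = truth)
}

.sample_sheet <- function(cfg) {
  ids <- c(sprintf("BC%02d", seq_len(cfg$n_bc)),
           sprintf("NC%02d", seq_len(cfg$n_nonbc)))
  group <- c(rep("BC", cfg$n_bc), rep("nonBC", cfg$n_nonbc))
  if (identical(cfg$tiers, "mixed")) {
    # emulates one-sample-per-flow-cell plus multiplexed runs
    tier <- c(rep(c("high", "low"), c(ceiling(cfg$n_bc * 0.7),
                                      cfg$n_bc - ceiling(cfg$n_bc * 0.7))),
              rep(c("high", "low"), c(ceiling(cfg$n_nonbc * 0.6),
                                      cfg$n_nonbc - ceiling(cfg$n_nonbc * 0.6))))
  } else {
    tier <- rep("high", length(ids))
  }
  tf <- c(runif(cfg$n_bc, cfg$tf_range[1L], cfg$tf_range[2L]),
          rep(0, cfg$n_nonbc))
  data.table(sample_id = ids, group = group, tier = tier,
             tumour_fraction = tf)
}

# choose non-overlapping planted intervals with enough CpGs
.plant_intervals <- function(cfg, ann) {
  prom_iv <- .promoter_intervals(ann)
  taken <- data.table(chrom = character(), start = integer(),
                      end = integer())
  count_cpg <- function(ch, s, e)
    sum(ann$cpg$chrom == ch & ann$cpg$pos >= s & ann$cpg$pos < e)
  overlaps_any <- function(ch, s, e, iv)
    nrow(iv) > 0L && any(iv$chrom == ch & iv$start < e & iv$end > s)

  # hyper: 70% on gene CpG islands (promoter), rest elsewhere
  n_prom <- round(cfg$hyper_promoter_frac * cfg$n_hyper)
  gsel <- ann$genes[sample(nrow(ann$genes), n_prom)]
  hyper <- data.table(chrom = gsel$chrom,
                      start = pmax(0L, gsel$tss - cfg$island_halfwidth),
                      end = gsel$tss + cfg$island_halfwidth,
                      level = cfg$hyper_level, gene_id = gsel$gene_id)
  taken <- rbind(taken, hyper[, .(chrom, start, end)])
  extra <- cfg$n_hyper - n_prom
  hyper_ext <- .random_intervals(extra, cfg$hyper_len_range, ann, cfg,
                                 avoid = rbind(prom_iv[, .(chrom, start, end)],
                                               taken),
                                 from_repeats = FALSE)
  if (nrow(hyper_ext) > 0L) {
    hyper_ext[, `:=`(level = cfg$hyper_level, gene_id = NA_character_)]
    hyper <- rbind(hyper, hyper_ext)
    taken <- rbind(taken, hyper_ext[, .(chrom, start, end)])
  }

  # hypo: 70% intergenic repeat-seeded, rest genic non-promoter
  n_ig <- round(cfg$hypo_intergenic_frac * cfg$n_hypo)
  gene_iv <- ann$genes[, .(chrom, start, end)]
  hypo_ig <- .random_intervals(n_ig, cfg$hypo_len_range, ann, cfg,
                               avoid = rbind(prom_iv[, .(chrom, start, end)],
                                             gene_iv, taken),
                               from_repeats = TRUE)
  taken <- rbind(taken, hypo_ig[, .(chrom, start, end)])
  hypo_gen <- .random_intervals(cfg$n_hypo - n_ig, cfg$hypo_len_range, ann,
                                cfg,
                                avoid = rbind(prom_iv[, .(chrom, start, end)],
                                              taken),
                                from_repeats = FALSE,
                                within = ann$genes[, .(chrom, start, end)])
  hypo <- rbind(hypo_ig, hypo_gen)
  hypo[, `:=`(level = cfg$hypo_level, gene_id = NA_character_)]
  list(hyper = hyper, hypo = hypo)
}

.random_intervals <- function(k, len_range, ann, cfg, avoid, from_repeats,
                              within = NULL) {
  out <- data.table(chrom = character(), start = integer(), end = integer())
  if (k <= 0L) return(out)
  tries <- 0L
  while (nrow(out) < k && tries < 500L * k) {
    tries <- tries + 1L
    len <- as.integer(runif(1, len_range[1L], len_range[2L]))
    if (from_repeats && nrow(ann$repeats) > 0L) {
      r <- ann$repeats[sample(nrow(ann$repeats), 1L)]
      ch <- r$chrom; s <- r$start
    } else if (!is.null(within)) {
      w <- within[sample(nrow(within), 1L)]
      if (w$end - w$start <= len) next
      ch <- w$chrom
      s <- as.integer(runif(1, w$start, w$end - len))
    } else {
      ch <- sample(names(ann$chrom_sizes), 1L)
      s <- as.integer(runif(1, 0, ann$chrom_sizes[[ch]] - len))
    }
    e <- s + len
    if (e > ann$chrom_sizes[[ch]]) next
    hit <- rbind(avoid, out)
    if (nrow(hit) > 0L && any(hit$chrom == ch & hit$start < e & hit$end > s))
      next
    ncpg <- sum(ann$cpg$chrom == ch & ann$cpg$pos >= s & ann$cpg$pos < e)
    if (ncpg < cfg$min_cpgs_planted) next
    out <- rbind(out, data.table(chrom = ch, start = s, end = e))
  }
  if (nrow(out) < k)
    stop("could not place ", k, " planted intervals; genome too crowded")
  out
}

.promoter_intervals <- function(ann) {
  data.table(chrom = ann$genes$chrom,
             start = pmax(0L, ann$genes$tss - ann$promoter_window),
             end = ann$genes$tss + ann$promoter_window,
             gene_id = ann$genes$gene_id)
}

# membership of cpg (chrom,pos) in a set of half-open intervals
.in_intervals <- function(cpg, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, nrow(cpg)))
  hit <- rep(FALSE, nrow(cpg))
  for (i in seq_len(nrow(iv)))
    hit <- hit | (cpg$chrom == iv$chrom[i] & cpg$pos >= iv$start[i] &
                    cpg$pos < iv$end[i])
  hit
}

.which_interval <- function(cpg, iv) {
  idx <- rep(NA_integer_, nrow(cpg))
  for (i in seq_len(nrow(iv))) {
    m <- cpg$chrom == iv$chrom[i] & cpg$pos >= iv$start[i] &
      cpg$pos < iv$end[i]
    idx[m] <- i
  }
  idx
}

#' Simulate shallow-coverage per-bin read counts with planted CNVs
#'
#' Expected counts follow the admixture model: a bin fully inside a planted
#' event of integer copy number `c` in a sample with tumour fraction `tf`
#' has expectation proportional to `tf * c/2 + (1 - tf)`; partial overlap
#' is width-weighted. Counts are Poisson.
#'
#' @param cfg A [sim_config()] (uses `cnv_reads_per_mb`).
#' @param truth A `synthetic_truth` (uses `samples` and `planted_cnv`;
#'   events apply to BC samples only).
#' @param bins `data.table` of non-overlapping bins (`chrom`, `start`,
#'   `end`) tiling the genome, e.g. from [make_bins()].
#' @param seed Optional integer seed.
#' @return Integer matrix bins x samples of simulated read counts.
#' @export
simulate_cnv_counts <- function(cfg, truth, bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bins <- as.data.table(bins)
  setorder(bins, chrom, start)
  if (any(bins[, .N, by = chrom][, N] > 1L)) {
    ov <- bins[, any(head(end, -1L) > tail(start, -1L)), by = chrom]$V1
    if (any(ov)) stop("bins overlap")
  }
  w <- bins$end - bins$start
  samples <- truth$samples
  cnv <- truth$planted_cnv
  # per-bin overlap-weighted copy number for a tumour genome
  cbin <- rep(2, nrow(bins))
  if (!is.null(cnv) && nrow(cnv) > 0L) {
    for (i in seq_len(nrow(cnv))) {
      ovl <- pmax(0, pmin(bins$end, cnv$end[i]) -
                    pmax(bins$start, cnv$start[i]))
      ovl[bins$chrom != cnv$chrom[i]] <- 0
      fr <- ovl / w
      cbin <- cbin * (1 - fr) + cnv$copy[i] * fr
    }
  }
  counts <- matrix(0L, nrow(bins), nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    tf <- if (samples$group[s] == "BC") samples$tumour_fraction[s] else 0
    lam <- w / 1e6 * cfg$cnv_reads_per_mb * (tf * cbin / 2 + (1 - tf))
    counts[, s] <- rpois(nrow(bins), lam)
  }
  counts
}

#' Simulate pathway gene sets with one planted enriched pathway
#'
#' Generates `n_pathways` gene sets over the annotation's gene universe.
#' One designated set draws a configurable fraction of its members
#' (default 60%) from the genes carrying planted promoter hypermethylation,
#' so that delta-ranked enrichment analysis has a known positive control;
#' all other sets are uniform draws.
#'
#' @param cfg A [sim_config()].
#' @param ann A `genome_annotation`.
#' @param truth A `synthetic_truth` (uses `planted_hyper$gene_id`).
#' @param seed Optional integer seed.
#' @return List with `sets` (named list of gene vectors), `enriched` (name
#'   of the designated set) and `planted_overlap` (its planted genes).
#' @export
simulate_pathways <- function(cfg, ann, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  universe <- ann$genes$gene_id
  planted <- truth$planted_hyper$gene_id
  planted <- planted[!is.na(planted)]
  sizes <- sample(cfg$pathway_size_range[1L]:cfg$pathway_size_range[2L],
                  cfg$n_pathways, replace = TRUE)
  if (max(sizes, cfg$enriched_size) > length(universe))
    stop("gene universe too small")
  nm <- sprintf("pathway_%02d", seq_len(cfg$n_pathways))
  which_enr <- sample(cfg$n_pathways, 1L)
  if (cfg$enriched_frac > 0) sizes[which_enr] <- cfg$enriched_size
  sets <- vector("list", cfg$n_pathways)
  for (i in seq_len(cfg$n_pathways)) {
    if (i == which_enr && cfg$enriched_frac > 0) {
      n_pl <- min(round(cfg$enriched_frac * sizes[i]), length(planted))
      pl <- sample(planted, n_pl)
      rest <- sample(setdiff(universe, pl), sizes[i] - n_pl)
      sets[[i]] <- sample(c(pl, rest))
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  names(sets) <- nm
  overlap <- intersect(sets[[which_enr]], planted)
  list(sets = sets, enriched = nm[which_enr], planted_overlap = overlap)
}
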