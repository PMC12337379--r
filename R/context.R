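#' Classify DMRs by genomic context
#'
#' Assigns each segment exactly one context class with any-overlap
#' precedence promoter > exonic > intronic > intergenic. The promoter is
#' the TSS +/- `ann$promoter_window` bp window (default 3 kb); the gene
#' body is the TSS-to-gene-end span, with introns the body minus exons.
#' `gene_ids` lists every gene whose promoter or body the segment
#' overlaps (semicolon-joined), so one segment can be associated with
#' several genes while keeping a single class.
#'
#' @param segs Segment table (`segment_id`, `chrom`, `start`, `end`).
#' @param ann A `genome_annotation`.
#' @return `data.table` with `segment_id`, `class` and `gene_ids`.
#' @export
classify_context <- function(segs, ann) {
  if (nrow(segs) == 0L)
    return(data.table(segment_id = character(), class = character(),
                      gene_ids = character()))
  unknown <- setdiff(unique(segs$chrom), names(ann$chrom_sizes))
  if (length(unknown) > 0L)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  qry <- GRanges(segs$chrom, IRanges(segs$start + 1L, segs$end))
  prom_iv <- .promoter_intervals(ann)
  prom <- GRanges(prom_iv$chrom, IRanges(prom_iv$start + 1L, prom_iv$end))
  exon <- GRanges(ann$exons$chrom,
                  IRanges(ann$exons$start + 1L, ann$exons$end))
  body <- GRanges(ann$genes$chrom,
                  IRanges(ann$genes$start + 1L, ann$genes$end))
  hit_p <- findOverlaps(qry, prom)
  hit_e <- findOverlaps(qry, exon)
  hit_b <- findOverlaps(qry, body)
  n <- nrow(segs)
  cls <- rep("intergenic", n)
  cls[unique(queryHits(hit_b))] <- "intronic"
  cls[unique(queryHits(hit_e))] <- "exonic"
  cls[unique(queryHits(hit_p))] <- "promoter"
  # gene association: any promoter-or-body overlap
  gmap <- vector("list", n)
  for (h in list(list(hit_p, prom_iv$gene_id),
                 list(hit_b, ann$genes$gene_id))) {
    q <- queryHits(h[[1]]); g <- h[[2]][subjectHits(h[[1]])]
    for (k in seq_along(q)) gmap[[q[k]]] <- c(gmap[[q[k]]], g[k])
  }
  gene_ids <- vapply(gmap, function(g)
    paste(sort(unique(g)), collapse = ";"), character(1L))
  gene_ids[cls == "intergenic"] <- ""
  data.table(segment_id = segs$segment_id, class = cls,
             gene_ids = gene_ids)
}

#' Context enrichment of hyper- versus hypomethylated DMRs
#'
#' Builds the class-by-direction contingency table, runs a Pearson
#' chi-square test without continuity correction, and reports the odds
#' ratio for a hypermethylated (vs hypomethylated) DMR to fall in a
#' promoter.
#'
#' @param class Character vector of context classes, one per DMR.
#' @param direction Matching vector of `"hyper"`/`"hypo"` calls.
#' @return List with `table`, `chisq` statistic, `df`, `p_value` and
#'   `promoter_or` (`NA` when no promoter class is present). Zero-margin
#'   rows are dropped with a warning before testing.
#' @export
context_enrichment <- function(class, direction) {
  stopifnot(length(class) == length(direction))
  tab <- table(class, direction)
  zero <- rowSums(tab) == 0L
  if (any(zero)) {
    warning("dropping zero-margin class(es): ",
            paste(rownames(tab)[zero], collapse = ", "))
    tab <- tab[!zero, , drop = FALSE]
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  promoter_or <- NA_real_
  if ("promoter" %in% rownames(tab) && all(c("hyper", "hypo") %in%
                                             colnames(tab))) {
    a <- tab["promoter", "hyper"]
    b <- sum(tab[rownames(tab) != "promoter", "hyper"])
    c <- tab["promoter", "hypo"]
    d <- sum(tab[rownames(tab) != "promoter", "hypo"])
    promoter_or <- (a * d) / (b * c)
  }
  list(table = tab, chisq = unname(ct$statistic),
       df = unname(ct$parameter), p_value = unname(ct$p.value),
       promoter_or = promoter_or)
}

#' Repeat content of segments
#'
#' Fraction of each segment's length overlapping repeat intervals.
#' Repeats are merged first, so the result is invariant to how the repeat
#' annotation is fragmented.
#'
#' @param segs Segment table (`chrom`, `start`, `end`).
#' @param repeats Interval table (`chrom`, `start`, `end`).
#' @return Numeric vector of fractions in `[0, 1]`, one per segment.
#' @export
repeat_content <- function(segs, repeats) {
  n <- nrow(segs)
  if (n == 0L) return(numeric(0))
  if (is.null(repeats) || nrow(repeats) == 0L) return(rep(0, n))
  rep_gr <- reduce(GRanges(repeats$chrom,
                           IRanges(repeats$start + 1L, repeats$end)))
  out <- numeric(n)
  qry <- GRanges(segs$chrom, IRanges(segs$start + 1L, segs$end))
  hits <- findOverlaps(qry, rep_gr)
  if (length(hits) > 0L) {
    ovl <- pmin(end(qry)[queryHits(hits)], end(rep_gr)[subjectHits(hits)]) -
      pmax(start(qry)[queryHits(hits)], start(rep_gr)[subjectHits(hits)]) + 1L
    agg <- tapply(ovl, queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / (segs$end - segs$start)
}

#' Coverage uniformity across repeat and non-repeat space
#'
#' Mean valid-call depth over CpG sites inside versus outside repeat
#' intervals, and their absolute difference — a check that long-read
#' coverage is not depressed in repetitive sequence.
#'
#' @param m A [sample_methylome()].
#' @param repeats Interval table (`chrom`, `start`, `end`).
#' @return List with `mean_depth_repeat`, `mean_depth_nonrepeat`,
#'   `abs_difference` and the site counts; the difference is `NA` (with
#'   `flagged = TRUE`) when one class has no sites.
#' @export
coverage_uniformity <- function(m, repeats) {
  r <- m$records
  if (nrow(r) == 0L) stop("empty methylome")
  inside <- .in_intervals(r[, .(chrom, pos = start)], repeats)
  mu_in <- if (any(inside)) mean(r$n_valid[inside]) else NA_real_
  mu_out <- if (any(!inside)) mean(r$n_valid[!inside]) else NA_real_
  list(mean_depth_repeat = mu_in, mean_depth_nonrepeat = mu_out,
       abs_difference = abs(mu_in - mu_out),
       n_repeat = sum(inside), n_nonrepeat = sum(!inside),
       flagged = is.na(mu_in) || is.na(mu_out))
}

#' Aggregate methylation metaplot over DMRs with flanks
#'
#' Rescales every segment body to `body_bins` bins, bins the fixed-width
#' flanks at `flank_binwidth` bp, and returns the per-bin
#' coverage-weighted mean methylation fraction of each group, pooled over
#' all segments. Hypermethylated DMR sets show a group-A body elevation
#' relative to the flanks, and vice versa for hypomethylated sets.
#'
#' @param segs Segment table (`chrom`, `start`, `end`).
#' @param cm A `cohort_matrix`.
#' @param flank Flank width in bp on each side (default 500).
#' @param body_bins Number of bins the body is rescaled to (default 50).
#' @param flank_binwidth Flank bin width in bp (default 25).
#' @param group_a,group_b Group labels.
#' @return `data.table` with `bin` (ordered index across
#'   upstream/body/downstream), `zone`, `mean_frac_A`, `mean_frac_B`.
#' @export
metaplot <- function(segs, cm, flank = 500L, body_bins = 50L,
                     flank_binwidth = 25L, group_a = "BC",
                     group_b = "nonBC") {
  stopifnot(nrow(segs) >= 1L)
  nf <- as.integer(flank / flank_binwidth)
  if (any(segs$end - segs$start < body_bins))
    warning("segment(s) shorter than body_bins bp; body bins interpolated")
  total <- 2L * nf + body_bins
  ia <- cm$samples$group == group_a
  ib <- cm$samples$group == group_b
  modm <- cm$mod * cm$mask
  valm <- cm$valid * cm$mask
  mA <- rowSums(modm[, ia, drop = FALSE])
  tA <- rowSums(valm[, ia, drop = FALSE])
  mB <- rowSums(modm[, ib, drop = FALSE])
  tB <- rowSums(valm[, ib, drop = FALSE])
  accA_m <- accA_t <- accB_m <- accB_t <- numeric(total)
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]; ch <- segs$chrom[i]
    rows <- which(cm$sites$chrom == ch & cm$sites$start >= s - flank &
                    cm$sites$start < e + flank)
    if (length(rows) == 0L) next
    pos <- cm$sites$start[rows]
    bin <- integer(length(pos))
    up <- pos < s
    dn <- pos >= e
    bd <- !up & !dn
    bin[up] <- pmin(nf - 1L, (pos[up] - (s - flank)) %/% flank_binwidth)
    bin[bd] <- nf + pmin(body_bins - 1L,
                         as.integer((pos[bd] - s) / (e - s) * body_bins))
    bin[dn] <- nf + body_bins +
      pmin(nf - 1L, (pos[dn] - e) %/% flank_binwidth)
    idx <- bin + 1L
    accA_m <- accA_m + as.numeric(tapply(mA[rows], factor(idx, levels = seq_len(total)), sum, default = 0))
    accA_t <- accA_t + as.numeric(tapply(tA[rows], factor(idx, levels = seq_len(total)), sum, default = 0))
    accB_m <- accB_m + as.numeric(tapply(mB[rows], factor(idx, levels = seq_len(total)), sum, default = 0))
    accB_t <- accB_t + as.numeric(tapply(tB[rows], factor(idx, levels = seq_len(total)), sum, default = 0))
  }
  data.table(
    bin = seq_len(total),
    zone = rep(c("upstream", "body", "downstream"),
               c(nf, body_bins, nf)),
    mean_frac_A = ifelse(accA_t > 0, accA_m / accA_t, NA_real_),
    mean_frac_B = ifelse(accB_t > 0, accB_m / accB_t, NA_real_))
}
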