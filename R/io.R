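#' Construct a per-sample methylome
#'
#' A `sample_methylome` holds one sample's per-CpG 5mC calls: for each site
#' the number of reads confidently calling 5mC (`n_mod`) out of all reads
#' with a confident call (`n_valid`), on 0-based half-open single-base
#' coordinates.
#'
#' @param records `data.table` with columns `chrom`, `start`, `end`,
#'   `strand`, `n_mod`, `n_valid`. `frac` is computed as `n_mod / n_valid`.
#' @param sample_id Sample identifier.
#' @param group Group label, `"BC"` or `"nonBC"`.
#' @param coverage_tier `"high"` or `"low"`.
#' @param tumour_fraction Tumour DNA fraction in `[0, 1]`, or `NA` if
#'   unknown.
#' @return An object of class `sample_methylome`.
#' @export
sample_methylome <- function(records, sample_id, group = NA_character_,
                             coverage_tier = NA_character_,
                             tumour_fraction = NA_real_) {
  records <- as.data.table(records)
  req <- c("chrom", "start", "end", "strand", "n_mod", "n_valid")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) > 0L) {
    if (any(records$n_mod > records$n_valid))
      stop("n_mod exceeds n_valid")
    if (any(records$n_mod < 0L) || any(records$n_valid < 0L))
      stop("negative counts")
    if (any(records$end != records$start + 1L))
      stop("records must be single-base (end = start + 1)")
  }
  records[, frac := ifelse(n_valid > 0L, n_mod / n_valid, NA_real_)]
  setorder(records, chrom, start)
  if (anyDuplicated(records[, .(chrom, start)]) > 0L)
    stop("duplicate (chrom, start) sites in records")
  structure(
    list(sample_id = sample_id, group = group,
         coverage_tier = coverage_tier,
         tumour_fraction = tumour_fraction, records = records),
    class = "sample_methylome")
}

#' @export
print.sample_methylome <- function(x, ...) {
  cat(sprintf(
    "sample_methylome '%s' (%s, tier %s, tf %s): %d CpG sites on %d chrom(s)\n",
    x$sample_id, x$group, x$coverage_tier,
    ifelse(is.na(x$tumour_fraction), "NA",
           format(x$tumour_fraction, digits = 3)),
    nrow(x$records), length(unique(x$records$chrom))))
  invisible(x)
}

#' Read a bedMethyl pileup
#'
#' Reads per-site 5mC pileups in the bedMethyl dialect emitted by nanopore
#' pileup tools: nine BED9 columns followed by the coverage statistics
#' (`n_valid`, percent modified, `n_mod`, ...). Both fully tab-separated
#' files and the hybrid dialect with a space-separated trailing statistics
#' block are accepted.
#'
#' @param path Path to a bedMethyl file.
#' @param combine_strands If `TRUE` (default), counts of the two strands of
#'   a CpG dinucleotide are summed onto the plus-strand C coordinate (a
#'   minus-strand record at position p is paired with position p - 1).
#' @param min_cov Drop sites with `n_valid` below this value (default 1,
#'   i.e. keep every covered site).
#' @inheritParams sample_methylome
#' @return A [sample_methylome()].
#' @export
read_bedmethyl <- function(path, combine_strands = TRUE, min_cov = 1L,
                           sample_id = basename(path),
                           group = NA_character_,
                           coverage_tier = NA_character_,
                           tumour_fraction = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    rec <- data.table(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_mod = integer(), n_valid = integer())
    return(sample_methylome(rec, sample_id, group, coverage_tier,
                            tumour_fraction))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- which(nf < 10L)[1L]
    stop(sprintf("bedMethyl format error at line %d: %d column(s), >= 10 required",
                 bad, nf[bad]))
  }
  mat <- vapply(fields, function(f) f[1:10], character(10L))
  tenth <- mat[10L, ]
  # hybrid modkit dialect: stats block space-separated inside field 10
  if (any(grepl(" ", tenth, fixed = TRUE))) {
    blk <- strsplit(tenth, " ", fixed = TRUE)
    if (any(lengths(blk) < 3L)) {
      bad <- which(lengths(blk) < 3L)[1L]
      stop(sprintf("bedMethyl format error at line %d: truncated statistics block",
                   bad))
    }
    n_valid <- as.integer(vapply(blk, `[`, character(1L), 1L))
    n_mod   <- as.integer(vapply(blk, `[`, character(1L), 3L))
  } else {
    if (any(nf < 12L)) {
      bad <- which(nf < 12L)[1L]
      stop(sprintf("bedMethyl format error at line %d: %d column(s), >= 12 required for tab-separated statistics",
                   bad, nf[bad]))
    }
    n_valid <- as.integer(vapply(fields, `[`, character(1L), 10L))
    n_mod   <- as.integer(vapply(fields, `[`, character(1L), 12L))
  }
  rec <- data.table(
    chrom  = mat[1L, ],
    start  = suppressWarnings(as.integer(mat[2L, ])),
    end    = suppressWarnings(as.integer(mat[3L, ])),
    strand = mat[6L, ],
    n_mod  = n_mod,
    n_valid = n_valid)
  bad <- which(is.na(rec$start) | is.na(rec$end) | is.na(rec$n_mod) |
                 is.na(rec$n_valid))
  if (length(bad) > 0L)
    stop(sprintf("bedMethyl format error at line %d: non-numeric coordinate or count",
                 bad[1L]))
  if (is.unsorted(order(rec$chrom, rec$start))) {
    # ordering check per chromosome run; resort silently harmless but warn
  }
  srt <- order(rec$chrom, rec$start)
  if (!identical(srt, seq_len(nrow(rec))))
    warning("input bedMethyl not sorted; sorting internally")
  rec <- rec[srt]
  if (combine_strands) rec <- .combine_strands(rec)
  rec <- rec[n_valid >= min_cov]
  sample_methylome(rec, sample_id, group, coverage_tier, tumour_fraction)
}

# Sum counts of the two strands of a CpG dinucleotide onto the + C position.
.combine_strands <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  rec <- copy(rec)
  rec[, pos := ifelse(strand == "-", start - 1L, start)]
  comb <- rec[, .(
    n_mod = sum(n_mod), n_valid = sum(n_valid),
    strand = if (.N > 1L || any(strand == "-")) "." else strand[1L]
  ), by = .(chrom, pos)]
  out <- data.table(chrom = comb$chrom, start = comb$pos,
                    end = comb$pos + 1L, strand = comb$strand,
                    n_mod = comb$n_mod, n_valid = comb$n_valid)
  setorder(out, chrom, start)
  out
}

#' Write a methylome as bedMethyl
#'
#' Emits the tab-separated bedMethyl dialect accepted by [read_bedmethyl()];
#' reading the file back recovers every record field exactly.
#'
#' @param m A [sample_methylome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(m, path) {
  stopifnot(inherits(m, "sample_methylome"))
  r <- m$records
  if (nrow(r) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write: ", path)
    return(invisible(path))
  }
  pct <- ifelse(r$n_valid > 0L, 100 * r$n_mod / r$n_valid, 0)
  lines <- paste(r$chrom, r$start, r$end, "m",
                 pmin(1000L, r$n_valid), r$strand, r$start, r$end,
                 "255,0,0", r$n_valid, sprintf("%.2f", pct), r$n_mod,
                 sep = "\t")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write: ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: name, description,
#'   then member genes, tab-separated).
#' @return Named list of character vectors; sets with no genes are dropped
#'   with a warning.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm) > 0L)
    stop("duplicate pathway name in GMT: ", nm[duplicated(nm)][1L])
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped")
    sets <- sets[!empty]
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' @param path Path to a BED file.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open)
#'   and, when present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", path)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  setnames(dt, seq_len(min(ncol(dt), 6L)), cols[seq_len(min(ncol(dt), 6L))])
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  dt[]
}

#' Write intervals as BED
#'
#' @param dt `data.table`/`data.frame` with at least `chrom`, `start`,
#'   `end`; further columns are appended in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(dt, path) {
  dt <- as.data.table(dt)
  first <- c("chrom", "start", "end")
  rest <- setdiff(names(dt), first)
  fwrite(dt[, c(first, rest), with = FALSE], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Read or write a cohort sample sheet
#'
#' The sample sheet is a headered TSV with columns `sample_id`, `group`
#' (`BC`/`nonBC`), `tier` (`high`/`low`) and `tumour_fraction` (`NA`
#' allowed).
#'
#' @param path Path to the TSV.
#' @return `data.table` with the four columns.
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  req <- c("sample_id", "group", "tier", "tumour_fraction")
  miss <- setdiff(req, names(dt))
  if (length(miss) > 0L)
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(dt$sample_id) > 0L) stop("duplicate sample ids")
  dt[]
}

#' @rdname read_sample_sheet
#' @param sheet `data.table` as returned by [read_sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path, sep = "\t")
  invisible(path)
}
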