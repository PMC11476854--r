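# Run-of-homozygosity detection with a sliding-window scanner in the
# style of PLINK 1.9 --homozyg, and Table-style per-sample summaries.
#
# Algorithm, per sample and chromosome:
#   1. every window of `window_snps` consecutive SNPs is "homozygous" when
#      it contains at most `window_het_max` heterozygous and
#      `window_missing_max` missing calls;
#   2. a SNP passes when the fraction of windows containing it that are
#      homozygous is at least `window_hit_fraction`;
#   3. maximal runs of passing SNPs are split wherever two adjacent SNPs
#      are more than `max_gap_kb` apart, then trimmed so both endpoints
#      are homozygous non-missing calls;
#   4. a run is emitted when it has at least `min_snps` SNPs, spans more
#      than `min_kb` kb, and its kb-per-SNP density does not exceed
#      `min_density_kb_per_snp`.
# Chromosomes with fewer SNPs than `window_snps` contain no windows and
# therefore yield no runs.  Segment length is end - start + 1 bp
# (1-based inclusive).

#' ROH scanner parameters
#'
#' The two headline constraints target long autozygous segments — at
#' least 100 SNPs (`--homozyg-snp` in PLINK terms) spanning more than
#' 1000 kb (`--homozyg-kb`); the remaining fields are the PLINK 1.9
#' `--homozyg` defaults and fully specify the scanner.
#'
#' @param min_snps minimum SNPs per emitted segment.
#' @param min_kb segments must span strictly more than this many kb.
#' @param window_snps SNPs per scanning window.
#' @param window_het_max maximum heterozygous calls per homozygous window.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param window_hit_fraction minimum fraction of homozygous windows
#'   covering a SNP for the SNP to pass.
#' @param max_gap_kb maximum gap (kb) between consecutive SNPs of a run.
#' @param min_density_kb_per_snp maximum kb per SNP within a segment.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 100L, min_kb = 1000, window_snps = 50L,
                       window_het_max = 1L, window_missing_max = 5L,
                       window_hit_fraction = 0.05, max_gap_kb = 1000,
                       min_density_kb_per_snp = 50) {
  if (min_snps < 1L) abort_arg("min_snps must be >= 1")
  if (min_kb <= 0) abort_arg("min_kb must be > 0")
  if (window_snps < 1L) abort_arg("window_snps must be >= 1")
  if (window_hit_fraction <= 0 || window_hit_fraction > 1) {
    abort_arg("window_hit_fraction must lie in (0, 1]")
  }
  structure(list(min_snps = as.integer(min_snps), min_kb = min_kb,
                 window_snps = as.integer(window_snps),
                 window_het_max = as.integer(window_het_max),
                 window_missing_max = as.integer(window_missing_max),
                 window_hit_fraction = window_hit_fraction,
                 max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp),
            class = "roh_params")
}

# Sliding sum of a logical/numeric vector over windows of width w.
run_sum <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs[(w + 1L):length(cs)] - cs[1L:(length(cs) - w)]
}

#' Scan one chromosome of one sample for runs of homozygosity
#'
#' Low-level scanner operating on genotype codes; most callers use
#' [detect_roh()] on a whole variant table instead.
#'
#' @param pos integer vector of strictly increasing 1-based positions.
#' @param geno integer codes per SNP: 0 hom-ref, 1 het, 2 hom-alt,
#'   NA missing (see [gt_code()]).
#' @param params a [roh_params()].
#' @return a data.table with columns `start_bp`, `end_bp`, `n_snps`,
#'   `length_kb`; zero rows when no run qualifies.
#' @export
roh_scan <- function(pos, geno, params = roh_params()) {
  n <- length(geno)
  if (length(pos) != n) abort_arg("pos and geno lengths differ")
  if (n > 1L && any(diff(pos) <= 0L)) {
    abort_arg("positions must be strictly increasing within a chromosome")
  }
  empty <- data.table(start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0))
  w <- params$window_snps
  if (n < w) return(empty)

  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  win_ok <- run_sum(het, w) <= params$window_het_max &
    run_sum(mis, w) <= params$window_missing_max
  n_win <- length(win_ok)

  # windows covering SNP i are those starting in [max(1, i-w+1), min(n_win, i)]
  idx <- seq_len(n)
  lo <- pmax(1L, idx - w + 1L)
  hi <- pmin(n_win, idx)
  cum_ok <- c(0, cumsum(win_ok))
  frac <- (cum_ok[hi + 1L] - cum_ok[lo]) / (hi - lo + 1L)
  pass <- frac >= params$window_hit_fraction

  segs <- list()
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hom <- !is.na(geno) & geno != 1L
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    # split at large inter-SNP gaps
    run_idx <- i0:i1
    gap_break <- which(diff(pos[run_idx]) > params$max_gap_kb * 1000)
    piece_start <- c(run_idx[1L], run_idx[gap_break + 1L])
    piece_end <- c(run_idx[gap_break], run_idx[length(run_idx)])
    for (p in seq_along(piece_start)) {
      a <- piece_start[p]; b <- piece_end[p]
      # trim to homozygous non-missing endpoints
      while (a <= b && !hom[a]) a <- a + 1L
      while (b >= a && !hom[b]) b <- b - 1L
      if (a > b) next
      n_snp <- b - a + 1L
      len_kb <- (pos[b] - pos[a] + 1L) / 1000
      if (n_snp >= params$min_snps && len_kb > params$min_kb &&
          len_kb / n_snp <= params$min_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <- data.table(
          start_bp = pos[a], end_bp = pos[b],
          n_snps = n_snp, length_kb = len_kb)
      }
    }
  }
  if (length(segs) == 0L) return(empty)
  rbindlist(segs)
}

#' Detect runs of homozygosity in a variant table
#'
#' Scans every requested sample chromosome by chromosome.  Only autosomal
#' records are scanned: X and mitochondrial genotypes never enter ROH
#' detection because the inbreeding coefficient derived from ROH is
#' defined on autosomes.
#'
#' @param table a [variant_table()].
#' @param samples samples to scan (default: all).
#' @param params a [roh_params()].
#' @param naming a [compartment_config()] classifying chromosomes.
#' @return a data.table of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_kb`, sorted by sample, chromosome and
#'   start.
#' @export
detect_roh <- function(table, samples = vt_samples(table),
                       params = roh_params(),
                       naming = compartment_config()) {
  stopifnot(inherits(params, "roh_params"))
  auto <- compartment_of(table$chrom, naming) == "autosome"
  out <- list()
  chroms <- unique(table$chrom[auto])
  for (s in samples) {
    for (cc in chroms) {
      sel <- auto & table$chrom == cc
      segs <- roh_scan(table$pos[sel], gt_code(table[[s]][sel]), params)
      if (nrow(segs)) {
        segs[, `:=`(sample_id = s, chrom = cc)]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(sample_id = character(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), length_kb = numeric(0)))
  }
  res <- rbindlist(out)
  setcolorder(res, c("sample_id", "chrom", "start_bp", "end_bp",
                     "n_snps", "length_kb"))
  setorder(res, sample_id, chrom, start_bp)
  res[]
}

#' Summarize one sample's ROH segments
#'
#' Produces the per-sample summary row: segment count (NSEG), cumulative
#' length (KB), mean segment length (KBAVG) and the genomic inbreeding
#' coefficient F_ROH = KB / autosomal genome length.  Segments on X or MT
#' are excluded from all four statistics.
#'
#' @param segments a data.table of segments for one sample (as returned
#'   by [detect_roh()]; a `chrom` column is optional for pre-summarized
#'   input, a `sample_id` column is optional but must be constant).
#' @param autosome_kb total autosomal genome length in kb (default: the
#'   2,212,284 kb canine autosomal assembly length).
#' @param naming a [compartment_config()].
#' @return a one-row data.table: `sample_id`, `nseg`, `total_kb`,
#'   `kb_avg`, `f_roh`.
#' @export
#' @examples
#' segs <- data.table::data.table(length_kb = rep(681002 / 298, 298))
#' summarize_roh(segs) # kb_avg 2285.24, f_roh 0.308
summarize_roh <- function(segments, autosome_kb = 2212284,
                          naming = compartment_config()) {
  if (autosome_kb <= 0) abort_arg("autosome_kb must be > 0")
  sid <- NA_character_
  if ("sample_id" %in% names(segments) && nrow(segments)) {
    ids <- unique(segments$sample_id)
    if (length(ids) > 1L) {
      abort_arg("segments from multiple samples: ", paste(ids, collapse = ", "))
    }
    sid <- ids
  }
  if ("chrom" %in% names(segments) && nrow(segments)) {
    segments <- segments[compartment_of(segments$chrom, naming) == "autosome"]
  }
  nseg <- nrow(segments)
  total_kb <- if (nseg) sum(segments$length_kb) else 0
  data.table(sample_id = sid, nseg = nseg, total_kb = total_kb,
             kb_avg = if (nseg) total_kb / nseg else 0,
             f_roh = total_kb / autosome_kb)
}

#' Summarize ROH segments for every sample
#'
#' @param segments output of [detect_roh()] (any number of samples).
#' @param samples sample ids to report (default: those present); samples
#'   without segments get an all-zero row.
#' @inheritParams summarize_roh
#' @return a data.table with one summary row per sample.
#' @export
summarize_roh_all <- function(segments, samples = NULL,
                              autosome_kb = 2212284,
                              naming = compartment_config()) {
  if (is.null(samples)) samples <- unique(segments$sample_id)
  rows <- lapply(samples, function(s) {
    out <- summarize_roh(segments[segments$sample_id == s, ],
                         autosome_kb, naming)
    out$sample_id <- s
    out
  })
  rbindlist(rows)
}
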