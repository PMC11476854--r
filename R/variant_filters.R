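# SNV retention chain: hard filters with strict-inequality thresholds,
# depth-percentile rule, SNP-only selection, known-variant exclusion,
# proband-unique selection and compartment partitioning.

#' Hard-filter thresholds
#'
#' Thresholds for the standard short-variant hard filters.  A record fails
#' a filter only when the annotation is present and violates the strict
#' inequality (QD < qd_min fails, QD == qd_min passes, FS > fs_max fails,
#' and so on); records lacking an annotation pass that filter, mirroring
#' how VariantFiltration treats missing annotations.
#'
#' The depth rule removes records whose site-level DP lies strictly on the
#' `dp_direction` side of the `dp_quantile` nearest-rank percentile of all
#' DP values in the table being filtered.  The default direction,
#' `"below"`, discards records with DP under the 75th percentile, i.e.
#' keeps only the deepest quarter of sites; set `dp_quantile = NA` to
#' disable the depth rule entirely.
#'
#' @param qd_min minimum QD (quality by depth).
#' @param fs_max maximum FS (Fisher strand bias, Phred).
#' @param mq_min minimum MQ (RMS mapping quality).
#' @param sor_max maximum SOR (symmetric odds ratio strand bias).
#' @param mqranksum_min minimum MQRankSum.
#' @param readposranksum_min minimum ReadPosRankSum.
#' @param dp_quantile quantile of site DP used as depth cutoff, in (0,1);
#'   NA disables the depth rule.
#' @param dp_direction `"below"` discards records with DP strictly below
#'   the cutoff; `"above"` discards records strictly above it.
#' @param dp_method `"nearest_rank"` (sorted value at position
#'   `ceiling(q * n)`) or `"linear"` (interpolated, [stats::quantile()]
#'   type 7).
#' @return a list of class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(qd_min = 2.0, fs_max = 60.0, mq_min = 56.0,
                                   sor_max = 3.0, mqranksum_min = -12.5,
                                   readposranksum_min = -8.0,
                                   dp_quantile = 0.75,
                                   dp_direction = c("below", "above"),
                                   dp_method = c("nearest_rank", "linear")) {
  if (!is.na(dp_quantile) && (dp_quantile <= 0 || dp_quantile >= 1)) {
    abort_arg("dp_quantile must lie strictly between 0 and 1")
  }
  structure(list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
                 sor_max = sor_max, mqranksum_min = mqranksum_min,
                 readposranksum_min = readposranksum_min,
                 dp_quantile = dp_quantile,
                 dp_direction = match.arg(dp_direction),
                 dp_method = match.arg(dp_method)),
            class = "hard_filter_thresholds")
}

#' Depth-percentile threshold
#'
#' Nearest-rank quantile: the value at position `ceiling(q * n)` (1-based)
#' of the sorted sample.  This definition is exact and implementation
#' independent; `method = "linear"` gives the usual interpolated quantile
#' instead.
#'
#' @param dp_values numeric vector of site depths (NA values are dropped).
#' @param q quantile in (0,1).
#' @param method `"nearest_rank"` or `"linear"`.
#' @return the threshold value.
#' @export
#' @examples
#' dp_quantile_threshold(1:100, 0.75) # 75
dp_quantile_threshold <- function(dp_values, q = 0.75,
                                  method = c("nearest_rank", "linear")) {
  method <- match.arg(method)
  dp_values <- dp_values[!is.na(dp_values)]
  if (length(dp_values) == 0L) abort_arg("dp_values must be non-empty")
  if (q <= 0 || q >= 1) abort_arg("q must lie strictly between 0 and 1")
  if (method == "nearest_rank") {
    sort(dp_values)[ceiling(q * length(dp_values))]
  } else {
    unname(quantile(dp_values, q, type = 7))
  }
}

FILTER_NAMES <- c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum", "DP")

#' Apply hard filters to a variant table
#'
#' Evaluates every record against [hard_filter_thresholds()].  The DP
#' cutoff is computed from the DP values of the table as given, so the
#' depth rule always refers to the full call set handed to this function,
#' not to any later subset.
#'
#' @param table a [variant_table()].
#' @param thresholds a [hard_filter_thresholds()].
#' @return a data.table with one row per record: `chrom`, `pos`, `passed`,
#'   and `reasons` (list column of failed filter names; empty when
#'   passed).
#' @export
apply_hard_filters <- function(table, thresholds = hard_filter_thresholds()) {
  stopifnot(inherits(thresholds, "hard_filter_thresholds"))
  n <- nrow(table)
  fail <- matrix(FALSE, nrow = n, ncol = length(FILTER_NAMES),
                 dimnames = list(NULL, FILTER_NAMES))
  viol <- function(x, cmp, thr) !is.na(x) & cmp(x, thr)
  fail[, "QD"] <- viol(table$QD, `<`, thresholds$qd_min)
  fail[, "FS"] <- viol(table$FS, `>`, thresholds$fs_max)
  fail[, "MQ"] <- viol(table$MQ, `<`, thresholds$mq_min)
  fail[, "SOR"] <- viol(table$SOR, `>`, thresholds$sor_max)
  fail[, "MQRankSum"] <- viol(table$MQRankSum, `<`, thresholds$mqranksum_min)
  fail[, "ReadPosRankSum"] <- viol(table$ReadPosRankSum, `<`,
                                   thresholds$readposranksum_min)
  if (!is.na(thresholds$dp_quantile) && any(!is.na(table$DP))) {
    cut <- dp_quantile_threshold(table$DP, thresholds$dp_quantile,
                                 method = thresholds$dp_method)
    if (thresholds$dp_direction == "below") {
      fail[, "DP"] <- viol(table$DP, `<`, cut)
    } else {
      fail[, "DP"] <- viol(table$DP, `>`, cut)
    }
  }
  reasons <- apply(fail, 1L, function(r) FILTER_NAMES[r], simplify = FALSE)
  data.table(chrom = table$chrom, pos = table$pos,
             passed = rowSums(fail) == 0L, reasons = reasons)
}

#' Keep only records passing the hard filters
#'
#' @inheritParams apply_hard_filters
#' @return the filtered [variant_table()].
#' @export
filter_passing <- function(table, thresholds = hard_filter_thresholds()) {
  v <- apply_hard_filters(table, thresholds)
  vt_rewrap(table[v$passed], vt_samples(table))
}

#' Select SNP-type records
#'
#' Retains records whose reference allele and every alternate allele are
#' single nucleotides; a record with any indel-style allele is dropped
#' whole, matching record-level SNP selection semantics.
#'
#' @param table a [variant_table()].
#' @return the SNP-only [variant_table()].
#' @export
select_snps <- function(table) {
  alts <- strsplit(table$alt, ",", fixed = TRUE)
  keep <- nchar(table$ref) == 1L &
    vapply(alts, function(a) length(a) > 0L && all(nchar(a) == 1L), logical(1))
  vt_rewrap(table[keep], vt_samples(table))
}

#' Exclude known variants
#'
#' Removes records matching a known-variant list by chromosome, position
#' and alleles.  With `match = "allele"` (default) a multi-allelic record
#' is removed only when every one of its alternate alleles is known at
#' that site; `match = "position"` removes any record at a known
#' chromosome/position.
#'
#' @param table a [variant_table()].
#' @param known a data.table with columns `chrom`, `pos`, `ref`, `alt`
#'   (see [read_known_variants()]); `alt` is a single allele per row.
#' @param match `"allele"` or `"position"`.
#' @return the filtered [variant_table()].
#' @export
exclude_known <- function(table, known, match = c("allele", "position")) {
  match <- match.arg(match)
  if (is.null(known) || nrow(known) == 0L) return(table)
  if (match == "position") {
    key_tab <- paste(table$chrom, table$pos)
    key_known <- unique(paste(known$chrom, known$pos))
    keep <- !(key_tab %in% key_known)
  } else {
    known_keys <- unique(paste(known$chrom, known$pos, known$ref, known$alt))
    alts <- strsplit(table$alt, ",", fixed = TRUE)
    nalt <- lengths(alts)
    rec <- rep(seq_len(nrow(table)), nalt)
    keys <- paste(table$chrom[rec], table$pos[rec], table$ref[rec],
                  unlist(alts))
    novel <- tabulate(rec[!(keys %chin% known_keys)], nbins = nrow(table))
    keep <- novel > 0L | nalt == 0L
  }
  vt_rewrap(table[keep], vt_samples(table))
}

#' Select proband-unique variants
#'
#' Retains records where every sample has a non-missing call, the proband
#' carries at least one alternate allele, and no other sample carries any
#' of the proband's alternate alleles in any dose — not even
#' heterozygously.  Haploid records (e.g. mitochondrial) are handled with
#' single-allele calls under the same rule.
#'
#' @param table a [variant_table()].
#' @param proband_id sample identifier of the proband.
#' @return the proband-unique [variant_table()].
#' @export
proband_unique <- function(table, proband_id) {
  samples <- vt_samples(table)
  if (!proband_id %in% samples) {
    abort_arg("proband '", proband_id, "' is not a sample of the table")
  }
  if (length(samples) < 2L) abort_arg("need at least 2 samples")
  controls <- setdiff(samples, proband_id)
  n <- nrow(table)
  if (n == 0L) return(table)

  allele_sets <- lapply(samples, function(s) gt_alleles(table[[s]]))
  names(allele_sets) <- samples
  keep <- vapply(seq_len(n), function(i) {
    calls <- lapply(allele_sets, `[[`, i)
    if (any(vapply(calls, is.null, logical(1)))) return(FALSE)  # call in all samples
    pro_alt <- setdiff(calls[[proband_id]], 0L)
    if (length(pro_alt) == 0L) return(FALSE)                    # proband carries no alt
    for (s in controls) {
      if (length(intersect(calls[[s]], pro_alt))) return(FALSE) # alt seen in a control
    }
    TRUE
  }, logical(1))
  vt_rewrap(table[keep], samples)
}

#' Partition records by genome compartment
#'
#' Counts records on autosomes, the X chromosome and mitochondrial DNA.
#'
#' @param table a [variant_table()].
#' @param naming a [compartment_config()].
#' @return named integer vector with elements `autosome`, `X`, `MT`;
#'   the counts sum to the record count.
#' @export
partition_by_compartment <- function(table, naming = compartment_config()) {
  comp <- compartment_of(table$chrom, naming)
  out <- base::table(comp)
  setNames(as.integer(out), names(out))
}
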