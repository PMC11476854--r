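# The in-memory form of a merged multi-sample SNV call set.
#
# A variant_table is a data.table with one row per VCF record:
#   chrom, pos (1-based), ref, alt (comma-joined alternate alleles),
#   the seven calling annotations as numeric columns (NA = absent),
#   then one character column per sample holding the raw GT string
#   ("0/1", "1" for haploid records, "./." or "." when missing).
# Simulation-truth columns (qc_fail, injected) may also be present; they
# are ignored by the writers and by all filtering logic.

ANNOTATION_KEYS <- c("DP", "QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")
RESERVED_COLS <- c("chrom", "pos", "ref", "alt", ANNOTATION_KEYS,
                   "qc_fail", "injected")

#' Construct a multi-sample variant table
#'
#' @param dt a data.frame/data.table with columns `chrom`, `pos`, `ref`,
#'   `alt` plus one genotype column per sample; annotation columns
#'   (DP, QD, FS, MQ, SOR, MQRankSum, ReadPosRankSum) are added as NA
#'   when missing.
#' @param samples character vector of sample identifiers, in column order.
#' @return a `variant_table` (a data.table sorted by chromosome and
#'   position, with a `samples` attribute).
#' @export
variant_table <- function(dt, samples) {
  dt <- as.data.table(dt)
  if (length(samples) == 0L) abort_arg("sample list must be non-empty")
  if (anyDuplicated(samples)) abort_arg("duplicate sample identifiers")
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", samples), names(dt))
  if (length(missing_cols)) {
    abort_arg("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (k in ANNOTATION_KEYS) if (!k %in% names(dt)) dt[, (k) := NA_real_]
  setcolorder(dt, c("chrom", "pos", "ref", "alt", ANNOTATION_KEYS,
                    intersect(c("qc_fail", "injected"), names(dt)), samples))
  setorder(dt, chrom, pos)
  setattr(dt, "samples", as.character(samples))
  setattr(dt, "class", c("variant_table", class(dt)))
  dt[]
}

#' Sample identifiers of a variant table
#'
#' @param x a `variant_table`.
#' @return character vector of sample ids.
#' @export
vt_samples <- function(x) {
  s <- attr(x, "samples", exact = TRUE)
  if (is.null(s)) s <- setdiff(names(x), RESERVED_COLS)
  s
}

# Rebuild a variant_table after row-subsetting operations that may have
# stripped attributes.
vt_rewrap <- function(dt, samples) {
  dt <- as.data.table(dt)
  setattr(dt, "samples", as.character(samples))
  if (!inherits(dt, "variant_table")) {
    setattr(dt, "class", c("variant_table", class(dt)))
  }
  dt[]
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records, %d samples (%s)\n",
              nrow(x), length(vt_samples(x)),
              paste(vt_samples(x), collapse = ", ")))
  NextMethod()
  invisible(x)
}

# ---- genotype string helpers -------------------------------------------

# Allele indices of a vector of GT strings, as a list of integer vectors;
# missing calls give integer(0) elements tagged NA via attribute-free
# convention: list element is NULL when the call is missing.
gt_alleles <- function(gt) {
  gt <- sub(":.*", "", gt)
  parts <- strsplit(gt, "[/|]")
  lapply(parts, function(p) {
    if (length(p) == 0L || any(p == "." | p == "")) return(NULL)
    as.integer(p)
  })
}

# TRUE when the call is missing ("./.", ".", ".|.", NA)
gt_is_missing <- function(gt) {
  gt <- sub(":.*", "", gt)
  is.na(gt) | gt == "." | grepl("(^|[/|])\\.([/|]|$)", gt)
}

#' Encode genotype strings as homozygosity codes
#'
#' Encodes diploid GT strings for ROH scanning: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, NA = missing or haploid.
#' Any call whose two allele indices are equal counts as homozygous.
#'
#' @param gt character vector of GT strings.
#' @return integer vector of codes.
#' @export
gt_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  a <- sub("[/|].*", "", gt)
  b <- sub(".*[/|]", "", gt)
  haploid <- !grepl("[/|]", gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !haploid & a != "." & b != "."
  ai <- suppressWarnings(as.integer(a[ok]))
  bi <- suppressWarnings(as.integer(b[ok]))
  code <- ifelse(ai != bi, 1L, ifelse(ai == 0L, 0L, 2L))
  out[ok] <- code
  out
}
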