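# File-format boundary: VCF, BED4 gene annotations, pedigree files and
# tab-separated known-variant lists.
#
# Coordinate conventions: VCF positions are 1-based and kept 1-based
# internally; BED input is 0-based half-open and is converted to 1-based
# inclusive on read (start + 1, end unchanged).  All interval arithmetic
# inside the package is 1-based inclusive.

#' Read a merged multi-sample VCF
#'
#' Parses a VCF 4.x file into a [variant_table()].  The seven calling
#' annotations (DP, QD, FS, MQ, SOR, MQRankSum, ReadPosRankSum) are taken
#' from INFO where present; absent keys are stored as NA and tolerated
#' downstream.  GT strings are preserved verbatim so that haploid calls
#' ("1") and missing calls ("./." or ".") survive a round-trip.
#'
#' @param path path to a VCF file.
#' @return a [variant_table()].
#' @export
read_merged_vcf <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) abort_arg("malformed VCF header in ", path, ": ",
                                  conditionMessage(e))
  )
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    abort_arg("VCF has no sample columns: ", path)
  }
  samples <- colnames(gt)[-1L]
  n <- nrow(fix)
  if (is.null(n)) n <- 0L
  ann <- lapply(ANNOTATION_KEYS, function(k) {
    if (n == 0L) return(numeric(0))
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", k, "=[^;]+"), fix[, "INFO"]))
    out <- rep(NA_real_, n)
    hit <- grepl(paste0("(^|;)", k, "="), fix[, "INFO"])
    out[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", k, "="), "", m)))
    out
  })
  names(ann) <- ANNOTATION_KEYS

  gt_cols <- list()
  if (n > 0L) {
    fmt <- strsplit(gt[, 1L], ":", fixed = TRUE)
    gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
    if (anyNA(gt_idx)) {
      abort_arg("GT field absent from FORMAT at record ",
                which(is.na(gt_idx))[1L], " of ", path)
    }
    for (s in samples) {
      fields <- strsplit(gt[, s], ":", fixed = TRUE)
      gt_cols[[s]] <- vapply(seq_len(n), function(i) {
        f <- fields[[i]]
        if (length(f) < gt_idx[i] || is.na(gt[i, s])) NA_character_
        else f[gt_idx[i]]
      }, character(1))
    }
    # an absent call is re-encoded with the record's ploidy: "." when the
    # record's observed calls are haploid, "./." otherwise
    gtm <- do.call(cbind, gt_cols)
    if (anyNA(gtm)) {
      row_haploid <- apply(gtm, 1L, function(r) {
        r <- r[!is.na(r)]
        length(r) > 0L && !any(grepl("[/|]", r))
      })
      for (s in samples) {
        miss <- is.na(gt_cols[[s]])
        gt_cols[[s]][miss] <- ifelse(row_haploid[miss], ".", "./.")
      }
    }
  } else {
    for (s in samples) gt_cols[[s]] <- character(0)
  }

  dt <- data.table(
    chrom = if (n) as.character(fix[, "CHROM"]) else character(0),
    pos = if (n) as.integer(fix[, "POS"]) else integer(0),
    ref = if (n) as.character(fix[, "REF"]) else character(0),
    alt = if (n) as.character(fix[, "ALT"]) else character(0)
  )
  for (k in ANNOTATION_KEYS) dt[, (k) := ann[[k]]]
  for (s in samples) dt[, (s) := gt_cols[[s]]]
  variant_table(dt, samples)
}

#' Write a variant table as plain-text VCF 4.2
#'
#' Emits samples in table order and INFO keys in the fixed order
#' DP, QD, FS, MQ, SOR, MQRankSum, ReadPosRankSum (absent annotations are
#' skipped).  Haploid genotypes are written as a single allele index;
#' missing calls as "./." (diploid) or "." (haploid).
#'
#' @param table a [variant_table()].
#' @param path output file path.
#' @return invisibly, the path written.
#' @export
write_vcf <- function(table, path) {
  samples <- vt_samples(table)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg",
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="%s">',
            ANNOTATION_KEYS, ANNOTATION_KEYS),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- hdr
  if (nrow(table) > 0L) {
    ann <- as.matrix(table[, ANNOTATION_KEYS, with = FALSE])
    info <- vapply(seq_len(nrow(table)), function(i) {
      present <- !is.na(ann[i, ])
      if (!any(present)) return(".")
      paste(paste0(ANNOTATION_KEYS[present], "=",
                   format(ann[i, present], trim = TRUE, scientific = FALSE,
                          digits = 15)),
            collapse = ";")
    }, character(1))
    gtm <- as.matrix(table[, samples, with = FALSE])
    body <- paste(table$chrom, table$pos, ".", table$ref, table$alt, ".", ".",
                  info, "GT",
                  apply(gtm, 1L, paste, collapse = "\t"),
                  sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED4 gene annotation
#'
#' Input intervals follow the BED convention (0-based half-open); the
#' returned table is converted to 1-based inclusive coordinates and sorted
#' within each chromosome.
#'
#' @param path path to a tab-separated file with at least 4 columns:
#'   chrom, start, end, gene name.
#' @return a data.table with columns `chrom`, `start`, `end`, `gene`
#'   (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  raw <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(raw) < 4L) abort_arg("gene BED needs >= 4 tab-separated columns")
  dt <- raw[, 1:4]
  setnames(dt, c("chrom", "start", "end", "gene"))
  dt[, chrom := as.character(chrom)]
  dt[, gene := as.character(gene)]
  bad <- which(dt$start >= dt$end)
  if (length(bad)) {
    abort_arg("start >= end at line ", bad[1L], " of ", path)
  }
  dt[, start := as.integer(start) + 1L]  # BED -> 1-based inclusive
  dt[, end := as.integer(end)]
  setorder(dt, chrom, start, end)
  dt[]
}

#' Read a pedigree file
#'
#' Expects 4 tab-separated columns (individual, father, mother, sex) with
#' "0" meaning unknown parent, the format shared by PLINK-style pedigrees.
#' A header line starting with `#` or with the literal column names is
#' skipped.
#'
#' @param path path to the pedigree file.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(dt) < 4L) abort_arg("pedigree file needs 4 columns (id, father, mother, sex)")
  setnames(dt, 1:4, c("id", "father", "mother", "sex"))
  if (dt$id[1L] %in% c("id", "#id", "ID")) dt <- dt[-1L]
  pedigree(id = dt$id,
           father = ifelse(dt$father == "0", NA_character_, dt$father),
           mother = ifelse(dt$mother == "0", NA_character_, dt$mother),
           sex = dt$sex)
}

#' Write a pedigree file
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @return invisibly, the path written.
#' @export
write_pedigree <- function(ped, path) {
  dt <- data.table(id = ped$id,
                   father = ifelse(is.na(ped$father), "0", ped$father),
                   mother = ifelse(is.na(ped$mother), "0", ped$mother),
                   sex = ped$sex)
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a known-variant list
#'
#' Accepts either a VCF (positions and alleles taken from the fixed
#' columns) or a 4-column tab-separated file (chrom, pos, ref, alt).
#'
#' @param path path to the known-variant file.
#' @return a data.table with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path)) abort_arg("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- v@fix
    return(data.table(chrom = as.character(fix[, "CHROM"]),
                      pos = as.integer(fix[, "POS"]),
                      ref = as.character(fix[, "REF"]),
                      alt = as.character(fix[, "ALT"])))
  }
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) abort_arg("known-variant file needs 4 columns (chrom, pos, ref, alt)")
  dt <- dt[, 1:4]
  setnames(dt, c("chrom", "pos", "ref", "alt"))
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            ref = as.character(ref), alt = as.character(alt))]
  dt[]
}
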