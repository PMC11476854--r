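# Orchestration: the full post-calling analysis as one seeded, logged
# run, plus small clinical-summary helpers.

#' Known-variant list from a simulated marker map
#'
#' The simulated marker backdrop plays the role of the common-SNP
#' database: excluding it from the call set leaves only variants absent
#' from the population panel, exactly as a dbSNP filter would.
#'
#' @param map a [simulate_map()] result.
#' @return a data.table with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
known_from_map <- function(map) {
  map$markers[, .(chrom, pos, ref, alt)]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (VCF file or simulation) -> SNP-type
#' selection -> hard filters including the depth-percentile rule ->
#' known-variant exclusion -> proband-unique selection -> compartment
#' partition; in parallel, ROH detection on the hard-filtered SNP set
#' (before known-variant exclusion, which would strip the common SNPs the
#' scanner needs) -> per-sample summaries -> F_ROH and pedigree-expected
#' inbreeding -> ROH-gene overlap -> keyword triage.  Record counts
#' surviving each stage are logged and returned.
#'
#' @param vcf path to a merged multi-sample VCF, or NULL when simulating.
#' @param sim a [sim_config()], or NULL when reading a VCF; exactly one
#'   of `vcf`/`sim` must be given.
#' @param proband_id proband sample id (default: the simulation's).
#' @param known known-variant table or file path (optional; defaults to
#'   the simulated marker backdrop when simulating).
#' @param genes gene intervals (data.table or BED path, optional).
#' @param enrichment enrichment table (data.table or path, optional).
#' @param thresholds a [hard_filter_thresholds()].
#' @param roh a [roh_params()].
#' @param autosome_kb autosomal genome length in kb; defaults to the
#'   simulated autosome total when simulating, else 2,212,284.
#' @param ped a [pedigree()] or pedigree file path (optional; defaults to
#'   the simulation's pedigree) used for the expected-inbreeding
#'   cross-check.
#' @param keywords triage keywords.
#' @param naming a [compartment_config()].
#' @param out_dir directory for tab-separated intermediates (optional).
#' @param verbose log stage survivor counts via [message()].
#' @return a list of class `pipeline_report`: `unique_variants`,
#'   `partition`, `roh_segments`, `roh_summary`, `inbreeding`
#'   (per-sample F_ROH with baseline and expectations), `overlap`,
#'   `triage`, `stage_counts`.
#' @export
run_pipeline <- function(vcf = NULL, sim = NULL, proband_id = NULL,
                         known = NULL, genes = NULL, enrichment = NULL,
                         thresholds = hard_filter_thresholds(),
                         roh = roh_params(), autosome_kb = NULL,
                         ped = NULL, keywords = c("Development", "Sex",
                                                  "hermaphrodit"),
                         naming = compartment_config(), out_dir = NULL,
                         verbose = TRUE) {
  if (is.null(vcf) == is.null(sim)) {
    abort_arg("exactly one of 'vcf' and 'sim' must be supplied")
  }
  log_msg <- function(...) if (verbose) message("[autozyg] ", ...)
  counts <- c()

  if (!is.null(sim)) {
    log_msg("simulating study data (seed ", sim$seed, ")")
    study <- simulate_quartet(sim)
    tab <- study$table
    if (is.null(proband_id)) proband_id <- sim$proband_id
    if (is.null(known)) known <- known_from_map(study$map)
    if (is.null(ped)) ped <- sim$ped
    if (is.null(autosome_kb)) {
      a <- study$map$chromosomes
      autosome_kb <- sum(a$length_bp[a$compartment == "autosome"]) / 1000
    }
  } else {
    log_msg("reading ", vcf)
    tab <- read_merged_vcf(vcf)
    if (is.null(proband_id)) abort_arg("proband_id required with a VCF input")
    if (is.null(autosome_kb)) autosome_kb <- 2212284
  }
  if (is.character(known)) known <- read_known_variants(known)
  if (is.character(genes)) genes <- read_gene_bed(genes)
  if (is.character(enrichment)) enrichment <- read_enrichment_table(enrichment)
  if (is.character(ped)) ped <- read_pedigree(ped)
  samples <- vt_samples(tab)
  counts["input"] <- nrow(tab)
  log_msg(nrow(tab), " records, ", length(samples), " samples")

  snp <- select_snps(tab)
  counts["select_snps"] <- nrow(snp)
  log_msg(nrow(snp), " SNP-type records")

  filt <- filter_passing(snp, thresholds)
  counts["hard_filters"] <- nrow(filt)
  log_msg(nrow(filt), " records pass hard filters")

  nk <- if (is.null(known)) filt else exclude_known(filt, known)
  counts["exclude_known"] <- nrow(nk)
  log_msg(nrow(nk), " records after known-variant exclusion")

  uniq <- proband_unique(nk, proband_id)
  counts["proband_unique"] <- nrow(uniq)
  log_msg(nrow(uniq), " proband-unique variants")
  part <- partition_by_compartment(uniq, naming)

  segs <- detect_roh(filt, samples, roh, naming)
  summ <- summarize_roh_all(segs, samples, autosome_kb, naming)

  control_ids <- setdiff(samples, proband_id)
  baseline <- baseline_from_controls(summ[summ$sample_id %in% control_ids, ])
  expected_closed <- expected_sib_f(baseline)
  expected_ped <- NA_real_
  if (!is.null(ped) && proband_id %in% ped$id &&
      !is.na(ped$father[proband_id]) && !is.na(ped$mother[proband_id])) {
    ped_b <- pedigree(ped$id, ped$father, ped$mother, ped$sex,
                      founder_f = baseline)
    expected_ped <- expected_inbreeding(ped_b, proband_id)
  }
  inb <- data.table(
    sample_id = summ$sample_id,
    f_roh = summ$f_roh,
    baseline_f = baseline,
    f_expected = ifelse(summ$sample_id == proband_id, expected_closed,
                        NA_real_),
    f_expected_pedigree = ifelse(summ$sample_id == proband_id, expected_ped,
                                 NA_real_))

  overlap <- NULL
  if (!is.null(genes)) {
    overlap <- overlap_genes(segs[segs$sample_id == proband_id, ], genes)
    log_msg(length(overlap$genes), " genes in proband ROH segments")
  }
  triage <- NULL
  if (!is.null(enrichment)) {
    triage <- keyword_triage(enrichment, keywords)
    log_msg(nrow(triage$rows), " enrichment terms match keywords")
  }

  report <- structure(
    list(unique_variants = uniq, partition = part, roh_segments = segs,
         roh_summary = summ, inbreeding = inb, overlap = overlap,
         triage = triage, stage_counts = counts, proband_id = proband_id,
         autosome_kb = autosome_kb),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(uniq, file.path(out_dir, "unique_variants.vcf"))
    fwrite(segs, file.path(out_dir, "roh_segments.tsv"), sep = "\t")
    fwrite(summ, file.path(out_dir, "roh_summary.tsv"), sep = "\t")
    fwrite(inb, file.path(out_dir, "inbreeding.tsv"), sep = "\t")
    fwrite(data.table(compartment = names(part), n = as.integer(part)),
           file.path(out_dir, "partition.tsv"), sep = "\t")
    if (!is.null(overlap)) {
      fwrite(overlap$per_segment, file.path(out_dir, "overlap_genes.tsv"),
             sep = "\t")
    }
    if (!is.null(triage)) {
      tr <- copy(triage$rows)
      tr[, genes := vapply(genes, paste, character(1), collapse = ",")]
      fwrite(tr, file.path(out_dir, "triage.tsv"), sep = "\t")
    }
    fwrite(data.table(stage = names(counts), records = as.integer(counts)),
           file.path(out_dir, "stage_counts.tsv"), sep = "\t")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("autozyg pipeline report\n")
  cat("  proband:", x$proband_id, "\n")
  cat("  stage survivors:",
      paste(names(x$stage_counts), x$stage_counts, sep = "=",
            collapse = ", "), "\n")
  cat("  unique variants:", nrow(x$unique_variants),
      sprintf("(autosome %d, X %d, MT %d)\n", x$partition["autosome"],
              x$partition["X"], x$partition["MT"]))
  cat("  ROH summary:\n")
  print(x$roh_summary)
  cat("  inbreeding:\n")
  print(x$inbreeding)
  invisible(x)
}

#' Mosaicism fraction with exact confidence interval
#'
#' Proportion of abnormal karyotypes among scored metaphase spreads,
#' reported as a whole-number percentage with a 95% exact
#' (Clopper-Pearson) binomial confidence interval.
#'
#' @param n_abnormal abnormal spreads observed.
#' @param n_total spreads scored (> 0).
#' @param conf_level confidence level.
#' @return a list: `percent` (integer-rounded), `fraction`, `ci`
#'   (two-sided interval on the fraction scale).
#' @export
#' @examples
#' mosaic_fraction(18, 82)$percent # 22
mosaic_fraction <- function(n_abnormal, n_total, conf_level = 0.95) {
  if (n_total <= 0) abort_arg("n_total must be > 0")
  if (n_abnormal < 0 || n_abnormal > n_total) {
    abort_arg("n_abnormal must lie in [0, n_total]")
  }
  alpha <- 1 - conf_level
  lo <- if (n_abnormal == 0) 0 else
    qbeta(alpha / 2, n_abnormal, n_total - n_abnormal + 1)
  hi <- if (n_abnormal == n_total) 1 else
    qbeta(1 - alpha / 2, n_abnormal + 1, n_total - n_abnormal)
  frac <- n_abnormal / n_total
  list(percent = as.integer(round_half_up(100 * frac)),
       fraction = frac, ci = c(lower = lo, upper = hi))
}
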