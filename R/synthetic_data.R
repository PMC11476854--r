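# Seeded gene-dropping simulator: founder haplotype pools, Haldane
# crossovers, pedigree transmission, proband-only variant injection and
# quality-annotation draws.  Every random step is reproducible from an
# integer seed, and identity-by-descent truth (founder-haplotype origin
# labels) is carried alongside the alleles so that realized autozygosity
# can be measured exactly.

#' Simulation configuration
#'
#' Bundles the genome, pedigree and noise settings of one simulated study.
#' The default genome is desk-scale — 4 autosomes of 120 Mb at 1 marker
#' per 3 kb and ~1 cM/Mb — large enough for 100-SNP/1000-kb runs of
#' homozygosity to arise in inbred individuals while keeping end-to-end
#' runs fast.  A small X chromosome and a mitochondrial contig are
#' included as variant compartments for unique-variant injection.
#'
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp autosome length in bp.
#' @param n_markers_per_chrom markers per autosome.
#' @param cm_per_mb genetic map density (cM per Mb; Haldane model).
#' @param maf_low,maf_high bounds of the uniform founder allele-frequency
#'   distribution (strictly inside (0, 1)).
#' @param founder_pool_size number of distinct founder haplotypes per
#'   chromosome in the source population; founders draw with replacement
#'   from this pool, so small pools create baseline autozygosity
#'   (expected founder autozygosity is 1/pool_size).  `Inf` means every
#'   founder haplotype is drawn independently (fully outbred source).
#' @param ped the [pedigree()] to gene-drop (default: full-sib mating
#'   quartet with two unrelated controls, see [quartet_pedigree()]).
#' @param samples individuals emitted as VCF samples (default: proband,
#'   father and the two controls).
#' @param proband_id sample receiving injected unique variants.
#' @param de_novo_count number of proband-only variants to inject.
#' @param de_novo_split named integer vector distributing the injected
#'   variants over compartments (autosome, X, MT); must sum to
#'   `de_novo_count`.
#' @param de_novo_cluster list(n, span_bp, compartment): place `n` of the
#'   injected variants within one span on one compartment.
#' @param annotation_fail_fraction fraction of records given exactly one
#'   violated hard-filter annotation.
#' @param missing_rate per-genotype missingness rate.
#' @param include_x,include_mt include the X / MT compartments.
#' @param x_length_bp,n_markers_x,mt_length_bp,n_markers_mt sizes of the
#'   extra compartments.
#' @param seed integer seed for the whole simulation.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4L, chrom_length_bp = 120e6,
                       n_markers_per_chrom = 40000L, cm_per_mb = 1,
                       maf_low = 0.1, maf_high = 0.5,
                       founder_pool_size = Inf,
                       ped = quartet_pedigree(),
                       samples = c("PROBAND", "FATHER", "CTRL1", "CTRL2"),
                       proband_id = "PROBAND",
                       de_novo_count = 43L,
                       de_novo_split = c(autosome = 20L, X = 9L, MT = 14L),
                       de_novo_cluster = list(n = 8L, span_bp = 800L,
                                              compartment = "X"),
                       annotation_fail_fraction = 0.05,
                       missing_rate = 0.01,
                       include_x = TRUE, x_length_bp = 120e6,
                       n_markers_x = 2000L,
                       include_mt = TRUE, mt_length_bp = 16000L,
                       n_markers_mt = 100L,
                       seed = 1L) {
  if (maf_low <= 0 || maf_high >= 1 || maf_low > maf_high) {
    abort_arg("need 0 < maf_low <= maf_high < 1")
  }
  if (founder_pool_size < 2) abort_arg("founder_pool_size must be >= 2")
  if (missing_rate < 0 || missing_rate > 1) abort_arg("missing_rate in [0,1]")
  if (annotation_fail_fraction < 0 || annotation_fail_fraction > 1) {
    abort_arg("annotation_fail_fraction in [0,1]")
  }
  if (sum(de_novo_split) != de_novo_count) {
    abort_arg("de_novo_split must sum to de_novo_count")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Full-sib quartet pedigree with unrelated controls
#'
#' The study pedigree: a proband whose parents are full siblings
#' (grandparents GP1 x GP2), the father among the sequenced samples, and
#' two unrelated founder controls.
#'
#' @param baseline_f founder inbreeding for all founders.
#' @return a [pedigree()].
#' @export
quartet_pedigree <- function(baseline_f = 0) {
  pedigree(id = c("GP1", "GP2", "FATHER", "MOTHER", "PROBAND",
                  "CTRL1", "CTRL2"),
           father = c(NA, NA, "GP1", "GP1", "FATHER", NA, NA),
           mother = c(NA, NA, "GP2", "GP2", "MOTHER", NA, NA),
           sex = c("1", "2", "1", "2", "2", "1", "1"),
           founder_f = baseline_f)
}

#' Simulate a marker map
#'
#' Draws strictly increasing marker positions per chromosome, random
#' ref/alt nucleotides and founder-pool allele frequencies uniform in
#' `[maf_low, maf_high]`.  Deterministic for a given config seed.
#'
#' @param config a [sim_config()].
#' @return a list of class `marker_map` with elements `chromosomes`
#'   (chrom, length_bp, cm_per_mb, compartment) and `markers`
#'   (chrom, pos, ref, alt, freq).
#' @export
simulate_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- data.table(
    chrom = paste0("chr", seq_len(config$n_chromosomes)),
    length_bp = config$chrom_length_bp,
    cm_per_mb = config$cm_per_mb,
    compartment = "autosome")
  if (config$include_x) {
    chroms <- rbind(chroms, data.table(chrom = "chrX",
                                       length_bp = config$x_length_bp,
                                       cm_per_mb = config$cm_per_mb,
                                       compartment = "X"))
  }
  if (config$include_mt) {
    chroms <- rbind(chroms, data.table(chrom = "chrM",
                                       length_bp = config$mt_length_bp,
                                       cm_per_mb = 0,
                                       compartment = "MT"))
  }
  nt <- c("A", "C", "G", "T")
  mk <- lapply(seq_len(nrow(chroms)), function(i) {
    nm <- switch(chroms$compartment[i],
                 autosome = config$n_markers_per_chrom,
                 X = config$n_markers_x,
                 MT = config$n_markers_mt)
    pos <- sort(sample.int(chroms$length_bp[i], nm))
    ref <- sample(nt, nm, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
    data.table(chrom = chroms$chrom[i], pos = pos, ref = ref,
               alt = unname(alt),
               freq = runif(nm, config$maf_low, config$maf_high))
  })
  structure(list(chromosomes = chroms, markers = rbindlist(mk)),
            class = "marker_map")
}

# indices of diploid (autosome + X) and MT markers within map$markers
map_dip_idx <- function(map) {
  comp <- map$chromosomes$compartment[match(map$markers$chrom,
                                            map$chromosomes$chrom)]
  which(comp != "MT")
}
map_mt_idx <- function(map) {
  comp <- map$chromosomes$compartment[match(map$markers$chrom,
                                            map$chromosomes$chrom)]
  which(comp == "MT")
}

#' Simulate founder haplotypes
#'
#' Each chromosome has a pool of `pool_size` distinct haplotypes drawn
#' from the marker allele frequencies; every founder receives two
#' independent draws (with replacement) from the pool, so founders become
#' autozygous wherever both draws hit the same pool haplotype.  With
#' `pool_size = Inf` every haplotype is drawn fresh and founders are
#' fully outbred.  Mitochondrial haplotypes are always drawn fresh per
#' founder (single maternal lineage, no pool).
#'
#' @param map a [simulate_map()] result.
#' @param founder_ids identifiers of the founders.
#' @param pool_size founder haplotype pool size per chromosome (>= 2 or
#'   Inf).
#' @param seed integer seed.
#' @return named list per founder: `h`/`o` 2-row allele and origin-label
#'   matrices over diploid markers, `mt`/`mt_o` mitochondrial alleles and
#'   label.
#' @export
simulate_founders <- function(map, founder_ids, pool_size = Inf, seed = 1L) {
  if (pool_size < 2) abort_arg("pool_size must be >= 2")
  set.seed(seed)
  dip <- map_dip_idx(map)
  mti <- map_mt_idx(map)
  mk <- map$markers
  dip_chroms <- unique(mk$chrom[dip])
  nf <- length(founder_ids)

  out <- vector("list", nf)
  names(out) <- founder_ids
  for (f in founder_ids) {
    out[[f]] <- list(h = matrix(0L, 2L, length(dip)),
                     o = matrix(0L, 2L, length(dip)),
                     mt = integer(length(mti)), mt_o = 0L)
  }

  label_counter <- 0L
  for (ci in seq_along(dip_chroms)) {
    cc <- dip_chroms[ci]
    cols <- which(mk$chrom[dip] == cc)
    freq <- mk$freq[dip][cols]
    m <- length(cols)
    if (is.finite(pool_size)) {
      pool <- matrix(rbinom(pool_size * m, 1L, rep(freq, each = pool_size)),
                     nrow = pool_size)
      labels <- label_counter + seq_len(pool_size)
      label_counter <- label_counter + pool_size
      for (f in founder_ids) {
        for (copy in 1:2) {
          k <- sample.int(pool_size, 1L)
          out[[f]]$h[copy, cols] <- pool[k, ]
          out[[f]]$o[copy, cols] <- labels[k]
        }
      }
    } else {
      for (f in founder_ids) {
        for (copy in 1:2) {
          label_counter <- label_counter + 1L
          out[[f]]$h[copy, cols] <- rbinom(m, 1L, freq)
          out[[f]]$o[copy, cols] <- label_counter
        }
      }
    }
  }
  if (length(mti)) {
    freq <- mk$freq[mti]
    for (f in founder_ids) {
      label_counter <- label_counter + 1L
      out[[f]]$mt <- rbinom(length(mti), 1L, freq)
      out[[f]]$mt_o <- label_counter
    }
  }
  out
}

# one meiosis: recombine the parent's two haplotypes (Haldane: Poisson
# crossover count, uniform positions, no interference)
make_gamete <- function(parent, map, dip) {
  mk <- map$markers
  al <- integer(length(dip))
  or <- integer(length(dip))
  for (i in seq_len(nrow(map$chromosomes))) {
    cc <- map$chromosomes$chrom[i]
    if (map$chromosomes$compartment[i] == "MT") next
    cols <- which(mk$chrom[dip] == cc)
    if (!length(cols)) next
    L <- map$chromosomes$length_bp[i]
    morgans <- L / 1e6 * map$chromosomes$cm_per_mb[i] / 100
    ncx <- rpois(1L, morgans)
    cx <- sort(runif(ncx, 0, L))
    phase <- (sample(0:1, 1L) +
                findInterval(mk$pos[dip][cols], cx)) %% 2L
    al[cols] <- ifelse(phase == 0L, parent$h[1L, cols], parent$h[2L, cols])
    or[cols] <- ifelse(phase == 0L, parent$o[1L, cols], parent$o[2L, cols])
  }
  list(al = al, or = or)
}

#' Gene-drop a pedigree
#'
#' Transmits founder haplotypes through the pedigree in topological
#' order: each meiosis draws a Poisson number of crossovers (Haldane, no
#' interference), recombines the parent's two haplotypes and transmits
#' one gamete.  Row 1 of each individual's matrices is the paternal
#' gamete, row 2 the maternal one.  Mitochondria pass intact down the
#' maternal line.
#'
#' @param ped a [pedigree()]; every non-founder must have both parents.
#' @param founders output of [simulate_founders()] covering all founders
#'   of `ped`.
#' @param map the [simulate_map()] result the founders were drawn on.
#' @param seed integer seed.
#' @return named list over all pedigree members with elements `h`, `o`,
#'   `mt`, `mt_o` as in [simulate_founders()].
#' @export
gene_drop <- function(ped, founders, map, seed = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  set.seed(seed)
  dip <- map_dip_idx(map)
  genos <- founders
  for (id in ped$order) {
    if (!is.null(genos[[id]])) next
    fa <- ped$father[id]
    mo <- ped$mother[id]
    if (is.na(fa) || is.na(mo)) {
      abort_arg("non-founder '", id, "' lacks a parent and no haplotypes ",
                "were supplied for it")
    }
    g_pat <- make_gamete(genos[[fa]], map, dip)
    g_mat <- make_gamete(genos[[mo]], map, dip)
    genos[[id]] <- list(h = rbind(g_pat$al, g_mat$al),
                        o = rbind(g_pat$or, g_mat$or),
                        mt = genos[[mo]]$mt, mt_o = genos[[mo]]$mt_o)
  }
  genos
}

#' Realized autozygosity of one simulated individual
#'
#' Uses the identity-by-descent truth carried by the simulator: a marker
#' is autozygous when both haplotype origin labels coincide.  Only
#' autosomal markers enter the fraction, mirroring the autosomal
#' definition of F_ROH.
#'
#' @param geno one element of a [gene_drop()] result.
#' @param map the marker map.
#' @return a list with `fraction` (marker-weighted autozygous fraction)
#'   and `segments` (data.table chrom/start_bp/end_bp of maximal
#'   autozygous marker runs).
#' @export
true_autozygosity <- function(geno, map) {
  dip <- map_dip_idx(map)
  mk <- map$markers
  comp <- map$chromosomes$compartment[match(mk$chrom[dip],
                                            map$chromosomes$chrom)]
  auto <- comp == "autosome"
  ibd <- geno$o[1L, ] == geno$o[2L, ]
  segs <- list()
  for (cc in unique(mk$chrom[dip][auto])) {
    cols <- which(mk$chrom[dip] == cc)
    r <- rle(ibd[cols])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      segs[[length(segs) + 1L]] <- data.table(
        chrom = cc,
        start_bp = mk$pos[dip][cols][starts[k]],
        end_bp = mk$pos[dip][cols][ends[k]])
    }
  }
  list(fraction = mean(ibd[auto]),
       segments = if (length(segs)) rbindlist(segs) else
         data.table(chrom = character(0), start_bp = integer(0),
                    end_bp = integer(0)))
}

#' Convert simulated genotypes to a variant table
#'
#' @param genos a [gene_drop()] result.
#' @param map the marker map.
#' @param samples individuals to emit, in column order.
#' @param missing_rate per-genotype probability of a missing call.
#' @param seed integer seed for the missingness draws.
#' @return a [variant_table()] (diploid GT on autosomes and X, haploid on
#'   MT).
#' @export
sim_variant_table <- function(genos, map, samples, missing_rate = 0,
                              seed = 1L) {
  set.seed(seed)
  dip <- map_dip_idx(map)
  mti <- map_mt_idx(map)
  mk <- map$markers
  n_dip <- length(dip)
  n_mt <- length(mti)
  dt <- data.table(chrom = c(mk$chrom[dip], mk$chrom[mti]),
                   pos = c(mk$pos[dip], mk$pos[mti]),
                   ref = c(mk$ref[dip], mk$ref[mti]),
                   alt = c(mk$alt[dip], mk$alt[mti]))
  for (s in samples) {
    g <- genos[[s]]
    if (is.null(g)) abort_arg("no genotypes for sample '", s, "'")
    gt <- c(paste0(g$h[1L, ], "/", g$h[2L, ]),
            if (n_mt) as.character(g$mt) else character(0))
    if (missing_rate > 0) {
      miss <- runif(length(gt)) < missing_rate
      gt[miss & seq_along(gt) <= n_dip] <- "./."
      gt[miss & seq_along(gt) > n_dip] <- "."
    }
    dt[, (s) := gt]
  }
  variant_table(dt, samples)
}

#' Inject proband-unique variants
#'
#' Adds records, at positions not occupied by existing markers, where the
#' proband is heterozygous (haploid-alternate on MT) and every other
#' sample is homozygous reference.  A cluster specification places a
#' subset of one compartment's variants within a single short span,
#' emulating tightly linked de novo clusters.
#'
#' @param table a [variant_table()].
#' @param proband_id the proband sample.
#' @param count number of variants to inject.
#' @param split named integer vector over compartments (autosome, X, MT)
#'   summing to `count`.
#' @param cluster list(n, span_bp, compartment) or NULL; the clustered
#'   variants count towards that compartment's share of `split`.
#' @param naming a [compartment_config()].
#' @param seed integer seed.
#' @return the augmented [variant_table()] with a logical `injected`
#'   column marking the new records.
#' @export
inject_unique_variants <- function(table, proband_id, count = 43L,
                                   split = c(autosome = 20L, X = 9L, MT = 14L),
                                   cluster = list(n = 8L, span_bp = 800L,
                                                  compartment = "X"),
                                   naming = compartment_config(),
                                   seed = 1L) {
  samples <- vt_samples(table)
  if (!proband_id %in% samples) abort_arg("unknown proband: ", proband_id)
  if (sum(split) != count) abort_arg("split must sum to count")
  if (count == 0L) return(table)
  set.seed(seed)
  comp <- compartment_of(table$chrom, naming)
  controls <- setdiff(samples, proband_id)
  nt <- c("A", "C", "G", "T")

  pick_positions <- function(compartment, n_new, span = NULL) {
    chroms <- unique(table$chrom[comp == compartment])
    if (!length(chroms)) {
      abort_arg("no '", compartment, "' chromosome in the table to inject into")
    }
    cc <- if (length(chroms) == 1L) chroms else sample(chroms, n_new,
                                                       replace = TRUE)
    if (!is.null(span)) {
      if (span < n_new) abort_arg("cluster span too small for ", n_new,
                                  " distinct positions")
      cc <- rep(sample(chroms, 1L), n_new)
      used <- table$pos[table$chrom == cc[1L]]
      repeat {
        anchor <- sample.int(max(used, span + 1L) , 1L)
        cand <- anchor + sample.int(span, n_new)
        if (!any(cand %in% used)) break
      }
      return(data.table(chrom = cc, pos = cand))
    }
    cc <- rep_len(cc, n_new)
    pos <- integer(n_new)
    for (i in seq_len(n_new)) {
      used <- table$pos[table$chrom == cc[i]]
      hi <- max(used, 1000L)
      repeat {
        p <- sample.int(hi, 1L)
        if (!p %in% used && !p %in% pos[seq_len(i - 1L)][cc[seq_len(i - 1L)] == cc[i]]) break
      }
      pos[i] <- p
    }
    data.table(chrom = cc, pos = pos)
  }

  rows <- list()
  for (compartment in names(split)) {
    n_comp <- split[[compartment]]
    if (n_comp == 0L) next
    n_clustered <- 0L
    if (!is.null(cluster) && identical(cluster$compartment, compartment)) {
      n_clustered <- min(cluster$n, n_comp)
      rows[[length(rows) + 1L]] <- cbind(
        pick_positions(compartment, n_clustered, span = cluster$span_bp),
        compartment = compartment)
    }
    if (n_comp - n_clustered > 0L) {
      rows[[length(rows) + 1L]] <- cbind(
        pick_positions(compartment, n_comp - n_clustered),
        compartment = compartment)
    }
  }
  new <- rbindlist(rows)
  new[, ref := sample(nt, .N, replace = TRUE)]
  new[, alt := vapply(ref, function(r) sample(setdiff(nt, r), 1L),
                      character(1))]
  haploid <- new$compartment == "MT"
  for (s in samples) {
    if (s == proband_id) {
      new[, (s) := ifelse(haploid, "1", "0/1")]
    } else {
      new[, (s) := ifelse(haploid, "0", "0/0")]
    }
  }
  new[, compartment := NULL]
  new[, injected := TRUE]
  old <- copy(table)
  if (!"injected" %in% names(old)) old[, injected := FALSE]
  variant_table(rbind(old, new, fill = TRUE), samples)
}

#' Attach quality annotations with known truth
#'
#' Draws the seven calling annotations for every record.  Passing records
#' receive values comfortably inside the hard-filter-permitted region;
#' a `fail_fraction` of records (chosen at random) instead violate
#' exactly one of the six named thresholds, the offender drawn uniformly.
#' The violated filter name is recorded in the `qc_fail` column (NA for
#' clean records), giving an exact truth label per record.
#'
#' @param table a [variant_table()].
#' @param fail_fraction fraction of records given one violated threshold.
#' @param thresholds the [hard_filter_thresholds()] defining the
#'   pass/fail regions.
#' @param seed integer seed.
#' @return the table with annotation columns and `qc_fail` filled in.
#' @export
attach_quality_annotations <- function(table, fail_fraction = 0,
                                       thresholds = hard_filter_thresholds(),
                                       seed = 1L) {
  set.seed(seed)
  n <- nrow(table)
  out <- copy(table)
  # passing region, away from every boundary
  out[, DP := as.numeric(10L + rpois(n, 40))]
  out[, QD := runif(n, thresholds$qd_min + 5, 35)]
  out[, FS := runif(n, 0, thresholds$fs_max / 6)]
  out[, MQ := runif(n, thresholds$mq_min + 2, 60)]
  out[, SOR := runif(n, 0.3, thresholds$sor_max - 0.5)]
  out[, MQRankSum := runif(n, thresholds$mqranksum_min + 10, 3)]
  out[, ReadPosRankSum := runif(n, thresholds$readposranksum_min + 6, 3)]
  out[, qc_fail := NA_character_]

  n_fail <- round(fail_fraction * n)
  if (n_fail > 0L) {
    victims <- sample.int(n, n_fail)
    which_filter <- sample(FILTER_NAMES[1:6], n_fail, replace = TRUE)
    viol <- function(idx, col, lo, hi) {
      if (length(idx)) set(out, i = idx, j = col, value = runif(length(idx), lo, hi))
    }
    viol(victims[which_filter == "QD"], "QD", 0, thresholds$qd_min - 0.1)
    viol(victims[which_filter == "FS"], "FS", thresholds$fs_max + 1,
         thresholds$fs_max + 40)
    viol(victims[which_filter == "MQ"], "MQ", 30, thresholds$mq_min - 0.1)
    viol(victims[which_filter == "SOR"], "SOR", thresholds$sor_max + 0.1,
         thresholds$sor_max + 3)
    viol(victims[which_filter == "MQRankSum"], "MQRankSum",
         thresholds$mqranksum_min - 8, thresholds$mqranksum_min - 0.1)
    viol(victims[which_filter == "ReadPosRankSum"], "ReadPosRankSum",
         thresholds$readposranksum_min - 7,
         thresholds$readposranksum_min - 0.1)
    set(out, i = victims, j = "qc_fail", value = which_filter)
  }
  vt_rewrap(out, vt_samples(table))
}

#' Simulate a complete quartet study
#'
#' Runs the whole generator: marker map, founder haplotypes, gene drop
#' through the full-sib pedigree, VCF-style genotype table for the four
#' sequenced samples, proband-unique variant injection and quality
#' annotations.  Truth (injected variants, realized autozygosity) is
#' returned alongside the data.
#'
#' @param config a [sim_config()].
#' @return a list with `table` (a [variant_table()]), `ped`, `map`,
#'   `genotypes`, and `truth` (list: `injected` data.table,
#'   `autozygosity` named list of [true_autozygosity()] results per
#'   sample).
#' @export
simulate_quartet <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  map <- simulate_map(config)
  founders <- simulate_founders(map, ped_founders(config$ped),
                                config$founder_pool_size, seed = seed + 1L)
  genos <- gene_drop(config$ped, founders, map, seed = seed + 2L)
  tab <- sim_variant_table(genos, map, config$samples,
                           missing_rate = config$missing_rate,
                           seed = seed + 3L)
  tab <- inject_unique_variants(tab, config$proband_id,
                                count = config$de_novo_count,
                                split = config$de_novo_split,
                                cluster = config$de_novo_cluster,
                                seed = seed + 4L)
  tab <- attach_quality_annotations(tab, config$annotation_fail_fraction,
                                    seed = seed + 5L)
  injected <- tab[tab$injected == TRUE,
                  c("chrom", "pos", "ref", "alt"), with = FALSE]
  autoz <- lapply(setNames(config$samples, config$samples),
                  function(s) true_autozygosity(genos[[s]], map))
  list(table = tab, ped = config$ped, map = map, genotypes = genos,
       truth = list(injected = injected, autozygosity = autoz))
}
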