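test_that("marker maps are sorted, sized and seed-deterministic", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 5e6,
                    n_markers_per_chrom = 1000L, include_x = FALSE,
                    include_mt = FALSE, de_novo_count = 0L,
                    de_novo_split = c(autosome = 0L, X = 0L, MT = 0L),
                    de_novo_cluster = NULL, seed = 3L)
  map <- simulate_map(cfg)
  expect_equal(nrow(map$markers), 2000L)
  by_chrom <- split(map$markers$pos, map$markers$chrom)
  expect_true(all(vapply(by_chrom, function(p) all(diff(p) > 0), logical(1))))
  expect_identical(simulate_map(cfg), map)
  # pinched maf bounds give constant frequencies
  cfg2 <- sim_config(maf_low = 0.4, maf_high = 0.4, n_chromosomes = 1L,
                     n_markers_per_chrom = 100L, include_x = FALSE,
                     include_mt = FALSE, de_novo_count = 0L,
                     de_novo_split = c(autosome = 0L, X = 0L, MT = 0L),
                     de_novo_cluster = NULL)
  expect_true(all(simulate_map(cfg2)$markers$freq == 0.4))
})

test_that("outbred founders reach Hardy-Weinberg homozygosity", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length_bp = 5e7,
                    n_markers_per_chrom = 10000L, include_x = FALSE,
                    include_mt = FALSE, seed = 5L)
  map <- simulate_map(cfg)
  f <- simulate_founders(map, c("A", "B"), pool_size = Inf, seed = 6L)
  p <- map$markers$freq
  hom_expected <- mean(p^2 + (1 - p)^2)
  hom_obs <- mean(f$A$h[1, ] == f$A$h[2, ])
  se <- sqrt(hom_expected * (1 - hom_expected) / length(p))
  expect_lt(abs(hom_obs - hom_expected), 3 * se)
  expect_identical(simulate_founders(map, c("A", "B"), Inf, seed = 6L), f)
})

test_that("a pool of two haplotypes allows at most three diplotypes", {
  cfg <- sim_config(n_chromosomes = 1L, chrom_length_bp = 1e6,
                    n_markers_per_chrom = 200L, include_x = FALSE,
                    include_mt = FALSE, seed = 7L)
  map <- simulate_map(cfg)
  f <- simulate_founders(map, paste0("F", 1:12), pool_size = 2, seed = 8L)
  diplos <- vapply(f, function(g) {
    paste(paste(sort(c(g$o[1, 1], g$o[2, 1])), collapse = "-"))
  }, character(1))
  expect_lte(length(unique(diplos)), 3L)
})

test_that("smaller founder pools mean more realized founder autozygosity", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 1e7,
                    n_markers_per_chrom = 2000L, include_x = FALSE,
                    include_mt = FALSE, seed = 9L)
  map <- simulate_map(cfg)
  frac <- vapply(c(2, 4, 16, 256), function(ps) {
    f <- simulate_founders(map, paste0("F", 1:30), pool_size = ps,
                           seed = 10L + ps)
    mean(vapply(f, function(g) true_autozygosity(g, map)$fraction, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(frac) < 0))  # decreasing with pool size
  # and close to the 1/pool_size expectation
  expect_equal(frac, 1 / c(2, 4, 16, 256), tolerance = 0.35)
})

test_that("gene dropping is Mendelian-consistent at every marker", {
  cfg <- tiny_sim_config(seed = 21)
  map <- simulate_map(cfg)
  founders <- simulate_founders(map, ped_founders(cfg$ped), Inf, seed = 22L)
  genos <- gene_drop(cfg$ped, founders, map, seed = 23L)
  for (id in setdiff(cfg$ped$id, ped_founders(cfg$ped))) {
    fa <- genos[[cfg$ped$father[id]]]
    mo <- genos[[cfg$ped$mother[id]]]
    me <- genos[[id]]
    expect_true(all(me$h[1, ] == fa$h[1, ] | me$h[1, ] == fa$h[2, ]), info = id)
    expect_true(all(me$h[2, ] == mo$h[1, ] | me$h[2, ] == mo$h[2, ]), info = id)
    expect_equal(me$mt, mo$mt, info = id)  # maternal mitochondria
  }
})

test_that("a zero-recombination map transmits intact parental haplotypes", {
  cfg <- sim_config(n_chromosomes = 2L, chrom_length_bp = 1e7,
                    n_markers_per_chrom = 500L, cm_per_mb = 0,
                    include_x = FALSE, include_mt = FALSE, seed = 31L)
  map <- simulate_map(cfg)
  founders <- simulate_founders(map, ped_founders(cfg$ped), Inf, seed = 32L)
  genos <- gene_drop(cfg$ped, founders, map, seed = 33L)
  for (id in c("FATHER", "MOTHER", "PROBAND")) {
    for (row in 1:2) {
      for (cc in unique(map$markers$chrom)) {
        cols <- which(map$markers$chrom == cc)
        expect_equal(length(unique(genos[[id]]$o[row, cols])), 1L,
                     info = paste(id, row, cc))
      }
    }
  }
})

test_that("injected variants mirror the requested compartment split", {
  sim <- simulate_quartet(tiny_sim_config(seed = 41))
  inj <- sim$table[sim$table$injected == TRUE, ]
  expect_equal(nrow(inj), 43L)
  expect_equal(partition_by_compartment(inj),
               c(autosome = 20L, X = 9L, MT = 14L))
  # the clustered subset sits within one short span on the X
  xpos <- sort(inj$pos[inj$chrom == "chrX"])
  windows <- vapply(seq_len(length(xpos) - 7L),
                    function(i) xpos[i + 7L] - xpos[i], numeric(1))
  expect_true(any(windows <= 800))
  # proband het or haploid-alt, controls reference
  expect_true(all(inj$PROBAND %in% c("0/1", "1")))
  expect_true(all(unlist(inj[, c("FATHER", "CTRL1", "CTRL2"),
                             with = FALSE]) %in% c("0/0", "0")))
})

test_that("injection count zero leaves the table unchanged", {
  cfg <- tiny_sim_config(seed = 43)
  map <- simulate_map(cfg)
  founders <- simulate_founders(map, ped_founders(cfg$ped), Inf, seed = 44L)
  genos <- gene_drop(cfg$ped, founders, map, seed = 45L)
  tab <- sim_variant_table(genos, map, cfg$samples, seed = 46L)
  out <- inject_unique_variants(tab, "PROBAND", count = 0L,
                                split = c(autosome = 0L, X = 0L, MT = 0L))
  expect_equal(nrow(out), nrow(tab))
})

test_that("a cluster span smaller than its variant count is rejected", {
  sim <- simulate_quartet(tiny_sim_config(seed = 47))
  expect_error(
    inject_unique_variants(sim$table, "PROBAND", count = 10L,
                           split = c(autosome = 0L, X = 10L, MT = 0L),
                           cluster = list(n = 10L, span_bp = 5L,
                                          compartment = "X")),
    "span too small")
})

test_that("the filter chain recovers exactly the injected variants", {
  cfg <- tiny_sim_config(seed = 51, annotation_fail_fraction = 0,
                         missing_rate = 0)
  sim <- simulate_quartet(cfg)
  chain <- proband_unique(
    exclude_known(
      filter_passing(select_snps(sim$table),
                     hard_filter_thresholds(dp_quantile = NA)),
      known_from_map(sim$map)),
    "PROBAND")
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  expect_setequal(key(chain), key(sim$truth$injected))
  expect_equal(nrow(chain), 43L)
})

test_that("annotation truth labels agree with filter verdicts", {
  cfg <- tiny_sim_config(seed = 61, annotation_fail_fraction = 0)
  sim <- simulate_quartet(cfg)
  th <- hard_filter_thresholds(dp_quantile = NA)
  v0 <- apply_hard_filters(sim$table, th)
  expect_true(all(v0$passed))

  tab <- attach_quality_annotations(sim$table, fail_fraction = 0.3,
                                    seed = 62L)
  v <- apply_hard_filters(tab, th)
  expect_equal(!v$passed, !is.na(tab$qc_fail))
  failed <- which(!v$passed)
  expect_true(all(vapply(failed, function(i)
    identical(v$reasons[[i]], tab$qc_fail[i]), logical(1))))
})

test_that("induced failures spread evenly over the six named filters", {
  n <- 6000L
  tab <- toy_table(chrom = rep("chr1", n), pos = seq_len(n) * 50L,
                   ref = rep("A", n), alt = rep("G", n), S1 = rep("0/1", n))
  tab <- attach_quality_annotations(tab, fail_fraction = 1, seed = 63L)
  counts <- table(tab$qc_fail)
  expect_equal(length(counts), 6L)
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("the whole simulation is reproducible from its seed", {
  a <- simulate_quartet(tiny_sim_config(seed = 71))
  b <- simulate_quartet(tiny_sim_config(seed = 71))
  expect_identical(data.table::as.data.table(a$table),
                   data.table::as.data.table(b$table))
  expect_identical(a$truth$injected, b$truth$injected)
})
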