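test_that("depth percentile uses the nearest-rank definition", {
  # independent check: sorted value at position ceiling(q * n)
  set.seed(5)
  for (i in 1:20) {
    vals <- sample.int(500, sample(3:200, 1), replace = TRUE)
    q <- stats::runif(1, 0.05, 0.95)
    expect_equal(dp_quantile_threshold(vals, q),
                 sort(vals)[ceiling(q * length(vals))])
  }
  expect_equal(dp_quantile_threshold(1:100, 0.75), 75)
  expect_equal(dp_quantile_threshold(rep(30, 17), 0.5), 30)
  expect_equal(dp_quantile_threshold(7, 0.75), 7)
  expect_error(dp_quantile_threshold(numeric(0), 0.75), "non-empty")
  expect_error(dp_quantile_threshold(1:10, 1), "strictly between")
  expect_equal(dp_quantile_threshold(1:100, 0.75, method = "linear"),
               unname(stats::quantile(1:100, 0.75)))
})

test_that("hard filters fail on strict inequalities and pass boundaries", {
  tab <- toy_table(
    chrom = c("chr1", "chr1", "chr1"), pos = c(100L, 200L, 300L),
    ref = c("A", "A", "A"), alt = c("G", "G", "G"),
    S1 = c("0/1", "0/1", "0/1"),
    ann = list(QD = c(1.5, 2.0, 25), FS = c(1, 60.0, 1),
               MQ = c(59, 56.0, 59), SOR = c(1, 3.0, 1),
               MQRankSum = c(0, -12.5, 0), ReadPosRankSum = c(0, -8.0, 0),
               DP = c(40, 40, 40)))
  v <- apply_hard_filters(tab, hard_filter_thresholds(dp_quantile = NA))
  expect_false(v$passed[1])
  expect_equal(v$reasons[[1]], "QD")
  expect_true(v$passed[2])  # every annotation exactly on its boundary
  expect_true(v$passed[3])
})

test_that("missing annotations never fail their filter", {
  tab <- toy_table("chr1", 100L, "A", "G", S1 = "0/1",
                   ann = list(QD = NA_real_, FS = NA_real_))
  v <- apply_hard_filters(tab, hard_filter_thresholds(dp_quantile = NA))
  expect_true(v$passed[1])
})

test_that("verdicts on randomized records match a brute-force re-evaluation", {
  set.seed(17)
  n <- 200L
  tab <- toy_table(
    chrom = rep("chr1", n), pos = seq_len(n) * 10L,
    ref = rep("A", n), alt = rep("G", n),
    S1 = rep("0/1", n),
    ann = list(
      QD = ifelse(runif(n) < 0.1, NA, runif(n, 0, 10)),
      FS = ifelse(runif(n) < 0.1, NA, runif(n, 0, 120)),
      MQ = ifelse(runif(n) < 0.1, NA, runif(n, 40, 62)),
      SOR = ifelse(runif(n) < 0.1, NA, runif(n, 0, 6)),
      MQRankSum = ifelse(runif(n) < 0.1, NA, runif(n, -20, 5)),
      ReadPosRankSum = ifelse(runif(n) < 0.1, NA, runif(n, -15, 5)),
      DP = ifelse(runif(n) < 0.1, NA, sample.int(80, n, replace = TRUE))))
  th <- hard_filter_thresholds()
  v <- apply_hard_filters(tab, th)
  dp_cut <- sort(tab$DP[!is.na(tab$DP)])[ceiling(0.75 * sum(!is.na(tab$DP)))]
  for (i in seq_len(n)) {
    expected <- character(0)
    chk <- function(x, bad, name) if (!is.na(x) && bad) c(expected, name) else expected
    expected <- chk(tab$QD[i], tab$QD[i] < 2.0, "QD")
    expected <- chk(tab$FS[i], tab$FS[i] > 60.0, "FS")
    expected <- chk(tab$MQ[i], tab$MQ[i] < 56.0, "MQ")
    expected <- chk(tab$SOR[i], tab$SOR[i] > 3.0, "SOR")
    expected <- chk(tab$MQRankSum[i], tab$MQRankSum[i] < -12.5, "MQRankSum")
    expected <- chk(tab$ReadPosRankSum[i], tab$ReadPosRankSum[i] < -8.0,
                    "ReadPosRankSum")
    expected <- chk(tab$DP[i], tab$DP[i] < dp_cut, "DP")
    expect_equal(v$reasons[[i]], expected, info = paste("record", i))
    expect_equal(v$passed[i], length(expected) == 0L)
  }
})

test_that("the depth cutoff is a function of the full table given to the filter", {
  set.seed(3)
  n <- 120L
  tab <- toy_table(chrom = rep("chr1", n), pos = seq_len(n) * 100L,
                   ref = rep("A", n), alt = rep("G", n),
                   S1 = sample(c("0/0", "0/1", "1/1"), n, replace = TRUE),
                   S2 = rep("0/0", n),
                   ann = list(DP = sample.int(100, n, replace = TRUE)))
  v_full <- apply_hard_filters(tab)
  # permuting row order does not change any verdict
  perm <- sample.int(n)
  tab_perm <- variant_table(data.table::as.data.table(tab)[perm], c("S1", "S2"))
  v_perm <- apply_hard_filters(tab_perm)
  expect_equal(v_perm[order(v_perm$pos)]$passed, v_full[order(v_full$pos)]$passed)
  # downstream selection sees a different (subset) cutoff: the DP rule must
  # therefore be applied before uniqueness selection, as the chain does
  keep <- filter_passing(tab)
  expect_true(dp_quantile_threshold(keep$DP, 0.75) >=
                dp_quantile_threshold(tab$DP, 0.75))
})

test_that("direction switch inverts the depth rule", {
  tab <- toy_table(chrom = rep("chr1", 100L), pos = seq_len(100L),
                   ref = rep("A", 100L), alt = rep("G", 100L),
                   S1 = rep("0/1", 100L), ann = list(DP = as.numeric(1:100)))
  below <- apply_hard_filters(tab, hard_filter_thresholds())
  above <- apply_hard_filters(tab, hard_filter_thresholds(dp_direction = "above"))
  expect_equal(sum(!below$passed), 74L)  # DP < 75 discarded
  expect_equal(sum(!above$passed), 25L)  # DP > 75 discarded
})

test_that("SNP selection is record-level", {
  tab <- toy_table(chrom = rep("chr1", 3), pos = c(1L, 2L, 3L),
                   ref = c("A", "AT", "A"), alt = c("G", "A", "G,AT"),
                   S1 = c("0/1", "0/1", "0/1"))
  out <- select_snps(tab)
  expect_equal(out$pos, 1L)  # deletion and mixed records both removed
})

test_that("known-variant exclusion equals a set-difference oracle", {
  empty_known <- data.table::data.table(chrom = character(0), pos = integer(0),
                                        ref = character(0), alt = character(0))
  tab1 <- toy_table("chr1", 500L, "A", "G", S1 = "0/1")
  expect_equal(nrow(exclude_known(tab1, empty_known)), 1L)
  expect_equal(nrow(exclude_known(
    tab1, data.table::data.table(chrom = "chr1", pos = 500L,
                                 ref = "A", alt = "G"))), 0L)

  set.seed(31)
  n <- 1000L
  tab <- toy_table(chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
                   pos = sample.int(1e5, n),
                   ref = sample(c("A", "C"), n, replace = TRUE),
                   alt = sample(c("G", "T"), n, replace = TRUE),
                   S1 = rep("0/1", n))
  known <- data.table::data.table(
    chrom = sample(paste0("chr", 1:3), 800, replace = TRUE),
    pos = sample.int(1e5, 800), ref = sample(c("A", "C"), 800, replace = TRUE),
    alt = sample(c("G", "T"), 800, replace = TRUE))
  out <- exclude_known(tab, known)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  survivors_oracle <- setdiff(key(tab), key(known))
  expect_setequal(key(out), intersect(key(tab), survivors_oracle))

  # anti-monotonicity: excluding a union removes at least as much
  extra <- data.table::data.table(chrom = "chr1", pos = tab$pos[1],
                                  ref = tab$ref[1], alt = tab$alt[1])
  both <- exclude_known(tab, rbind(known, extra))
  expect_true(all(key(both) %in% key(out)))
})

test_that("multi-allelic records are excluded only when every alt is known", {
  tab <- toy_table("chr1", 500L, "A", "G,T", S1 = "1/2")
  known_one <- data.table::data.table(chrom = "chr1", pos = 500L,
                                      ref = "A", alt = "G")
  known_both <- rbind(known_one,
                      data.table::data.table(chrom = "chr1", pos = 500L,
                                             ref = "A", alt = "T"))
  expect_equal(nrow(exclude_known(tab, known_one)), 1L)
  expect_equal(nrow(exclude_known(tab, known_both)), 0L)
  expect_equal(nrow(exclude_known(tab, known_one, match = "position")), 0L)
})

test_that("proband-unique selection follows the never-even-het rule", {
  tab <- toy_table(chrom = rep("chr1", 4), pos = 1:4 * 100L,
                   ref = rep("A", 4), alt = rep("G", 4),
                   PRO = c("0/1", "1/1", "0/1", "0/0"),
                   C1 = c("0/0", "0/1", "0/0", "0/0"),
                   C2 = c("0/0", "0/0", "./.", "0/0"),
                   C3 = c("0/0", "0/0", "0/0", "0/0"))
  out <- proband_unique(tab, "PRO")
  # kept: only record 1 (het proband, all controls hom-ref).
  # record 2: a control is het for the alt; record 3: a control has no
  # call; record 4: proband carries no alt.
  expect_equal(out$pos, 100L)
  expect_error(proband_unique(tab, "NOPE"), "not a sample")
})

test_that("haploid records obey the same uniqueness rule", {
  tab <- toy_table(chrom = rep("chrM", 3), pos = 1:3 * 10L,
                   ref = rep("A", 3), alt = rep("G", 3),
                   PRO = c("1", "1", "0"),
                   C1 = c("0", "1", "0"))
  out <- proband_unique(tab, "PRO")
  expect_equal(out$pos, 10L)
})

test_that("any retained record is lost if a control gains the proband allele", {
  sim <- simulate_quartet(tiny_sim_config(seed = 8))
  tab <- sim$table
  uniq <- proband_unique(tab, "PROBAND")
  expect_true(nrow(uniq) > 0)
  set.seed(2)
  for (i in sample(seq_len(nrow(uniq)), min(10L, nrow(uniq)))) {
    mutated <- data.table::copy(data.table::as.data.table(uniq))
    victim <- sample(c("FATHER", "CTRL1", "CTRL2"), 1)
    haploid <- !grepl("/", mutated[[victim]][i])
    data.table::set(mutated, i, victim, if (haploid) "1" else "0/1")
    out <- proband_unique(variant_table(mutated, vt_samples(tab)), "PROBAND")
    expect_equal(nrow(out), nrow(uniq) - 1L)
  }
})

test_that("compartment partition is exhaustive and mirrors construction", {
  tab <- toy_table(
    chrom = c(rep("chr5", 20), rep("chrX", 9), rep("chrM", 14)),
    pos = seq_len(43L) * 100L, ref = rep("A", 43), alt = rep("G", 43),
    S1 = rep("0/1", 43))
  part <- partition_by_compartment(tab)
  expect_equal(part, c(autosome = 20L, X = 9L, MT = 14L))
  expect_equal(sum(part), nrow(tab))

  empty <- toy_table(character(0), integer(0), character(0), character(0),
                     S1 = character(0))
  expect_equal(partition_by_compartment(empty), c(autosome = 0L, X = 0L, MT = 0L))

  allx <- toy_table(rep("chrX", 5), 1:5 * 10L, rep("A", 5), rep("G", 5),
                    S1 = rep("0/1", 5))
  expect_equal(partition_by_compartment(allx), c(autosome = 0L, X = 5L, MT = 0L))
})
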