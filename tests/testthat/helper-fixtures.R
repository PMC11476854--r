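# Programmatic fixtures shared across test files.

# small variant table built directly from genotype strings
toy_table <- function(chrom, pos, ref = "A", alt = "G", ..., ann = list()) {
  gt <- list(...)
  dt <- data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
  for (k in names(ann)) dt[, (k) := ann[[k]]]
  for (s in names(gt)) dt[, (s) := gt[[s]]]
  variant_table(dt, names(gt))
}

# genotype vector with a homozygous core flanked by missing pads and
# dense heterozygous blocks; returns list(pos, geno) for roh_scan
flanked_hom_block <- function(n_hom = 120, hom_spacing_bp = 12600,
                              n_het = 90, n_pad = 5, seed = 1) {
  set.seed(seed)
  geno <- c(rep(1L, n_het), rep(NA_integer_, n_pad),
            sample(c(0L, 2L), n_hom, replace = TRUE),
            rep(NA_integer_, n_pad), rep(1L, n_het))
  gaps <- c(rep(1000L, n_het + n_pad),
            rep(hom_spacing_bp, n_hom - 1L),
            rep(1000L, n_pad + n_het + 1L))
  pos <- cumsum(c(10000L, gaps))[seq_along(geno)]
  list(pos = pos, geno = geno)
}

# random genotype vector mixing unstructured noise with homozygous blocks
random_geno_vector <- function(n, seed) {
  set.seed(seed)
  if (seed %% 2 == 0) {
    geno <- sample(c(0L, 1L, 2L, NA_integer_), n, replace = TRUE,
                   prob = c(0.4, 0.25, 0.3, 0.05))
  } else {
    geno <- integer(0)
    while (length(geno) < n) {
      if (stats::runif(1) < 0.5) {
        len <- sample(30:250, 1L)
        block <- sample(c(0L, 2L, NA_integer_), len, replace = TRUE,
                        prob = c(0.5, 0.45, 0.05))
      } else {
        len <- sample(10:80, 1L)
        block <- sample(c(0L, 1L, 2L, NA_integer_), len, replace = TRUE,
                        prob = c(0.35, 0.3, 0.3, 0.05))
      }
      geno <- c(geno, block)
    }
    geno <- geno[seq_len(n)]
  }
  pos <- cumsum(sample(500:25000, n, replace = TRUE))
  list(pos = pos, geno = geno)
}

# tiny simulation config for fast end-to-end tests
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(n_chromosomes = 2L, chrom_length_bp = 2e7,
             n_markers_per_chrom = 3000L, n_markers_x = 300L,
             n_markers_mt = 50L, seed = seed, ...)
}
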