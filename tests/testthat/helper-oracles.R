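# Independent oracles: deliberately naive re-implementations used to pin
# down the semantics of the fast code paths.  They share no code with the
# package internals.

# ---- brute-force ROH scanner -------------------------------------------
# Materializes every window and every candidate run with plain loops.
oracle_roh <- function(pos, geno, p = roh_params()) {
  empty <- data.table::data.table(start_bp = integer(0), end_bp = integer(0),
                                  n_snps = integer(0), length_kb = numeric(0))
  n <- length(geno)
  w <- p$window_snps
  if (n < w) return(empty)
  n_win <- n - w + 1L
  win_ok <- logical(n_win)
  for (s in seq_len(n_win)) {
    win <- geno[s:(s + w - 1L)]
    win_ok[s] <- sum(win == 1L, na.rm = TRUE) <= p$window_het_max &&
      sum(is.na(win)) <= p$window_missing_max
  }
  pass <- logical(n)
  for (i in seq_len(n)) {
    covering <- intersect(seq_len(n_win), (i - w + 1L):i)
    pass[i] <- mean(win_ok[covering]) >= p$window_hit_fraction
  }
  is_hom <- function(i) !is.na(geno[i]) && geno[i] != 1L
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!pass[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && pass[j + 1L]) j <- j + 1L
    # split the run at large gaps
    bounds <- i
    if (j > i) {
      for (k in i:(j - 1L)) {
        if (pos[k + 1L] - pos[k] > p$max_gap_kb * 1000) {
          bounds <- c(bounds, k, k + 1L)
        }
      }
    }
    bounds <- c(bounds, j)
    for (b in seq(1L, length(bounds), by = 2L)) {
      a2 <- bounds[b]; b2 <- bounds[b + 1L]
      while (a2 <= b2 && !is_hom(a2)) a2 <- a2 + 1L
      while (b2 >= a2 && !is_hom(b2)) b2 <- b2 - 1L
      if (a2 > b2) next
      n_snp <- b2 - a2 + 1L
      len_kb <- (pos[b2] - pos[a2] + 1L) / 1000
      if (n_snp >= p$min_snps && len_kb > p$min_kb &&
          len_kb / n_snp <= p$min_density_kb_per_snp) {
        segs[[length(segs) + 1L]] <- data.table::data.table(
          start_bp = pos[a2], end_bp = pos[b2],
          n_snps = n_snp, length_kb = len_kb)
      }
    }
    i <- j + 1L
  }
  if (!length(segs)) empty else data.table::rbindlist(segs)
}

# ---- Wright path-counting kinship --------------------------------------
oracle_ancestors <- function(ped, x) {
  out <- x
  fa <- ped$father[x]; mo <- ped$mother[x]
  if (!is.na(fa)) out <- c(out, oracle_ancestors(ped, fa))
  if (!is.na(mo)) out <- c(out, oracle_ancestors(ped, mo))
  unique(out)
}

# all ancestral paths from x up to a, as vectors of ids (x first, a last)
oracle_paths_up <- function(ped, x, a) {
  if (x == a) return(list(x))
  out <- list()
  for (par in c(ped$father[x], ped$mother[x])) {
    if (is.na(par)) next
    for (pp in oracle_paths_up(ped, par, a)) {
      out[[length(out) + 1L]] <- c(x, pp)
    }
  }
  out
}

oracle_inbreeding <- function(ped, x) {
  fa <- ped$father[x]; mo <- ped$mother[x]
  if (is.na(fa) && is.na(mo)) return(unname(ped$founder_f[x]))
  if (is.na(fa) || is.na(mo)) return(0)
  oracle_kinship(ped, fa, mo)
}

# kinship by exhaustive enumeration of path pairs sharing only the
# common ancestor, each contributing (1/2)^(L1+L2+1) * (1 + F_A)
oracle_kinship <- function(ped, i, j) {
  if (i == j) return(0.5 * (1 + oracle_inbreeding(ped, i)))
  common <- intersect(oracle_ancestors(ped, i), oracle_ancestors(ped, j))
  total <- 0
  for (a in common) {
    fa_term <- 1 + oracle_inbreeding(ped, a)
    for (p1 in oracle_paths_up(ped, i, a)) {
      for (p2 in oracle_paths_up(ped, j, a)) {
        shared <- intersect(setdiff(p1, a), setdiff(p2, a))
        if (length(shared) == 0L) {
          total <- total + 0.5^(length(p1) - 1L + length(p2) - 1L + 1L) * fa_term
        }
      }
    }
  }
  total
}

# random multi-generation pedigree with occasional founder inbreeding
random_pedigree <- function(n_gen = 4, founders = 3, per_gen = 3, seed = 1) {
  set.seed(seed)
  id <- paste0("F", seq_len(founders))
  father <- rep(NA_character_, founders)
  mother <- rep(NA_character_, founders)
  for (g in seq_len(n_gen - 1)) {
    pool <- id
    for (k in seq_len(per_gen)) {
      pa <- sample(pool, 2L)
      nid <- paste0("G", g, "N", k)
      id <- c(id, nid)
      father <- c(father, pa[1])
      mother <- c(mother, pa[2])
    }
  }
  ff <- stats::runif(founders, 0, 0.3) * stats::rbinom(founders, 1, 0.5)
  pedigree(id, father, mother,
           founder_f = stats::setNames(ff, paste0("F", seq_len(founders))))
}

# ---- exact binomial interval via root finding on pbinom ----------------
oracle_clopper_pearson <- function(x, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) 1 - stats::pbinom(x - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) stats::pbinom(x, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lo, upper = hi)
}
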