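# Genomic and pedigree inbreeding: F_ROH, recursive kinship (the tabular
# method), and the closed-form full-sib-mating expectation with a
# population baseline.

#' Genomic inbreeding coefficient from ROH totals
#'
#' F_ROH is the proportion of the autosomal genome covered by runs of
#' homozygosity.
#'
#' @param total_roh_kb cumulative autosomal ROH length in kb.
#' @param autosome_kb autosomal genome length in kb (default 2,212,284,
#'   the canine autosomal assembly total; configurable per genome build).
#' @return F_ROH in `[0, 1]`.
#' @export
#' @examples
#' f_roh(681002)          # 0.3078...
#' f_roh(318511)          # 0.1439...
f_roh <- function(total_roh_kb, autosome_kb = 2212284) {
  if (autosome_kb <= 0) abort_arg("autosome_kb must be > 0")
  if (any(total_roh_kb < 0) || any(total_roh_kb > autosome_kb)) {
    abort_arg("total_roh_kb must lie in [0, autosome_kb]")
  }
  total_roh_kb / autosome_kb
}

#' Construct a pedigree
#'
#' Directed acyclic parent structure used both for expected-inbreeding
#' computation and for gene-dropping simulation.  Founders (individuals
#' with both parents unknown) may carry a founder inbreeding coefficient,
#' which models baseline autozygosity in the source population.
#'
#' @param id character vector of individual identifiers (unique).
#' @param father,mother parent identifiers, NA when unknown; referenced
#'   parents must appear in `id`.
#' @param sex optional sex codes (free-form; "1"/"M" male, "2"/"F"
#'   female by convention), used by the simulator for mitochondrial
#'   transmission.
#' @param founder_f founder inbreeding: a single value for all founders
#'   or a named vector keyed by founder id (default 0).
#' @return a list of class `pedigree` with elements `id`, `father`,
#'   `mother`, `sex`, `founder_f`, and `order` (a topological order,
#'   parents before offspring).
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = NULL,
                     founder_f = 0) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) abort_arg("duplicate individual ids")
  father <- rep_len(as.character(father), n)
  mother <- rep_len(as.character(mother), n)
  bad <- setdiff(c(father, mother), c(id, NA))
  if (length(bad)) abort_arg("unknown parent ids: ", paste(bad, collapse = ", "))
  if (is.null(sex)) sex <- rep(NA_character_, n)

  # topological sort; failure to place everyone means a cycle
  placed <- rep(FALSE, n)
  names(placed) <- id
  ord <- character(0)
  repeat {
    ready <- !placed &
      (is.na(father) | placed[father]) & (is.na(mother) | placed[mother])
    if (!any(ready)) break
    ord <- c(ord, id[ready])
    placed[id[ready]] <- TRUE
  }
  if (!all(placed)) {
    abort_arg("pedigree contains a cycle involving: ",
              paste(id[!placed], collapse = ", "))
  }

  is_founder <- is.na(father) & is.na(mother)
  ff <- setNames(rep(0, n), id)
  if (length(founder_f) == 1L && is.null(names(founder_f))) {
    ff[is_founder] <- founder_f
  } else {
    ff[names(founder_f)] <- founder_f
  }
  structure(list(id = id, father = setNames(father, id),
                 mother = setNames(mother, id),
                 sex = setNames(as.character(sex), id),
                 founder_f = ff, order = ord),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d founders)\n",
              length(x$id), sum(is.na(x$father) & is.na(x$mother))))
  invisible(x)
}

#' Founder identifiers of a pedigree
#' @param ped a [pedigree()].
#' @return character vector of founder ids.
#' @export
ped_founders <- function(ped) {
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' Kinship matrix of a pedigree
#'
#' The tabular (recursive) method: processing individuals parents-first,
#' f(i,i) = (1 + F_i)/2 with F_i the kinship of i's parents (a founder's
#' F is its founder inbreeding), and for j processed before i,
#' f(i,j) = (f(father_i, j) + f(mother_i, j))/2, an unknown parent
#' contributing 0.  Distinct founders are unrelated.
#'
#' @param ped a [pedigree()].
#' @return a symmetric matrix of kinship coefficients, dimnames = ids.
#' @export
kinship_matrix <- function(ped) {
  ids <- ped$order
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    me <- ids[i]
    fa <- ped$father[me]
    mo <- ped$mother[me]
    if (is.na(fa) && is.na(mo)) {
      Fi <- ped$founder_f[me]
    } else {
      Fi <- if (is.na(fa) || is.na(mo)) 0 else K[fa, mo]
    }
    K[me, me] <- 0.5 * (1 + Fi)
    if (i > 1L) {
      prev <- ids[seq_len(i - 1L)]
      kf <- if (is.na(fa)) rep(0, i - 1L) else K[fa, prev]
      km <- if (is.na(mo)) rep(0, i - 1L) else K[mo, prev]
      K[me, prev] <- K[prev, me] <- 0.5 * (kf + km)
    }
  }
  K[ped$id, ped$id]
}

#' Kinship coefficient between two individuals
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return the kinship coefficient f(i, j).
#' @export
#' @examples
#' ped <- pedigree(id = c("A", "B", "S1", "S2", "P"),
#'                 father = c(NA, NA, "A", "A", "S1"),
#'                 mother = c(NA, NA, "B", "B", "S2"))
#' kinship(ped, "S1", "S2") # 0.25: full sibs of unrelated founders
kinship <- function(ped, i, j) {
  if (!all(c(i, j) %in% ped$id)) {
    abort_arg("unknown individual id: ",
              paste(setdiff(c(i, j), ped$id), collapse = ", "))
  }
  kinship_matrix(ped)[i, j]
}

#' Pedigree-expected inbreeding of an individual
#'
#' The inbreeding coefficient of an individual equals the kinship of its
#' parents.
#'
#' @param ped a [pedigree()].
#' @param individual individual id; must have both parents recorded.
#' @return the expected inbreeding coefficient, or NA with a warning when
#'   a parent is unknown.
#' @export
expected_inbreeding <- function(ped, individual) {
  if (!individual %in% ped$id) abort_arg("unknown individual id: ", individual)
  fa <- ped$father[individual]
  mo <- ped$mother[individual]
  if (is.na(fa) || is.na(mo)) {
    warning("individual '", individual,
            "' has an unknown parent; expected inbreeding undefined")
    return(NA_real_)
  }
  kinship(ped, fa, mo)
}

#' Expected inbreeding of a full-sib-mating offspring
#'
#' Closed form for the offspring of two full siblings whose founder
#' grandparents carry a baseline inbreeding level:
#' F = 0.25 * (1 + baseline_f).  With non-inbred founders this is the
#' familiar 0.25; a breed-level baseline (for instance the mean F_ROH of
#' unaffected individuals) raises the expectation accordingly.
#'
#' @param baseline_f baseline (founder) inbreeding in `[0, 1)`.
#' @return the expected inbreeding coefficient.
#' @export
#' @examples
#' expected_sib_f(0)      # 0.25
#' expected_sib_f(0.137)  # 0.284..., 0.28 to 2 decimals
#' expected_sib_f(0.144)  # 0.286, 0.29 to 2 decimals
expected_sib_f <- function(baseline_f) {
  if (any(baseline_f < 0) || any(baseline_f >= 1)) {
    abort_arg("baseline_f must lie in [0, 1)")
  }
  0.25 * (1 + baseline_f)
}

#' Full-sib-mating pedigree
#'
#' Convenience constructor: two founder grandparents, two full siblings,
#' and their offspring (the proband), optionally with baseline founder
#' inbreeding — the pedigree whose expected proband inbreeding is
#' [expected_sib_f()] of the baseline.
#'
#' @param baseline_f founder inbreeding assigned to both grandparents.
#' @param ids identifiers for (grandfather, grandmother, sib-father,
#'   sib-mother, proband).
#' @return a [pedigree()].
#' @export
sib_mating_pedigree <- function(baseline_f = 0,
                                ids = c("GP1", "GP2", "FATHER", "MOTHER",
                                        "PROBAND")) {
  stopifnot(length(ids) == 5L)
  pedigree(id = ids,
           father = c(NA, NA, ids[1], ids[1], ids[3]),
           mother = c(NA, NA, ids[2], ids[2], ids[4]),
           sex = c("1", "2", "1", "2", "2"),
           founder_f = baseline_f)
}

#' Baseline inbreeding from control summaries
#'
#' The breed-level baseline used by [expected_sib_f()]: the arithmetic
#' mean of control F_ROH values.
#'
#' @param summaries either a numeric vector of F_ROH values or a
#'   data.table with an `f_roh` column (as from [summarize_roh_all()]).
#' @return the mean F_ROH.
#' @export
#' @examples
#' baseline_from_controls(c(0.135, 0.144, 0.132)) # 0.137
baseline_from_controls <- function(summaries) {
  vals <- if (is.numeric(summaries)) summaries else summaries$f_roh
  if (length(vals) == 0L) abort_arg("need at least one control summary")
  mean(vals)
}
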