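# Internal helpers shared across modules.

#' Round half-up to a number of decimal places
#'
#' Base [round()] uses round-half-to-even; reported inbreeding expectations
#' follow the conventional half-up rule instead (0.285 -> 0.29).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.28425, 2) # 0.28
#' round_half_up(0.2860, 2)  # 0.29
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Chromosome-naming configuration for genome compartments
#'
#' Maps verbatim chromosome names onto the three compartments used by the
#' pipeline: autosome, X and MT.  Names are matched case-sensitively and
#' any name not listed as X or MT is treated as autosomal, so the package
#' stays agnostic to the genome build's naming scheme.
#'
#' @param x_names chromosome names treated as the X chromosome.
#' @param mt_names chromosome names treated as mitochondrial.
#' @return a list of class `compartment_config`.
#' @export
compartment_config <- function(x_names = c("chrX", "X"),
                               mt_names = c("chrM", "chrMT", "MT", "M")) {
  structure(list(x_names = x_names, mt_names = mt_names),
            class = "compartment_config")
}

#' Assign chromosomes to genome compartments
#'
#' @param chrom character vector of chromosome names.
#' @param naming a [compartment_config()].
#' @return factor with levels `autosome`, `X`, `MT`.
#' @export
#' @examples
#' compartment_of(c("chr1", "chrX", "chrM"))
compartment_of <- function(chrom, naming = compartment_config()) {
  stopifnot(inherits(naming, "compartment_config"))
  out <- rep("autosome", length(chrom))
  out[chrom %in% naming$x_names] <- "X"
  out[chrom %in% naming$mt_names] <- "MT"
  factor(out, levels = c("autosome", "X", "MT"))
}

# stop() with a consistent prefix for user-facing argument errors
abort_arg <- function(...) stop(..., call. = FALSE)
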