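#' Define a binned genome
#'
#' A genome specification fixes the chromosome names, the number of bins per
#' chromosome at the base (finest) resolution, and the bin size in base pairs.
#' All matrices, tracks and truth objects in the package refer back to such a
#' spec. Bin indices are 1-based inside R; all text files written by the
#' package use 0-based half-open coordinates.
#'
#' @param chromosomes named integer vector: bins per chromosome, names are
#'   chromosome names (unique).
#' @param bin_size bin width in base pairs at this resolution.
#' @param seed integer seed associated with the genome (used by generators
#'   that take the spec as their only source of randomness).
#' @return An object of class `genome_spec`.
#' @examples
#' gs <- genome_spec(c(chr1 = 200, chr2 = 150), bin_size = 25000)
#' gs
#' @export
genome_spec <- function(chromosomes, bin_size, seed = 1L) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    err_param("chromosome names must be present and unique")
  chromosomes <- stats::setNames(as.integer(chromosomes), names(chromosomes))
  if (any(chromosomes < 20L))
    err_param("each chromosome needs at least 20 bins")
  if (bin_size <= 0) err_param("bin_size must be positive")
  structure(
    list(chromosomes = chromosomes, bin_size = as.numeric(bin_size),
         seed = as.integer(seed)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosome(s), bin size %s bp\n",
              length(x$chromosomes), format(x$bin_size, big.mark = ",")))
  for (nm in names(x$chromosomes))
    cat(sprintf("  %s: %d bins (%.2f Mb)\n", nm, x$chromosomes[[nm]],
                x$chromosomes[[nm]] * x$bin_size / 1e6))
  invisible(x)
}

chrom_bins <- function(spec, chrom) {
  if (!chrom %in% names(spec$chromosomes))
    err_format(sprintf("unknown chromosome '%s'", chrom))
  spec$chromosomes[[chrom]]
}
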