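#' Standard genetic code with degeneracy classes
#'
#' Builds the codon-level bookkeeping used throughout the package: the 64
#' codons in fixed alphabetical order, their amino-acid assignments under the
#' standard genetic code, stop flags, synonymous-family sizes, and the
#' "informative" mask that excludes stop codons and the single-codon families
#' (Met/ATG, Trp/TGG) from bias statistics. The bacterial code (NCBI table 11)
#' assigns CDS-internal codons identically, so one table serves both organisms.
#'
#' @return An object of class \code{genetic_code}: a list with elements
#'   \describe{
#'     \item{codons}{character(64), alphabetical codon order used everywhere.}
#'     \item{aa}{named character(64), one-letter amino acid (\code{"*"} = stop).}
#'     \item{is_stop}{named logical(64).}
#'     \item{family_size}{named integer(64), synonymous family size of each
#'       sense codon (\code{NA} for stops).}
#'     \item{informative}{named logical(64), TRUE for the 59 codons entering
#'       RSCU/CAI/SiD (sense codons minus ATG and TGG).}
#'     \item{families}{named list, amino acid -> its codons.}
#'     \item{degeneracy}{named integer, amino acid -> family size.}
#'   }
#' @examples
#' gc <- standard_genetic_code()
#' sum(!gc$is_stop)        # 61 sense codons
#' sum(gc$informative)     # 59 informative codons
#' @export
standard_genetic_code <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  names(aa) <- codons
  is_stop <- aa == "*"
  families <- split(codons[!is_stop], aa[!is_stop])
  degeneracy <- vapply(families, length, integer(1))
  family_size <- rep(NA_integer_, 64)
  names(family_size) <- codons
  family_size[!is_stop] <- degeneracy[aa[!is_stop]]
  informative <- !is_stop & family_size > 1L
  stopifnot(sum(!is_stop) == 61L, sum(degeneracy) == 61L,
            sum(informative) == 59L)
  structure(
    list(codons = codons, aa = aa, is_stop = is_stop,
         family_size = family_size, informative = informative,
         families = families, degeneracy = degeneracy),
    class = "genetic_code"
  )
}

# Amino acids whose synonymous third position is fully degenerate (fourfold
# boxes); the fourfold sub-boxes of the sixfold families (Leu, Ser, Arg) are
# deliberately excluded from the default PR2 codon set.
FOURFOLD_AA <- c("A", "G", "P", "T", "V")
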