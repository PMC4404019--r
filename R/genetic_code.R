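#' The 64 codons in RNA alphabet
#'
#' Codons are listed in the classic codon-table order (first base slowest,
#' bases ordered U, C, A, G). All codon-indexed objects in the package
#' (counts, RSCU tables, 64x64 pair matrices) use this order.
#'
#' @return Character vector of the 64 RNA-alphabet codons.
#' @export
codons <- function() {
  b <- c("U", "C", "A", "G")
  as.vector(vapply(b, function(b1)
    vapply(b, function(b2) paste0(b1, b2, b), character(4)),
    character(16)))
}

#' Standard genetic code with synonymous family sizes
#'
#' Returns the standard genetic code as a mapping from RNA-alphabet codons to
#' one-letter amino acids (stop codons map to \code{"*"}, displayed as TER)
#' together with the synonymous family size of each amino acid, i.e. the
#' number of codons encoding it. Family sizes are the \eqn{n_i} of the RSCU
#' formula: Met and Trp have size 1, the TER family size 3.
#'
#' @return A list with components \code{codon_to_aa} (named character vector
#'   over the 64 codons) and \code{family_size} (named integer vector over
#'   amino acids plus \code{"*"}).
#' @examples
#' gc <- genetic_code()
#' gc$family_size[["M"]]  # 1
#' gc$family_size[["*"]]  # 3
#' @export
genetic_code <- function() {
  cods <- codons()
  dna <- chartr("U", "T", cods)
  aa <- unname(Biostrings::GENETIC_CODE[dna])
  names(aa) <- cods
  fam <- table(aa)
  list(codon_to_aa = aa,
       family_size = stats::setNames(as.integer(fam), names(fam)))
}

# three-letter display names used in report tables (stop printed as TER)
AA_NAMES <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "TER"
)

#' @rdname genetic_code
#' @param aa One-letter amino-acid codes (\code{"*"} for stop).
#' @return \code{aa_name()}: three-letter display names (\code{"TER"} for stop).
#' @export
aa_name <- function(aa) unname(AA_NAMES[aa])
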