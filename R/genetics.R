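## Standard genetic code, taken from Biostrings at load time; stop codons are "*".
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  structure(as.character(gc), names = names(gc))
}

.CODE <- NULL # filled in .onLoad

.onLoad <- function(libname, pkgname) {
  .CODE <<- .genetic_code()
}

#' Translate codons with the standard genetic code
#'
#' Vectorised lookup in the standard (nuclear) codon table. Stop codons
#' translate to `"*"`.
#'
#' @param codon character vector of 3-mers over `A`, `C`, `G`, `T`.
#' @return character vector of one-letter amino-acid codes (`"*"` for stop).
#' @examples
#' translate_codon(c("ATG", "TAG"))
#' @export
translate_codon <- function(codon) {
  if (is.null(.CODE)) .CODE <<- .genetic_code()
  codon <- toupper(codon)
  bad <- nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  }
  unname(.CODE[codon])
}

#' Codons encoding an amino acid
#'
#' @param aa one-letter amino-acid code, or `"*"` for stop.
#' @return character vector of codons.
#' @export
codons_for_aa <- function(aa) {
  if (is.null(.CODE)) .CODE <<- .genetic_code()
  stopifnot(length(aa) == 1L)
  sort(names(.CODE)[.CODE == aa])
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Complement nucleotide bases
#'
#' @param base character vector of single bases in `A`, `C`, `G`, `T`.
#' @return complemented bases.
#' @export
complement_base <- function(base) {
  out <- .COMPLEMENT[toupper(base)]
  if (anyNA(out)) stop("non-ACGT base in complement_base()")
  unname(out)
}

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character strings.
#'
#' @param x character vector of nucleotide strings.
#' @return reverse-complemented strings.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Three-letter -> one-letter residue codes, plus stop spellings used in text.
.AA3TO1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)

.AA1TO3 <- structure(names(.AA3TO1), names = unname(.AA3TO1))

#' Normalise an amino-acid token to a one-letter code
#'
#' Accepts one-letter codes, three-letter codes (`Arg`, `Ter`, ...) and the
#' stop spellings `X` and `*`.
#'
#' @param token character vector of residue tokens.
#' @return one-letter codes, with `"*"` for stop.
#' @export
normalize_aa <- function(token) {
  one <- ifelse(token %in% c("X", "x", "*"), "*",
    ifelse(nchar(token) == 1L, toupper(token),
      unname(.AA3TO1[paste0(
        toupper(substr(token, 1, 1)), tolower(substr(token, 2, 3))
      )])
    )
  )
  if (anyNA(one) || !all(one %in% c(unname(.AA3TO1), "*"))) {
    stop("unrecognised amino-acid token(s): ",
         paste(unique(token[is.na(one)]), collapse = ", "))
  }
  one
}

#' Classify a base substitution as transition or transversion
#'
#' Purine\eqn{\leftrightarrow}purine (A/G) and
#' pyrimidine\eqn{\leftrightarrow}pyrimidine (C/T) changes are transitions
#' (`Ti`); changes across the two base classes are transversions (`Tv`).
#'
#' @param ref_allele,sub_allele single reference and substituted bases
#'   (vectorised); the two must differ position-wise.
#' @return character vector of `"Ti"` / `"Tv"`.
#' @examples
#' ti_tv("A", "G") # transition
#' ti_tv("A", "T") # transversion
#' @export
ti_tv <- function(ref_allele, sub_allele) {
  ref_allele <- toupper(ref_allele)
  sub_allele <- toupper(sub_allele)
  ok <- ref_allele %in% names(.COMPLEMENT) & sub_allele %in% names(.COMPLEMENT)
  if (!all(ok)) stop("ti_tv(): alleles must be in A, C, G, T")
  if (any(ref_allele == sub_allele)) {
    stop("ti_tv(): reference and substituted allele are identical")
  }
  purine <- c("A", "G")
  same_class <- (ref_allele %in% purine) == (sub_allele %in% purine)
  ifelse(same_class, "Ti", "Tv")
}

## The 12 ordered single-nucleotide allele pairs, in a fixed display order
## (transitions first), used by the allele-pair distribution and tests.
.ALLELE_PAIRS <- c(
  "AG", "GA", "CT", "TC",
  "AC", "AT", "CA", "CG", "GC", "GT", "TA", "TG"
)

#' The 12 ordered allele pairs
#'
#' @return character vector of the 12 ordered reference-to-substituted pairs
#'   (e.g. `"AG"` means A substituted by G), transitions listed first.
#' @export
allele_pairs <- function() .ALLELE_PAIRS

#' Hamming distance between equal-length strings
#' @keywords internal
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
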