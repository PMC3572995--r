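#' @importFrom stats pchisq qchisq rnorm runif setNames
#' @importFrom utils read.table write.table
NULL

# IUPAC machinery for diploid consensus sequences.
#
# A heterozygous Sanger consensus shows, at each site where the two
# chromosomes differ, the 2-base IUPAC code for the union of the two bases.
# superpose() formalises that: it is the per-position IUPAC union of two
# unambiguous sequences, and is the ground truth the typing step inverts.

IUPAC_BASES <- c("A", "C", "G", "T")

# two-base union codes, keyed by the sorted base pair
.SUPERPOSE_CODE <- c(
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K"
)

# 4x4 lookup: [base_a, base_b] -> consensus code
.SUPERPOSE_MAT <- local({
  m <- matrix("", 4, 4, dimnames = list(IUPAC_BASES, IUPAC_BASES))
  for (a in IUPAC_BASES) for (b in IUPAC_BASES) {
    m[a, b] <- if (a == b) a else .SUPERPOSE_CODE[paste(sort(c(a, b)), collapse = "")]
  }
  m
})

.IUPAC_ALL <- names(Biostrings::IUPAC_CODE_MAP)

#' Superpose two unambiguous sequences into a diploid IUPAC consensus
#'
#' Models the single-trace consensus of a heterozygote: positions where the
#' two sequences agree pass through; positions where they differ become the
#' 2-base IUPAC ambiguity code (A/G -> R, C/T -> Y, C/G -> S, A/T -> W,
#' G/T -> K, A/C -> M). The operation is commutative and
#' `superpose(s, s) == s`.
#'
#' @param seq_a,seq_b Equal-length nucleotide strings over `A`,`C`,`G`,`T`.
#' @return A single IUPAC string of the same length.
#' @export
#' @examples
#' superpose("ACGT", "GCTT")  # "RCKT"
superpose <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("frame error: sequences have unequal lengths (",
         nchar(seq_a), " vs ", nchar(seq_b), ")")
  }
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  bad <- !(a %in% IUPAC_BASES) | !(b %in% IUPAC_BASES)
  if (any(bad)) {
    stop("superpose() requires unambiguous A/C/G/T sequences; offending position ",
         which(bad)[1])
  }
  paste(.SUPERPOSE_MAT[cbind(a, b)], collapse = "")
}

#' Reverse-complement an IUPAC string
#'
#' Ambiguity codes complement as unions of their bases (R <-> Y, K <-> M,
#' S and W are self-complementary).
#'
#' @param x A single IUPAC nucleotide string.
#' @return The reverse complement, same length.
#' @export
reverse_complement_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  validate_iupac(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# stop() unless every character is a valid IUPAC code; returns x invisibly
validate_iupac <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% .IUPAC_ALL)
  if (any(bad)) {
    stop("invalid nucleotide character '", chars[which(bad)[1]],
         "' at position ", which(bad)[1])
  }
  invisible(x)
}

# TRUE where a string contains any code covering 3+ bases (incl. N):
# a diploid superposition can only produce 1- or 2-base codes.
has_multibase_code <- function(x) {
  grepl("[VHDBN]", x)
}

# normalise raw sequence text: uppercase, RNA U -> T
normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
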