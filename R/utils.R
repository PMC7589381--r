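#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' Draws a uniform random nucleotide string from the current RNG stream.
#' All exported generators wrap their randomness in [withr::with_seed()],
#' so this helper never touches the caller's RNG state when used through
#' them.
#'
#' @param n Sequence length in nucleotides.
#' @return A single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' GC content of a sequence
#'
#' @param x A single DNA string.
#' @return GC percentage in \[0, 100\].
#' @export
gc_percent <- function(x) {
  b <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  100 * mean(b %in% c("G", "C"))
}

# Nucleotide scoring close to EDNAFULL ratios; used by every alignment in
# the package so identities and event calls are mutually consistent.
.sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
}

.align_global <- function(a, b) {
  Biostrings::pairwiseAlignment(a, b,
    type = "global",
    substitutionMatrix = .sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
}

# Aligned pattern/subject strings with '-' gap characters.
.aligned_strings <- function(aln) {
  c(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln))
  )
}

#' Global-alignment identity between two sequences
#'
#' Identity is the number of matching columns divided by the total number
#' of alignment columns; gap columns count as mismatches.
#'
#' @param a,b DNA strings.
#' @return Identity fraction in \[0, 1\].
#' @export
alignment_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- .align_global(a, b)
  cols <- nchar(.aligned_strings(aln)[1])
  Biostrings::nmatch(aln) / cols
}

# Substitute the character at string position i.
.subst_at <- function(seq, i, base) {
  substr(seq, i, i) <- base
  seq
}

# A base different from `base`, drawn from the RNG stream.
.other_base <- function(base) {
  sample(setdiff(DNA_BASES, base), 1L)
}
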