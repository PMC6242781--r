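## IUPAC nucleotide alphabet utilities shared by all modules.
##
## Coordinates throughout the package are 1-based and closed (the native
## R/Bioconductor convention): a window [start, end] of length end - start + 1.

#' @keywords internal
IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_CHARS <- names(IUPAC_CODES)

## complement pairs: A<->T, C<->G, R<->Y, K<->M, B<->V, D<->H; S,W,N self
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Set of concrete bases denoted by an IUPAC code
#'
#' @param code single IUPAC character.
#' @return character vector of concrete bases (subset of A, C, G, T).
#' @keywords internal
iupac_set <- function(code) {
  s <- IUPAC_CODES[[code]]
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Validate a DNA string over the IUPAC alphabet
#'
#' @param seq character scalar.
#' @param allow_gap allow the `-` gap character.
#' @param id record identifier used in error messages.
#' @return the validated, upper-cased sequence (invisibly usable).
#' @keywords internal
validate_dna <- function(seq, allow_gap = FALSE, id = "<seq>") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop("alphabet error: record '", id, "' has an empty or missing sequence",
         call. = FALSE)
  }
  seq <- toupper(seq)
  ok <- IUPAC_CHARS
  if (allow_gap) ok <- c(ok, "-")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(ch %in% ok))
  if (length(bad)) {
    stop("alphabet error: record '", id, "' contains invalid character '",
         ch[bad[1]], "' at position ", bad[1], call. = FALSE)
  }
  seq
}

#' Reverse complement of an IUPAC DNA string
#'
#' Ambiguity codes map to their complements (R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary). Gap characters are rejected.
#'
#' @param seq DNA string (character scalar), ungapped.
#' @return the reverse complement as a character scalar.
#' @examples
#' revcomp("ACGT")  # palindrome: "ACGT"
#' revcomp("AAA")   # "TTT"
#' @export
revcomp <- function(seq) {
  seq <- validate_dna(seq, allow_gap = FALSE, id = "revcomp input")
  comp <- chartr(IUPAC_FROM, IUPAC_TO, seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Remove gap characters from a sequence
#' @param seq character scalar possibly containing `-`.
#' @return ungapped sequence.
#' @export
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

## fast char-vector helpers used in inner loops
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]
chars_seq <- function(ch) paste(ch, collapse = "")
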