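# Shared small helpers: alphabet handling, reverse complement, rounding.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Normalise a nucleotide string to uppercase RNA (T -> U)
#' @param x character vector of sequences
#' @return character vector over A/C/G/U
#' @keywords internal
as_rna <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Normalise a nucleotide string to uppercase DNA (U -> T)
#' @param x character vector of sequences
#' @return character vector over A/C/G/T
#' @keywords internal
as_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

check_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUTacgut]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement (alphabet preserved: DNA in -> DNA out, RNA in -> RNA out)
#' @param x character vector of sequences
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE) & !grepl("T", toupper(x), fixed = TRUE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(as_dna(x))))
  ifelse(is_rna, as_rna(out), out)
}

complement_base <- function(b, rna = TRUE) {
  comp <- c(A = if (rna) "U" else "T", C = "G", G = "C", U = "A", T = "A")
  unname(comp[b])
}

# Watson-Crick or wobble pairing between two RNA bases (both 5'->3' reading,
# i.e. the caller has already anti-parallelised the strands).
pairs_wc <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}
pairs_wobble <- function(a, b) {
  (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Round half away from zero at a given number of decimals
#'
#' Reporting convention for fold changes and percentages: 1.25 -> 1.3,
#' -1.25 -> -1.3 (base R `round` rounds half to even).
#' @param x numeric
#' @param digits integer number of decimals
#' @return numeric
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

random_seq <- function(n, bases = DNA_BASES, prob = NULL) {
  paste(sample(bases, n, replace = TRUE, prob = prob), collapse = "")
}

# substring of a vectorised character scalar as character vector of single chars
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

TISSUES <- c("seedlings", "flag_leaves", "seed_5d", "seed_10d", "seed_20d")
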