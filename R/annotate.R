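# Genome matching, ncRNA contaminant removal, known-miRNA assignment and
# conservation classing.

#' Match unique reads to the genome by exact full-length search
#'
#' Every occurrence of each read (or its reverse complement) in the contigs
#' is reported; matching treats T and U as equivalent.
#'
#' @param sequences character vector of unique read sequences.
#' @param genome named `DNAStringSet` or named character vector of contigs.
#' @param max_report cap on reported loci per read (total count still in
#'   `n_loci`).
#' @return list: `hits` data.frame (`sequence`, `contig`, `start`, `end`
#'   1-based inclusive, `strand`, `n_loci`), `matched` and `unmatched`
#'   character vectors.
#' @export
match_genome <- function(sequences, genome, max_report = 50L) {
  genome <- as_genome_set(genome)
  if (length(genome) == 0 || all(!nzchar(genome))) {
    stop("empty genome", call. = FALSE)
  }
  subjects <- Biostrings::DNAStringSet(genome)
  seqs_dna <- as_dna(sequences)
  widths <- nchar(seqs_dna)
  rows <- list()
  # width-grouped PDict keeps exact multi-pattern search fast
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pats_f <- Biostrings::DNAStringSet(seqs_dna[idx])
    pats_r <- Biostrings::reverseComplement(pats_f)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") pats_f else pats_r)
      for (ci in seq_along(subjects)) {
        m <- Biostrings::matchPDict(pd, subjects[[ci]])
        starts <- BiocGenerics::start(m)  # IntegerList, one element per pattern
        hit_pat <- which(lengths(starts) > 0)
        for (p in hit_pat) {
          st <- starts[[p]]
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = sequences[idx[p]], contig = names(genome)[ci],
            start = st, end = st + w - 1L, strand = strand)
        }
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  n_loci_tab <- table(hits$sequence)
  if (nrow(hits) > 0) {
    hits$n_loci <- as.integer(n_loci_tab[hits$sequence])
    hits <- do.call(rbind, lapply(split(hits, hits$sequence),
                                  utils::head, max_report))
    hits <- hits[order(match(hits$sequence, sequences), hits$contig, hits$start), ,
                 drop = FALSE]
  } else {
    hits$n_loci <- integer(0)
  }
  rownames(hits) <- NULL
  n_loci <- integer(length(sequences))
  got <- match(names(n_loci_tab), sequences)
  n_loci[got] <- as.integer(n_loci_tab)
  list(hits = hits,
       matched = sequences[n_loci > 0],
       unmatched = sequences[n_loci == 0])
}

#' Remove reads resembling non-coding RNAs
#'
#' A read is removed when an ungapped full-length alignment to any reference
#' (either strand) has identity strictly above `min_identity`, with identity
#' defined as matches divided by read length.
#'
#' @param sequences character vector of reads.
#' @param refs named character vector or `DNAStringSet` of ncRNA references
#'   (rRNA/tRNA/snRNA/snoRNA); must be non-empty.
#' @param min_identity identity threshold (0.90).
#' @return list with `removed` and `retained` character vectors.
#' @export
filter_ncrna <- function(sequences, refs, min_identity = 0.90) {
  if (inherits(refs, "DNAStringSet")) refs <- as.character(refs)
  if (length(refs) == 0) stop("ncRNA reference set is empty", call. = FALSE)
  subjects <- Biostrings::DNAStringSet(as_dna(refs))
  seqs_dna <- as_dna(sequences)
  widths <- nchar(seqs_dna)
  hit <- rep(FALSE, length(sequences))
  # fast path: verbatim (0-mismatch) fragments via width-grouped PDict
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pats_f <- Biostrings::DNAStringSet(seqs_dna[idx])
    pats_r <- Biostrings::reverseComplement(pats_f)
    for (subj in seq_along(subjects)) {
      hit[idx] <- hit[idx] |
        lengths(BiocGenerics::start(
          Biostrings::matchPDict(Biostrings::PDict(pats_f), subjects[[subj]]))) > 0 |
        lengths(BiocGenerics::start(
          Biostrings::matchPDict(Biostrings::PDict(pats_r), subjects[[subj]]))) > 0
    }
  }
  # remaining reads: ungapped alignment allowing mismatches up to the
  # identity bound (identity > min_identity <=> mismatches < len * (1 - id))
  for (k in which(!hit)) {
    len <- widths[k]
    mm_max <- as.integer(floor(len * (1 - min_identity) - 1e-9))
    if (mm_max < 1) next
    pat <- Biostrings::DNAString(seqs_dna[k])
    hit[k] <-
      any(Biostrings::vcountPattern(pat, subjects, max.mismatch = mm_max) > 0) ||
      any(Biostrings::vcountPattern(Biostrings::reverseComplement(pat), subjects,
                                    max.mismatch = mm_max) > 0)
  }
  list(removed = sequences[hit], retained = sequences[!hit])
}

#' Read a known-miRNA catalogue FASTA
#'
#' Headers follow `name|family|species` with species a `;`-separated tag list
#' (`tae` marks wheat).
#'
#' @param path catalogue FASTA.
#' @return data.frame: `name`, `family`, `species` (";"-separated),
#'   `sequence` (RNA).
#' @export
read_mirna_catalogue <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) {
    stop("catalogue headers must be name|family|species", call. = FALSE)
  }
  data.frame(name = vapply(parts, `[[`, character(1), 1),
             family = vapply(parts, `[[`, character(1), 2),
             species = vapply(parts, `[[`, character(1), 3),
             sequence = as_rna(as.character(x)))
}

#' Assign known miRNAs by exact sequence-and-length match
#'
#' A read is assigned iff its sequence is identical (same bases, same length;
#' T/U equivalent) to a catalogue mature sequence. Matches whose catalogue
#' entry carries no wheat (`tae`) species tag are flagged as requiring a
#' wheat precursor validation, to be handed to the discovery stage.
#'
#' @param sequences character vector of reads.
#' @param catalogue data.frame from [read_mirna_catalogue()] (or with the
#'   same columns).
#' @return data.frame of assignments: `sequence`, `name`, `family`,
#'   `needs_validation`; zero rows if nothing matches.
#' @export
assign_known <- function(sequences, catalogue) {
  dup <- duplicated(catalogue$sequence)
  if (any(dup)) {
    for (s in unique(catalogue$sequence[dup])) {
      fams <- unique(catalogue$family[catalogue$sequence == s])
      if (length(fams) > 1) {
        stop("catalogue sequence assigned to conflicting families: ",
             paste(fams, collapse = " vs "), " (", s, ")", call. = FALSE)
      }
    }
  }
  idx <- match(as_rna(sequences), catalogue$sequence)
  sel <- !is.na(idx)
  species <- strsplit(catalogue$species[idx[sel]], ";", fixed = TRUE)
  data.frame(sequence = sequences[sel],
             name = catalogue$name[idx[sel]],
             family = catalogue$family[idx[sel]],
             needs_validation = !vapply(species, function(sp) "tae" %in% sp,
                                        logical(1)))
}

CONSERVATION_SPECIES <- c("Arabidopsis", "soybean", "Populus",
                          "rice", "maize", "Brachypodium")

#' Classify family conservation across the six reference species
#'
#' Highly conserved families are present in all three dicots (Arabidopsis,
#' soybean, Populus) and all three monocots (rice, maize, Brachypodium);
#' moderately conserved families are present in at least one but not all six;
#' families in none are non-conserved.
#'
#' @param species_presence character vector, subset of the six species.
#' @return one of "highly_conserved", "moderately_conserved", "non_conserved".
#' @export
classify_conservation <- function(species_presence) {
  species_presence <- unique(species_presence)
  unknown <- setdiff(species_presence, CONSERVATION_SPECIES)
  if (length(unknown)) {
    stop("unknown species label: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- length(species_presence)
  if (n == length(CONSERVATION_SPECIES)) "highly_conserved"
  else if (n >= 1) "moderately_conserved"
  else "non_conserved"
}
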