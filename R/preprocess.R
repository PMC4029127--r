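# Raw read cleaning (adapters, length, quality, low-complexity repeats),
# unique-tag collapsing, and size-distribution statistics.

#' Read raw reads from FASTQ or collapsed FASTA
#'
#' FASTQ (Phred+33) files yield one entry per read with qualities; collapsed
#' FASTA files with `>id_count` headers are expanded according to their
#' counts (qualities are then NULL).
#'
#' @param path input file.
#' @return list with `sequences` (character vector, DNA) and `qualities`
#'   (character vector of Phred+33 strings, or NULL).
#' @export
read_raw_reads <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0) return(list(sequences = character(0), qualities = NULL))
  if (startsWith(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    list(sequences = unname(as.character(x)),
         qualities = unname(as.character(S4Vectors::mcols(x)$qualities)))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    counts <- suppressWarnings(as.integer(sub(".*_", "", names(x))))
    if (anyNA(counts)) stop("collapsed FASTA headers must end in _<count>",
                            call. = FALSE)
    list(sequences = rep(unname(as.character(x)), counts), qualities = NULL)
  }
}

#' Clean raw sRNA reads
#'
#' Per read: checks mean base quality, discards 5'-adapter contaminants,
#' locates and removes the 3' adapter (exact seed of `seed_len` nt, extension
#' matched exactly), and keeps inserts of 18-30 nt whose longest homopolymer
#' run and longest dinucleotide-repeat run each cover at most half of the
#' read. Reads whose 3' adapter cannot be located are discarded by default
#' (their insert boundary is unknown). Cleaning already-clean inserts (no
#' adapter present) therefore requires `discard_no_adapter = FALSE`, under
#' which such reads pass through unchanged.
#'
#' @param reads character vector of raw reads (or the list from
#'   [read_raw_reads()]).
#' @param adapter_3p,adapter_5p adapter sequences (DNA, non-empty).
#' @param qualities optional Phred+33 quality strings.
#' @param min_len,max_len insert length bounds (18 and 30 nt).
#' @param quality_min minimum mean Phred score (20).
#' @param repeat_max maximal fraction of the read covered by its longest
#'   homopolymer or dinucleotide-repeat run (0.5).
#' @param seed_len adapter seed length.
#' @param discard_no_adapter discard reads without a located 3' adapter.
#' @return list with `clean` (character vector of inserts) and `log` (named
#'   integer tally: input, kept and each discard reason).
#' @export
trim_and_filter <- function(reads, adapter_3p, adapter_5p = NULL,
                            qualities = NULL,
                            min_len = 18L, max_len = 30L, quality_min = 20,
                            repeat_max = 0.5, seed_len = 8L,
                            discard_no_adapter = TRUE) {
  if (is.list(reads) && !is.null(reads$sequences)) {
    qualities <- reads$qualities
    reads <- reads$sequences
  }
  if (!nzchar(adapter_3p)) stop("adapter_3p must be a non-empty DNA string",
                                call. = FALSE)
  n <- length(reads)
  log <- c(input = n, kept = 0L, low_quality = 0L, adapter5_contaminant = 0L,
           no_adapter = 0L, too_short = 0L, too_long = 0L, low_complexity = 0L)
  if (n == 0) {
    warning("empty input: no reads to clean")
    return(list(clean = character(0), log = log))
  }
  bad <- grepl("[^ACGTNacgtn]", reads)
  if (any(bad)) stop("unreadable record at index ", which(bad)[1], call. = FALSE)
  reads <- unname(toupper(reads))

  keep_qual <- rep(TRUE, n)
  if (!is.null(qualities)) {
    mean_q <- vapply(qualities, function(q) {
      mean(utf8ToInt(q)) - 33
    }, numeric(1), USE.NAMES = FALSE)
    keep_qual <- mean_q >= quality_min
  }
  log["low_quality"] <- sum(!keep_qual)

  seed3 <- substr(adapter_3p, 1L, min(seed_len, nchar(adapter_3p)))
  is_contam <- if (!is.null(adapter_5p) && nzchar(adapter_5p)) {
    startsWith(reads, substr(adapter_5p, 1L, min(seed_len, nchar(adapter_5p))))
  } else rep(FALSE, n)

  clean <- character(0)
  for (i in seq_len(n)) {
    if (!keep_qual[i]) next
    if (is_contam[i]) { log["adapter5_contaminant"] <- log["adapter5_contaminant"] + 1L; next }
    r <- reads[i]
    pos <- find_adapter(r, adapter_3p, seed3)
    if (is.na(pos)) {
      if (discard_no_adapter) { log["no_adapter"] <- log["no_adapter"] + 1L; next }
      insert <- r
    } else {
      insert <- substr(r, 1L, pos - 1L)
    }
    len <- nchar(insert)
    if (len < min_len) { log["too_short"] <- log["too_short"] + 1L; next }
    if (len > max_len) { log["too_long"] <- log["too_long"] + 1L; next }
    if (max_repeat_fraction(insert) > repeat_max) {
      log["low_complexity"] <- log["low_complexity"] + 1L; next
    }
    clean <- c(clean, insert)
  }
  log["kept"] <- length(clean)
  list(clean = clean, log = log)
}

# First position of the 3' adapter in the read: exact seed occurrence whose
# following bases continue the adapter exactly (to the end of read or adapter).
find_adapter <- function(read, adapter, seed) {
  starts <- gregexpr(seed, read, fixed = TRUE)[[1]]
  if (starts[1] == -1) return(NA_integer_)
  for (p in starts) {
    tail_len <- min(nchar(read) - p + 1L, nchar(adapter))
    if (substr(read, p, p + tail_len - 1L) == substr(adapter, 1L, tail_len)) {
      return(p)
    }
  }
  NA_integer_
}

# Fraction of the read covered by its longest homopolymer or
# dinucleotide-repeat run.
max_repeat_fraction <- function(x) {
  longest <- function(pattern) {
    m <- gregexpr(pattern, x, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else max(attr(m, "match.length"))
  }
  run <- max(longest("(.)\\1+"), longest("(..)\\1+"))
  run / nchar(x)
}

#' Collapse clean reads to a unique-sequence count table
#'
#' @param libraries named list of character vectors (clean reads per library).
#' @return data.frame: `sequence`, one count column per library,
#'   `total_count`; one row per distinct sequence, ordered by decreasing
#'   total count then sequence.
#' @export
collapse_unique <- function(libraries) {
  stopifnot(is.list(libraries), !is.null(names(libraries)))
  all_seqs <- sort(unique(unlist(libraries, use.names = FALSE)))
  out <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(libraries)) {
    tab <- table(libraries[[lib]])
    out[[lib]] <- as.integer(tab[out$sequence])
    out[[lib]][is.na(out[[lib]])] <- 0L
  }
  out$total_count <- as.integer(rowSums(out[names(libraries)]))
  out <- out[order(-out$total_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-length size distribution of clean reads
#'
#' Frequencies are expressed as a percentage of the total number of clean
#' reads (redundant variant) or of distinct sequences (unique variant), per
#' library.
#'
#' @param table a unique-read table from [collapse_unique()].
#' @param min_len,max_len length range to tabulate.
#' @return data.frame: `library`, `length`, `redundant_pct`, `unique_pct`.
#'   Libraries with no reads are omitted.
#' @export
size_distribution <- function(table, min_len = 18L, max_len = 30L) {
  libs <- setdiff(names(table), c("sequence", "total_count"))
  lens <- nchar(table$sequence)
  stopifnot(all(lens >= min_len & lens <= max_len))
  rows <- list()
  for (lib in libs) {
    counts <- table[[lib]]
    tot_red <- sum(counts)
    tot_unq <- sum(counts > 0)
    if (tot_red == 0) next
    for (L in min_len:max_len) {
      sel <- lens == L
      rows[[length(rows) + 1L]] <- data.frame(
        library = lib, length = L,
        redundant_pct = 100 * sum(counts[sel]) / tot_red,
        unique_pct = 100 * sum(counts[sel] > 0) / tot_unq)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(library = character(0), length = integer(0),
                      redundant_pct = numeric(0), unique_pct = numeric(0)))
  }
  do.call(rbind, rows)
}
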