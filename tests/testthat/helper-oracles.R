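# Independent brute-force oracles used to cross-check the implementation.

# deterministic non-complementary substitution for mismatch fixtures
flip_base <- function(b) c(A = "C", C = "A", G = "T", T = "G", U = "A")[[b]]

# Bracket matching by explicit scan (independent of pair_table)
oracle_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  pt <- integer(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") open <- c(open, i)
    if (ch[i] == ")") {
      pt[i] <- open[length(open)]
      pt[open[length(open)]] <- i
      open <- open[-length(open)]
    }
  }
  pt
}

# Brute-force duplex walk: derives the star span with the explicit canonical
# rule and re-counts pairs / mismatches / bulges from the pair list.
oracle_duplex <- function(db, m1, m2) {
  pt <- oracle_pairs(db)
  partners <- pt[m1:m2]
  if (all(partners == 0)) return(list(valid = FALSE))
  outside <- partners[partners > 0]
  if (any(outside >= m1 & outside <= m2)) return(list(valid = FALSE))
  if (any(outside > m2) && any(outside < m1)) return(list(valid = FALSE))
  j <- m2 - 2L
  while (j >= m1 && pt[j] == 0) j <- j - 1L
  i <- m1
  while (i <= m2 && pt[i] == 0) i <- i + 1L
  star_start <- pt[j] - ((m2 - 2L) - j)
  star_end <- pt[i] + (i - m1) + 2L
  paired_pos <- (m1:m2)[pt[m1:m2] > 0]
  paired <- length(paired_pos)
  mism <- 0L
  bulges <- integer(0)
  if (paired > 1) {
    for (k in seq_len(paired - 1L)) {
      a <- paired_pos[k + 1L] - paired_pos[k] - 1L
      b <- abs(pt[paired_pos[k]] - pt[paired_pos[k + 1L]]) - 1L
      mism <- mism + min(a, b)
      if (a != b) bulges <- c(bulges, abs(a - b))
    }
  }
  mism <- mism + (paired_pos[1] - m1) + max(0L, (m2 - 2L) - paired_pos[paired])
  list(valid = TRUE, paired_bases = paired, mismatches = mism,
       bulge_sizes = bulges, star_start = star_start, star_end = star_end)
}

# Naive O(n*m) substring scan over both strands
oracle_genome_scan <- function(sequences, genome) {
  rows <- list()
  rc <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  for (s in sequences) {
    sd <- gsub("U", "T", toupper(s))
    for (cn in names(genome)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sd else rc(sd)
        hitpos <- integer(0)
        from <- 1L
        repeat {
          p <- regexpr(pat, substr(genome[[cn]], from, nchar(genome[[cn]])),
                       fixed = TRUE)[1]
          if (p == -1) break
          hitpos <- c(hitpos, from + p - 1L)
          from <- from + p
        }
        for (h in hitpos) {
          rows[[length(rows) + 1L]] <- data.frame(
            sequence = s, contig = cn, start = h,
            end = h + nchar(sd) - 1L, strand = strand)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0))
}

# Exhaustive target-site scoring: every start and site length, no prefilter
oracle_target_sites <- function(mirna, transcript, max_expectation = 3,
                                params = wheatmir::target_params()) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  rows <- list()
  for (s0 in seq_len(Tn)) {
    for (site_len in (L - params$max_gaps):(L + params$max_gaps)) {
      e0 <- s0 + site_len - 1L
      if (e0 > Tn) next
      sc <- tryCatch(
        wheatmir::score_duplex(mirna, substr(transcript, s0, e0), params),
        error = function(e) NULL)
      if (is.null(sc) || sc$expectation > max_expectation + 1e-9) next
      rows[[length(rows) + 1L]] <- data.frame(start = s0, end = e0,
                                              expectation = sc$expectation)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), expectation = numeric(0))
}
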