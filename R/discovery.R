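# Hairpin precursor validation: duplex geometry from the dot-bracket,
# MIREAP-style thresholds, locus read partitioning and the final
# novel / candidate / rejected call.

#' Default precursor / duplex validation parameters
#'
#' The thresholds used for miRNA precursor validation: mature length 20-23 nt,
#' precursor MFE at most -18 kcal/mol, at least 16 mature bases paired in the
#' miRNA/miRNA* duplex, bulges at most 2 nt with at most 2 asymmetric bulges
#' and per-bulge asymmetry at most 2, at most 300 nt between the duplex arms,
#' at most 20 genomic copies, 20-nt precursor flanks, and at most 4 mismatched
#' mature bases (5 when the star read is detected). Abundance cut-off for a
#' novel/candidate call is 5 RPM in at least one tissue. "Maximal/minimal"
#' thresholds are inclusive; the read-partition fractions (>95% of
#' precursor-mapped reads on the locus set, >75% of those reads exactly the
#' mature sequence) are strict, following the wording of each rule.
#'
#' @return named list of thresholds.
#' @export
mireap_params <- function() {
  list(
    min_mature_len   = 20L,
    max_mature_len   = 23L,
    max_copy_number  = 20L,
    max_mfe          = -18,    # kcal/mol, inclusive
    max_arm_span     = 300L,   # nt between miRNA and miRNA*
    min_paired       = 16L,    # paired mature bases
    max_bulge        = 2L,     # nt, per asymmetric bulge
    max_asym_bulges  = 2L,
    max_asymmetry    = 2L,
    max_mismatch     = 4L,     # mismatched mature bases, no star
    max_mismatch_star = 5L,    # ... when miRNA* detected
    flank            = 20L,    # precursor flank, nt
    min_frac_locus   = 0.95,   # strict >
    min_frac_reliable = 0.75,  # strict >
    min_rpm          = 5,
    star_tolerance   = 2L      # +/- nt around predicted star 5' end
  )
}

#' Evaluate the miRNA/miRNA* duplex implied by a precursor structure
#'
#' Given a folded precursor and the mature miRNA position on it, derives the
#' star arm by the canonical rule (the star spans the positions pairing with
#' the mature, shifted for the Dicer-type 2-nt 3' overhangs) and walks the
#' pairing table to count paired bases, mismatches and bulges. A mismatch is
#' a symmetric unpaired position facing the star arm; an asymmetric bulge is
#' the surplus of unpaired bases on one side of an internal loop, and the
#' asymmetry reported is the largest such surplus.
#'
#' @param structure a `secondary_structure` (see [fold()]).
#' @param mature_start,mature_end 1-based inclusive mature coordinates on the
#'   precursor.
#' @return a `duplex_metrics` list: `valid`, `reason`, `paired_bases`,
#'   `mismatches`, `bulge_sizes`, `n_asymmetric_bulges`, `asymmetry`,
#'   `overhang_3p_mature`, `overhang_3p_star`, `star_start`, `star_end`,
#'   `star_seq`, `mature_star_span`, `arm` ("5p"/"3p").
#' @export
evaluate_duplex <- function(structure, mature_start, mature_end) {
  stopifnot(inherits(structure, "secondary_structure"))
  n <- nchar(structure$dot_bracket)
  m1 <- as.integer(mature_start); m2 <- as.integer(mature_end)
  if (m1 < 1 || m2 > n || m1 >= m2) {
    return(duplex_reject("mature coordinates outside precursor"))
  }
  pt <- pair_table(structure$dot_bracket)
  partners <- pt[m1:m2]
  paired_idx <- which(partners > 0)
  if (length(paired_idx) == 0) return(duplex_reject("mature entirely unpaired"))
  part <- partners[paired_idx]
  # mature must lie on a single arm: all partners on the same side, outside it
  if (any(part >= m1 & part <= m2)) {
    return(duplex_reject("loop-spanning (mature pairs within itself)"))
  }
  if (any(part > m2) && any(part < m1)) return(duplex_reject("loop-spanning"))
  arm <- if (all(part > m2)) "5p" else "3p"

  pos <- m1:m2
  ip <- pos[paired_idx]              # absolute paired mature positions
  i1 <- ip[1]; iK <- ip[length(ip)]  # first/last paired mature base

  # Canonical star span: partner of (mature_end - 2) .. partner of mature_start,
  # extended by the 2-nt 3' overhang; unpaired anchors are projected from the
  # nearest paired mature base (pairing runs anti-diagonally).
  anchor_hi <- max(ip[ip <= m2 - 2L], i1)   # proxy for mature_end - 2
  star_start <- pt[anchor_hi] - ((m2 - 2L) - anchor_hi)
  star_end   <- pt[i1] + (i1 - m1) + 2L
  star_start <- max(1L, min(n, star_start))
  star_end   <- max(1L, min(n, star_end))
  if (star_start > star_end) return(duplex_reject("degenerate star span"))
  star_seq <- substr(structure$sequence, star_start, star_end)

  # Walk consecutive paired mature bases and classify the gaps between them.
  mismatches <- 0L
  bulge_sizes <- integer(0)
  if (length(ip) > 1) {
    for (k in seq_len(length(ip) - 1L)) {
      a <- ip[k + 1L] - ip[k] - 1L            # unpaired on mature side
      b <- abs(pt[ip[k]] - pt[ip[k + 1L]]) - 1L  # unpaired on star side
      mismatches <- mismatches + min(a, b)
      if (a != b) bulge_sizes <- c(bulge_sizes, abs(a - b))
    }
  }
  # Unpaired mature bases before the first / after the last paired base,
  # excluding the 2-nt 3' overhang, count as mismatched mature bases.
  mismatches <- mismatches + (i1 - m1) + max(0L, (m2 - 2L) - iK)

  span <- if (arm == "5p") star_start - m2 - 1L else m1 - star_end - 1L

  structure(list(
    valid = TRUE, reason = NA_character_,
    arm = arm,
    paired_bases = length(ip),
    mismatches = as.integer(mismatches),
    bulge_sizes = bulge_sizes,
    n_asymmetric_bulges = length(bulge_sizes),
    asymmetry = if (length(bulge_sizes)) max(bulge_sizes) else 0L,
    overhang_3p_mature = m2 - iK,
    overhang_3p_star = star_end - pt[i1],
    star_start = star_start, star_end = star_end, star_seq = star_seq,
    mature_star_span = max(span, 0L)
  ), class = "duplex_metrics")
}

duplex_reject <- function(reason) {
  structure(list(valid = FALSE, reason = reason), class = "duplex_metrics")
}

#' Apply the precursor/duplex thresholds to one candidate
#'
#' @param mature_len mature sequence length (nt).
#' @param structure folded precursor (`secondary_structure`).
#' @param duplex `duplex_metrics` from [evaluate_duplex()].
#' @param star_detected logical; relaxes the mismatch cap from 4 to 5.
#' @param params threshold list, see [mireap_params()].
#' @return list with `pass` (logical) and `reasons` (character vector of every
#'   violated criterion; empty when passing).
#' @export
apply_mireap_criteria <- function(mature_len, structure, duplex,
                                  star_detected = FALSE,
                                  params = mireap_params()) {
  reasons <- character(0)
  if (!isTRUE(duplex$valid)) {
    return(list(pass = FALSE, reasons = paste0("duplex: ", duplex$reason)))
  }
  if (mature_len < params$min_mature_len || mature_len > params$max_mature_len) {
    reasons <- c(reasons, sprintf("mature length outside [%d,%d]",
                                  params$min_mature_len, params$max_mature_len))
  }
  if (structure$mfe > params$max_mfe) {
    reasons <- c(reasons, sprintf("free energy > %g kcal/mol", params$max_mfe))
  }
  if (duplex$paired_bases < params$min_paired) {
    reasons <- c(reasons, sprintf("min base pairs (%d)", params$min_paired))
  }
  if (length(duplex$bulge_sizes) && max(duplex$bulge_sizes) > params$max_bulge) {
    reasons <- c(reasons, sprintf("bulge > %d nt", params$max_bulge))
  }
  if (duplex$n_asymmetric_bulges > params$max_asym_bulges) {
    reasons <- c(reasons, sprintf("more than %d asymmetric bulges",
                                  params$max_asym_bulges))
  }
  if (duplex$asymmetry > params$max_asymmetry) {
    reasons <- c(reasons, sprintf("asymmetry > %d", params$max_asymmetry))
  }
  if (duplex$mature_star_span > params$max_arm_span) {
    reasons <- c(reasons, sprintf("arm span > %d nt", params$max_arm_span))
  }
  max_mm <- if (star_detected) params$max_mismatch_star else params$max_mismatch
  if (duplex$mismatches > max_mm) {
    reasons <- c(reasons, sprintf("mismatches > %d", max_mm))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Candidate precursor windows around a genome hit
#'
#' Extracts genomic windows that could contain the precursor, placing the
#' mature read on either arm with a range of spacer extents up to the maximal
#' arm span, plus fixed flanks. Windows are clipped at contig ends. Reads
#' hitting more than the copy-number cap are excluded.
#'
#' @param hit one-row data.frame with `contig`, `start`, `end` (1-based
#'   inclusive), `strand`, `n_loci` (as produced by [match_genome()]).
#' @param genome named `DNAStringSet` (or named character vector) of contigs.
#' @param params threshold list, see [mireap_params()].
#' @param extents candidate spacer extents (nt beyond the mature on the loop
#'   side); defaults cover spacings up to the maximal arm span.
#' @return data.frame of windows: `win_start`, `win_end` (contig, 1-based),
#'   `sequence` (strand-adjusted, 5'->3'), `mature_offset` (1-based on the
#'   window), `arm_side`, `clipped`; zero rows (with attribute `reason`)
#'   when the hit is excluded.
#' @export
extract_precursor_windows <- function(hit, genome, params = mireap_params(),
                                      extents = c(38L, 45L, 52L, 60L, 70L, 85L,
                                                  100L, 150L, 220L, 320L)) {
  genome <- as_genome_set(genome)
  empty <- data.frame(win_start = integer(0), win_end = integer(0),
                      sequence = character(0), mature_offset = integer(0),
                      arm_side = character(0), clipped = logical(0))
  if (hit$n_loci > params$max_copy_number) {
    attr(empty, "reason") <- sprintf("copy number > %d", params$max_copy_number)
    return(empty)
  }
  contig <- genome[[as.character(hit$contig)]]
  clen <- nchar(contig)
  read_len <- hit$end - hit$start + 1L
  extents <- as.integer(pmin(extents, params$max_arm_span + read_len))
  fl <- params$flank
  rows <- list()
  for (ext in unique(extents)) {
    for (side in c("mature_5p", "mature_3p")) {
      if (side == "mature_5p") {      # spacer + star downstream of the mature
        ws <- hit$start - fl; we <- hit$end + ext + fl
      } else {
        ws <- hit$start - ext - fl; we <- hit$end + fl
      }
      clipped <- ws < 1 || we > clen
      ws <- max(1L, ws); we <- min(clen, we)
      seq_fwd <- substr(contig, ws, we)
      if (hit$strand == "+") {
        sequence <- seq_fwd
        offset <- hit$start - ws + 1L
      } else {
        sequence <- revcomp(seq_fwd)
        offset <- we - hit$end + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        win_start = ws, win_end = we, sequence = sequence,
        mature_offset = offset, arm_side = side, clipped = clipped)
    }
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$sequence), , drop = FALSE]
}

#' Partition precursor-mapped reads for the locus-read rule
#'
#' Computes the fraction of precursor-mapped (redundant) reads that fall on
#' the mature/star arms and the fraction of the arm reads that exactly match
#' the mature sequence.
#'
#' @param precursor precursor sequence (character scalar).
#' @param mature_seq mature sequence.
#' @param star_span integer length-2 vector (start, end) of the star on the
#'   precursor, or NULL if unknown.
#' @param reads character vector of read sequences mapped to this precursor.
#' @param counts integer vector of redundant counts (same length as `reads`).
#' @param params threshold list.
#' @return list: `precursor_mapped`, `arm_reads`, `reliable_reads`,
#'   `frac_arm`, `frac_reliable`, `pass`, `reason`.
#' @export
partition_locus_reads <- function(precursor, mature_seq, star_span, reads, counts,
                                  params = mireap_params()) {
  stopifnot(length(reads) == length(counts))
  precursor <- as_rna(precursor); mature_seq <- as_rna(mature_seq)
  reads <- as_rna(reads)
  keep <- vapply(reads, function(r) grepl(r, precursor, fixed = TRUE), logical(1))
  reads <- reads[keep]; counts <- counts[keep]
  total <- sum(counts)
  if (total == 0) {
    return(list(precursor_mapped = 0L, arm_reads = 0L, reliable_reads = 0L,
                frac_arm = NA_real_, frac_reliable = NA_real_,
                pass = FALSE, reason = "no precursor-mapped reads"))
  }
  mstart <- regexpr(mature_seq, precursor, fixed = TRUE)[1]
  mspan <- c(mstart, mstart + nchar(mature_seq) - 1L)
  on_arm <- function(r) {
    p <- regexpr(r, precursor, fixed = TRUE)[1]
    s <- c(p, p + nchar(r) - 1L)
    overlaps <- function(a, b) s[1] <= b && s[2] >= a
    hit <- overlaps(mspan[1], mspan[2])
    if (!hit && !is.null(star_span)) hit <- overlaps(star_span[1], star_span[2])
    hit
  }
  arm <- vapply(reads, on_arm, logical(1))
  arm_reads <- sum(counts[arm])
  reliable <- sum(counts[reads == mature_seq])
  frac_arm <- arm_reads / total
  frac_reliable <- if (arm_reads > 0) reliable / arm_reads else 0
  pass <- frac_arm > params$min_frac_locus && frac_reliable > params$min_frac_reliable
  reason <- if (pass) NA_character_ else {
    paste(c(
      if (!(frac_arm > params$min_frac_locus))
        sprintf("arm fraction %.3f not > %.2f", frac_arm, params$min_frac_locus),
      if (!(frac_reliable > params$min_frac_reliable))
        sprintf("reliable fraction %.3f not > %.2f", frac_reliable,
                params$min_frac_reliable)), collapse = "; ")
  }
  list(precursor_mapped = total, arm_reads = arm_reads, reliable_reads = reliable,
       frac_arm = frac_arm, frac_reliable = frac_reliable,
       pass = pass, reason = reason)
}

#' Final status call for one candidate miRNA locus
#'
#' @param criteria result of [apply_mireap_criteria()].
#' @param locus_stats result of [partition_locus_reads()].
#' @param rpm numeric vector of per-tissue RPM for the mature sequence.
#' @param star_detected logical, star read observed in any library.
#' @param params threshold list.
#' @return list with `status` ("novel", "candidate" or "rejected"),
#'   `reasons`, `max_rpm`.
#' @export
classify_mirna <- function(criteria, locus_stats, rpm, star_detected,
                           params = mireap_params()) {
  reasons <- character(0)
  if (!criteria$pass) reasons <- c(reasons, criteria$reasons)
  if (!locus_stats$pass) reasons <- c(reasons, locus_stats$reason)
  max_rpm <- if (length(rpm)) max(rpm) else 0
  if (max_rpm < params$min_rpm) {
    reasons <- c(reasons, sprintf("abundance < %g RPM", params$min_rpm))
  }
  status <- if (length(reasons)) "rejected" else if (star_detected) "novel" else "candidate"
  list(status = status, reasons = reasons, max_rpm = max_rpm)
}

# Coerce genome to a plain named character vector of contigs
as_genome_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
  } else {
    out <- genome
  }
  if (length(out) == 0) return(character(0))
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("genome contigs must be named", call. = FALSE)
  }
  out
}
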