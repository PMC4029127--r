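# End-to-end novel-miRNA discovery over a unique-read table: genome hits,
# precursor windows, batched folding, duplex criteria, star detection and
# locus read partitioning. The final novel/candidate call is made once RPM
# denominators are known (see classify_mirna and run_pipeline).

#' Discover candidate miRNA loci from unique reads
#'
#' Considers unique reads of mature length (20-23 nt) not already assigned to
#' known miRNAs, folds candidate precursor windows around each genomic locus
#' and keeps, per read, the best window passing the structural criteria
#' (lowest MFE, then shortest precursor). Loci are deduplicated: a read whose
#' genomic position falls inside an already-accepted precursor (an isomiR or
#' the star of that locus) is absorbed by it; reads are processed in
#' decreasing redundant count, so the dominant arm becomes the mature.
#'
#' @param unique_table unique-read table from [collapse_unique()] (already
#'   genome-matched and ncRNA-filtered).
#' @param genome named contigs (character vector or `DNAStringSet`).
#' @param known_sequences sequences already assigned to known miRNAs
#'   (excluded from discovery).
#' @param params thresholds, see [mireap_params()].
#' @param genome_hits optional precomputed [match_genome()] result for the
#'   candidate sequences.
#' @return list with `loci` (one row per tested locus: coordinates, duplex
#'   metrics, star evidence, read-partition fractions, `structural_pass`,
#'   `reasons`, per-library mature counts in `count_<library>` columns) and
#'   `precursors` (named list of `secondary_structure`).
#' @export
discover_mirnas <- function(unique_table, genome, known_sequences = character(0),
                            params = mireap_params(), genome_hits = NULL) {
  libs <- setdiff(names(unique_table), c("sequence", "total_count"))
  lens <- nchar(unique_table$sequence)
  cand <- unique_table[lens >= params$min_mature_len &
                         lens <= params$max_mature_len &
                         !(as_dna(unique_table$sequence) %in% as_dna(known_sequences)), ,
                       drop = FALSE]
  cand <- cand[order(-cand$total_count, cand$sequence), , drop = FALSE]
  genome <- as_genome_set(genome)
  if (is.null(genome_hits)) genome_hits <- match_genome(cand$sequence, genome)
  hits <- genome_hits$hits

  all_seqs <- as_rna(unique_table$sequence)
  loci_rows <- list()
  precursors <- list()
  accepted <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0))
  n_locus <- 0L

  for (r in seq_len(nrow(cand))) {
    seq_r <- cand$sequence[r]
    len_r <- nchar(seq_r)
    h_r <- hits[hits$sequence == seq_r, , drop = FALSE]
    if (nrow(h_r) == 0) next
    for (hi in seq_len(nrow(h_r))) {
      hit <- h_r[hi, ]
      # absorbed by an already-accepted locus?
      inside <- accepted$contig == hit$contig &
        hit$start <= accepted$end & hit$end >= accepted$start
      if (any(inside)) next
      windows <- extract_precursor_windows(hit, genome, params)
      if (nrow(windows) == 0) {
        loci_rows[[length(loci_rows) + 1L]] <- locus_row(
          seq_r, hit, pass = FALSE,
          reasons = attr(windows, "reason") %||% "no windows")
        next
      }
      sts <- fold_many(windows$sequence)
      best <- NULL
      for (w in seq_len(nrow(windows))) {
        st <- sts[[w]]
        dm <- evaluate_duplex(st, windows$mature_offset[w],
                              windows$mature_offset[w] + len_r - 1L)
        crit <- apply_mireap_criteria(len_r, st, dm, star_detected = TRUE,
                                      params = params)
        if (!crit$pass) next
        if (is.null(best) || st$mfe < best$st$mfe - 1e-9 ||
            (abs(st$mfe - best$st$mfe) < 1e-9 &&
             nchar(st$sequence) < nchar(best$st$sequence))) {
          best <- list(st = st, dm = dm, w = w)
        }
      }
      if (is.null(best)) {
        loci_rows[[length(loci_rows) + 1L]] <- locus_row(
          seq_r, hit, pass = FALSE, reasons = "no qualifying hairpin window")
        next
      }
      st <- best$st; dm <- best$dm; w <- best$w
      precursor <- st$sequence
      star_span <- c(dm$star_start, dm$star_end)

      # star evidence: any unique read whose 5' end sits within the tolerance
      # of the predicted star 5' end
      occ <- vapply(all_seqs, function(s) {
        regexpr(s, precursor, fixed = TRUE)[1]
      }, integer(1), USE.NAMES = FALSE)
      mature_off <- windows$mature_offset[w]
      star_reads <- which(occ > 0 &
                            abs(occ - dm$star_start) <= params$star_tolerance &
                            occ != mature_off)
      star_detected <- length(star_reads) > 0

      crit <- apply_mireap_criteria(len_r, st, dm,
                                    star_detected = star_detected,
                                    params = params)
      on_prec <- which(occ > 0)
      stats <- partition_locus_reads(
        precursor, seq_r, star_span,
        unique_table$sequence[on_prec], unique_table$total_count[on_prec],
        params = params)
      pass <- crit$pass && stats$pass
      reasons <- c(crit$reasons, if (!stats$pass) stats$reason)

      n_locus <- n_locus + 1L
      name <- sprintf("locus-m%03d", n_locus)
      counts <- as.integer(unique_table[match(seq_r, unique_table$sequence), libs])
      row <- locus_row(seq_r, hit, pass = pass,
                       reasons = paste(reasons, collapse = "; "))
      row$name <- name
      row$precursor_start <- windows$win_start[w]
      row$precursor_end <- windows$win_end[w]
      row$arm <- dm$arm
      row$mfe <- st$mfe
      row$paired_bases <- dm$paired_bases
      row$mismatches <- dm$mismatches
      row$star_detected <- star_detected
      row$star_seq <- dm$star_seq
      row$frac_arm <- stats$frac_arm
      row$frac_reliable <- stats$frac_reliable
      for (j in seq_along(libs)) row[[paste0("count_", libs[j])]] <- counts[j]
      loci_rows[[length(loci_rows) + 1L]] <- row
      precursors[[name]] <- st
      if (pass) {
        accepted <- rbind(accepted, data.frame(
          contig = hit$contig, start = windows$win_start[w],
          end = windows$win_end[w]))
      }
    }
  }
  loci <- rbind_fill(loci_rows)
  list(loci = loci, precursors = precursors)
}

locus_row <- function(seq_r, hit, pass, reasons) {
  data.frame(name = NA_character_, mature_seq = as_rna(seq_r),
             contig = hit$contig, mature_start = hit$start,
             mature_end = hit$end, strand = hit$strand,
             n_loci = hit$n_loci,
             structural_pass = pass,
             reasons = if (length(reasons) && nzchar(reasons[1])) reasons else "",
             stringsAsFactors = FALSE)
}

rbind_fill <- function(rows) {
  if (length(rows) == 0) {
    return(data.frame(name = character(0), mature_seq = character(0),
                      structural_pass = logical(0)))
  }
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
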