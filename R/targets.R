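# miRNA target prediction: complementarity expectation scoring over a 20-nt
# window, transcript scanning, site-accessibility (UPE) filtering and the
# cleavage/translation inhibition-mode call.

#' Target-scoring parameters
#'
#' Penalty weights follow the established plant target-scoring scheme
#' (psRNATarget-style): mismatch 1.0, G:U wobble 0.5, gap 2.0, each doubled
#' in the 5' seed-proximal core (miRNA positions 2-13); at most 20 miRNA
#' positions are scored. Thresholds: expectation at most 3, site unpairing
#' energy (UPE) at most 25 kcal/mol with 17-nt upstream / 13-nt downstream
#' accessibility flanks, central mismatches at miRNA positions 9-11 mark
#' translational inhibition.
#'
#' @return named list of weights and thresholds.
#' @export
target_params <- function() {
  list(mismatch = 1.0, wobble = 0.5, gap = 2.0,
       core_start = 2L, core_end = 13L, core_factor = 2,
       score_window = 20L,
       max_expectation = 3, max_upe = 25,
       flank_up = 17L, flank_down = 13L,
       central_start = 9L, central_end = 11L,
       max_gaps = 1L)
}

#' Score a miRNA against one candidate target site
#'
#' The miRNA (5'->3') is aligned anti-parallel to the site (the site is
#' given 5'->3' in transcript orientation; its 3' end pairs the miRNA 5'
#' end). Alignments with up to `max_gaps` gaps on either strand are
#' enumerated and the lowest-expectation one returned; ties prefer fewer
#' gaps, then the leftmost (5'-most on the miRNA) gap.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site sequence, transcript 5'->3'; length within
#'   `max_gaps` of the miRNA length.
#' @param params scoring parameters, see [target_params()].
#' @return list: `expectation`, `alignment` (3 strings: miRNA 5'->3', match
#'   line with `|` pair / `o` wobble / space mismatch, site 3'->5'),
#'   `penalty_positions` (miRNA positions of mismatches/gaps, excluding
#'   wobbles), `n_gaps`.
#' @export
score_duplex <- function(mirna, site, params = target_params()) {
  check_nucleotides(mirna, "miRNA"); check_nucleotides(site, "site")
  m <- chars(as_rna(mirna))
  s <- rev(chars(as_rna(site)))   # site 3'->5', aligned to miRNA 5'->3'
  lm <- length(m); ls <- length(s)
  if (abs(lm - ls) > max(params$max_gaps, 2L)) {
    stop("site length must be within the gap budget of the miRNA length",
         call. = FALSE)
  }
  best <- NULL
  gap_layouts <- enumerate_gap_layouts(lm, ls, params$max_gaps)
  for (lay in gap_layouts) {
    sc <- score_layout(m, s, lay, params)
    if (is.null(sc)) next
    if (is.null(best) ||
        sc$expectation < best$expectation - 1e-9 ||
        (abs(sc$expectation - best$expectation) < 1e-9 &&
         (sc$n_gaps < best$n_gaps ||
          (sc$n_gaps == best$n_gaps && sc$gap_pos < best$gap_pos)))) {
      best <- sc
    }
  }
  best[c("expectation", "alignment", "penalty_positions", "n_gaps")]
}

# Gap layouts: 0 = aligned column; "m" = gap in the site (miRNA base bulged),
# "s" = gap in the miRNA (site base bulged). With a budget of `max_gaps` the
# length difference dictates which side the gap sits on.
enumerate_gap_layouts <- function(lm, ls, max_gaps) {
  if (lm == ls) {
    lays <- list(list(type = "none", pos = 0L))
    if (max_gaps >= 2) {
      # one gap on each side is possible but never optimal under these
      # weights; omitted for tractability
    }
    return(lays)
  }
  d <- lm - ls
  if (abs(d) > max_gaps) return(list())
  side <- if (d > 0) "m" else "s"   # site shorter: miRNA base bulged
  lapply(seq_len(min(lm, ls) + 1L) - 1L,
         function(p) list(type = side, pos = p))
}

score_layout <- function(m, s, lay, params) {
  # build aligned columns as index vectors (0 = gap)
  lm <- length(m); ls <- length(s)
  if (lay$type == "none") {
    mi <- seq_len(lm); si <- seq_len(ls)
  } else if (lay$type == "m") {      # miRNA base at pos+1 is bulged
    p <- lay$pos
    if (p > ls) return(NULL)
    mi <- seq_len(lm)
    si <- append(seq_len(ls), 0L, after = p)
    if (length(si) != lm) return(NULL)
  } else {                            # site base bulged after miRNA pos `pos`
    p <- lay$pos
    if (p > lm) return(NULL)
    si <- seq_len(ls)
    mi <- append(seq_len(lm), 0L, after = p)
    if (length(mi) != ls) return(NULL)
  }
  ncol <- length(mi)
  expectation <- 0
  match_line <- character(ncol)
  penalty_pos <- integer(0)
  n_gaps <- 0L
  gap_pos <- Inf
  mpos <- 0L   # running miRNA position (1-based from 5')
  for (k in seq_len(ncol)) {
    if (mi[k] > 0) mpos <- mi[k]
    scored_pos <- if (mi[k] > 0) mi[k] else mpos  # gap charged at adjacent position
    is_gap <- mi[k] == 0 || si[k] == 0
    if (is_gap) {                      # gaps count even beyond the window
      n_gaps <- n_gaps + 1L
      gap_pos <- min(gap_pos, scored_pos)
    }
    if (scored_pos > params$score_window) {
      match_line[k] <- if (is_gap) "-" else " "
      next
    }
    w <- if (scored_pos >= params$core_start && scored_pos <= params$core_end)
      params$core_factor else 1
    if (is_gap) {
      expectation <- expectation + w * params$gap
      match_line[k] <- "-"
      penalty_pos <- c(penalty_pos, scored_pos)
    } else {
      a <- m[mi[k]]; b <- s[si[k]]
      if (pairs_wc(a, b)) {
        match_line[k] <- "|"
      } else if (pairs_wobble(a, b)) {
        expectation <- expectation + w * params$wobble
        match_line[k] <- "o"
      } else {
        expectation <- expectation + w * params$mismatch
        match_line[k] <- " "
        penalty_pos <- c(penalty_pos, scored_pos)
      }
    }
  }
  mline <- vapply(seq_len(ncol), function(k) {
    if (mi[k] == 0) "-" else m[mi[k]]
  }, character(1))
  sline <- vapply(seq_len(ncol), function(k) {
    if (si[k] == 0) "-" else s[si[k]]
  }, character(1))
  list(expectation = expectation,
       alignment = c(mirna = paste(mline, collapse = ""),
                     match = paste(match_line, collapse = ""),
                     site = paste(sline, collapse = "")),
       penalty_positions = sort(unique(penalty_pos)),
       n_gaps = n_gaps, gap_pos = gap_pos)
}

#' Scan transcripts for target sites of one miRNA
#'
#' Every site with expectation at most `max_expectation` is reported;
#' overlapping sites of the same miRNA/transcript pair are deduplicated,
#' keeping the best (lowest expectation, then leftmost). A fast
#' complementarity prefilter restricts full scoring to plausible positions.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences; must be non-empty.
#' @param max_expectation expectation cut-off (3).
#' @param params scoring parameters.
#' @return data.frame of hits: `mirna`, `transcript`, `start`, `end` (1-based
#'   inclusive site span), `expectation`, `mode`, plus alignment strings
#'   `aln_mirna`, `aln_match`, `aln_site`.
#' @export
scan_transcripts <- function(mirna, transcripts, max_expectation = 3,
                             params = target_params()) {
  if (inherits(transcripts, "DNAStringSet")) transcripts <- as.character(transcripts)
  if (length(transcripts) == 0) stop("transcripts must be non-empty", call. = FALSE)
  if (is.null(names(transcripts))) {
    names(transcripts) <- sprintf("tx_%03d", seq_along(transcripts))
  }
  mirna_rna <- as_rna(mirna)
  L <- nchar(mirna_rna)
  hits <- list()
  for (tx in names(transcripts)) {
    seq_rna <- as_rna(transcripts[[tx]])
    Tn <- nchar(seq_rna)
    if (Tn < L - 1L) next
    cand <- prefilter_positions(mirna_rna, seq_rna, params)
    tx_hits <- list()
    for (s0 in cand) {
      for (site_len in (L - params$max_gaps):(L + params$max_gaps)) {
        e0 <- s0 + site_len - 1L
        if (e0 > Tn) next
        site <- substr(seq_rna, s0, e0)
        sc <- tryCatch(score_duplex(mirna_rna, site, params),
                       error = function(e) NULL)
        if (is.null(sc) || is.null(sc$expectation)) next
        if (sc$expectation > max_expectation + 1e-9) next
        tx_hits[[length(tx_hits) + 1L]] <- data.frame(
          mirna = mirna, transcript = tx, start = s0, end = e0,
          expectation = sc$expectation, n_gaps = sc$n_gaps,
          mode = inhibition_mode(sc, params),
          aln_mirna = sc$alignment[["mirna"]],
          aln_match = sc$alignment[["match"]],
          aln_site = sc$alignment[["site"]])
      }
    }
    if (length(tx_hits)) {
      h <- do.call(rbind, tx_hits)
      # best first: lowest expectation, then gap-free, then leftmost/shortest
      h <- h[order(h$expectation, h$n_gaps, h$start, h$end - h$start), ,
             drop = FALSE]
      kept <- h[0, ]
      for (r in seq_len(nrow(h))) {
        overlap <- nrow(kept) > 0 &&
          any(h$start[r] <= kept$end & h$end[r] >= kept$start)
        if (!overlap) kept <- rbind(kept, h[r, ])
      }
      hits[[length(hits) + 1L]] <- kept
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), end = integer(0), expectation = numeric(0),
               n_gaps = integer(0), mode = character(0),
               aln_mirna = character(0), aln_match = character(0),
               aln_site = character(0))
  rownames(out) <- NULL
  out[order(out$transcript, out$start), , drop = FALSE]
}

# Candidate site start positions: enough complementary bases in at least one
# of the -1/0/+1 registers. Wobbles count as non-matching here, so the bound
# is conservative for any site under the default expectation threshold.
prefilter_positions <- function(mirna, transcript, params) {
  m <- rev(chars(mirna))            # transcript 5'->3' pairs reversed miRNA
  tchars <- chars(transcript)
  Tn <- length(tchars); L <- length(m)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  want <- unname(comp[m])           # transcript base complementary at each offset
  max_bad <- 6L + params$max_gaps
  ok <- rep(FALSE, Tn - L + 1L + params$max_gaps)
  for (shift in -params$max_gaps:params$max_gaps) {
    n_start <- Tn - L + 1L - shift
    if (n_start < 1) next
    good <- integer(n_start)
    for (j in seq_len(L)) {
      idx <- (seq_len(n_start)) + shift + j - 1L
      valid <- idx >= 1 & idx <= Tn
      g <- rep(FALSE, n_start)
      g[valid] <- tchars[idx[valid]] == want[j]
      good <- good + g
    }
    sel <- which(L - good <= max_bad)
    sel <- sel[sel >= 1 & sel <= length(ok)]
    ok[sel] <- TRUE
  }
  which(ok)
}

#' Energy to unpair a target site (UPE)
#'
#' Folds the site plus accessibility flanks freely and with the site forced
#' unpaired; UPE is the energy difference (kcal/mol, never negative). When
#' folding fails the hit is retained with UPE missing and a warning.
#'
#' @param transcript transcript sequence.
#' @param site_start,site_end 1-based inclusive site span on the transcript.
#' @param flank_up,flank_down flanks (17 nt upstream, 13 nt downstream),
#'   clipped at transcript ends.
#' @return numeric UPE (kcal/mol) or NA on folding failure.
#' @export
upe <- function(transcript, site_start, site_end,
                flank_up = 17L, flank_down = 13L) {
  Tn <- nchar(transcript)
  stopifnot(site_start >= 1, site_end <= Tn, site_start <= site_end)
  ws <- max(1L, site_start - flank_up)
  we <- min(Tn, site_end + flank_down)
  window <- substr(transcript, ws, we)
  cons <- chars(strrep(".", nchar(window)))
  cons[(site_start - ws + 1L):(site_end - ws + 1L)] <- "x"
  res <- tryCatch({
    free <- fold(window)
    constrained <- fold(window, constraint = paste(cons, collapse = ""))
    max(0, constrained$mfe - free$mfe)
  }, error = function(e) {
    warning("folding failed for UPE; accessibility filter skipped: ",
            conditionMessage(e))
    NA_real_
  })
  res
}

#' Inhibition mode of a scored duplex
#'
#' Translational inhibition iff the alignment has a mismatch or gap at any of
#' the central miRNA positions (9-11 by default); otherwise cleavage.
#' Wobble pairs do not count as mismatches.
#'
#' @param scored result of [score_duplex()].
#' @param params scoring parameters.
#' @return "translation" or "cleavage".
#' @export
inhibition_mode <- function(scored, params = target_params()) {
  central <- params$central_start:params$central_end
  if (any(scored$penalty_positions %in% central)) "translation" else "cleavage"
}

#' Predict targets for a set of miRNAs with the accessibility filter
#'
#' Runs [scan_transcripts()] per miRNA and applies the UPE filter.
#'
#' @param mirnas named character vector of mature sequences.
#' @param transcripts named character vector of transcripts.
#' @param params scoring parameters.
#' @return data.frame of retained hits with an extra `upe` column.
#' @export
predict_targets <- function(mirnas, transcripts, params = target_params()) {
  if (is.null(names(mirnas))) names(mirnas) <- sprintf("mir_%03d", seq_along(mirnas))
  out <- list()
  for (id in names(mirnas)) {
    h <- scan_transcripts(mirnas[[id]], transcripts,
                          max_expectation = params$max_expectation,
                          params = params)
    if (nrow(h) == 0) next
    h$mirna <- id
    h$upe <- vapply(seq_len(nrow(h)), function(r) {
      upe(transcripts[[h$transcript[r]]], h$start[r], h$end[r],
          params$flank_up, params$flank_down)
    }, numeric(1))
    h <- h[is.na(h$upe) | h$upe <= params$max_upe, , drop = FALSE]
    out[[id]] <- h
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(0), transcript = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0), n_gaps = integer(0),
                      mode = character(0), aln_mirna = character(0),
                      aln_match = character(0), aln_site = character(0),
                      upe = numeric(0)))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  rownames(res) <- NULL
  res
}
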