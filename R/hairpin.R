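# Construction of synthetic MIRNA hairpin precursors with a planned
# miRNA/miRNA* duplex geometry. Construction is validated by round-tripping
# through fold() + evaluate_duplex(): a candidate is only accepted when the
# folded structure reproduces the planned pair/mismatch/bulge counts, so the
# returned geometry is a certificate, not an intention.

#' Plan a miRNA/miRNA* duplex
#'
#' @param mismatches number of mismatched mature bases (star side carries a
#'   non-pairing base opposite them).
#' @param bulges integer vector of bulge sizes (nt) inserted on the star arm;
#'   each bulge is asymmetric with asymmetry equal to its size.
#' @return a validated plan list.
#' @export
duplex_plan <- function(mismatches = 0L, bulges = integer(0)) {
  plan <- list(mismatches = as.integer(mismatches), bulges = as.integer(bulges))
  if (plan$mismatches < 0 || any(plan$bulges < 1)) {
    stop("invalid duplex plan: negative mismatches or empty bulges", call. = FALSE)
  }
  if (length(plan$bulges) > 2) {
    stop("infeasible duplex plan: more than 2 asymmetric bulges", call. = FALSE)
  }
  if (any(plan$bulges > 2)) {
    stop("infeasible duplex plan: bulge larger than 2 nt", call. = FALSE)
  }
  plan
}

#' Construct a hairpin precursor with a planned duplex
#'
#' Builds `flank(20) - mature - loop - star - flank(20)` (5p arm) or the
#' mirrored layout (3p arm). The star is the reverse complement of the mature
#' paired region with planned mismatch substitutions and star-side bulge
#' insertions, positioned for canonical 2-nt 3' overhangs. The candidate is
#' folded and accepted only if the observed duplex metrics equal the plan and
#' pass the default precursor thresholds; otherwise new random sequences are
#' drawn. The number of planned pairs, `mature_len - 2 - mismatches`, must be
#' at least 16.
#'
#' @param mature_len mature length, 20-23 nt.
#' @param plan a [duplex_plan()].
#' @param arm "5p" or "3p": which arm carries the mature miRNA.
#' @param loop_len unpaired spacer between the arms (>= 3 nt; the terminal
#'   loop additionally contains the 2-nt overhang bases).
#' @param flank flanking sequence length (20 nt by default).
#' @param max_tries rejection-sampling budget before giving up.
#' @return a `planted_hairpin` list: `precursor`, `mature_seq`, `star_seq`,
#'   `mature_start`, `mature_end`, `star_start`, `star_end` (1-based on the
#'   precursor), `arm`, `structure`, `duplex`, `plan`.
#' @export
make_hairpin <- function(mature_len, plan = duplex_plan(), arm = c("5p", "3p"),
                         loop_len = 8L, flank = 20L, max_tries = 80L) {
  arm <- match.arg(arm)
  mature_len <- as.integer(mature_len)
  if (mature_len < 20L || mature_len > 23L) {
    stop("mature_len must be within [20, 23]", call. = FALSE)
  }
  if (loop_len < 3L) stop("loop_len must be >= 3", call. = FALSE)
  planned_pairs <- mature_len - 2L - plan$mismatches
  if (planned_pairs < 16L) {
    stop("infeasible duplex plan: fewer than 16 planned base pairs", call. = FALSE)
  }
  params <- mireap_params()
  for (try in seq_len(max_tries)) {
    cand <- build_hairpin_candidate(mature_len, plan, arm, loop_len, flank)
    st <- fold(cand$precursor)
    dm <- evaluate_duplex(st, cand$mature_start, cand$mature_end)
    if (!isTRUE(dm$valid)) next
    ok <- dm$paired_bases == planned_pairs &&
      dm$mismatches == plan$mismatches &&
      identical(sort(dm$bulge_sizes), sort(plan$bulges)) &&
      dm$star_start == cand$star_start &&
      dm$star_end == cand$star_end &&
      st$mfe <= params$max_mfe
    if (!ok) next
    crit <- apply_mireap_criteria(mature_len, st, dm,
                                  star_detected = TRUE, params = params)
    if (!crit$pass) next
    return(structure(c(cand, list(structure = st, duplex = dm, plan = plan)),
                     class = "planted_hairpin"))
  }
  stop("could not realise the requested duplex plan in ", max_tries,
       " attempts; the plan may be infeasible", call. = FALSE)
}

# One random candidate realisation of the plan (not yet validated).
build_hairpin_candidate <- function(mature_len, plan, arm, loop_len, flank) {
  L <- mature_len
  # GC-leaning mature keeps the planned stem the dominant fold; the first
  # base leans U, as mature plant miRNAs predominantly start with uridine
  mature <- paste0(sample(RNA_BASES, 1, prob = c(0.15, 0.15, 0.15, 0.55)),
                   random_seq(L - 1L, RNA_BASES, prob = c(0.20, 0.30, 0.30, 0.20)))
  core_len <- L - 2L
  core_m <- substr(mature, 1L, core_len)   # paired region of the mature
  star_core <- chars(revcomp(core_m))      # star_core[i] pairs mature[core_len - i + 1]
  # mismatches: put the same base opposite the mature base (no WC, no wobble)
  if (plan$mismatches > 0) {
    if (core_len - 8L < plan$mismatches) stop("too many mismatches requested")
    mm_pos <- sort(sample(5:(core_len - 4L), plan$mismatches))
    for (j in mm_pos) star_core[core_len - j + 1L] <- substr(mature, j, j)
  }
  # star-side bulges: insert copies of the facing mature base between pairs
  if (length(plan$bulges)) {
    junctions <- sort(sample(6:(core_len - 6L), length(plan$bulges)))
    # insert from the right so earlier indices stay valid
    for (k in rev(seq_along(plan$bulges))) {
      j <- junctions[k]
      i <- core_len - j + 1L
      ins <- strrep(substr(mature, j, j), plan$bulges[k])
      star_core <- append(star_core, chars(ins), after = i)
    }
  }
  overhang <- random_seq(2L, c("A", "C"))
  star <- paste0(paste(star_core, collapse = ""), overhang)
  loop_core <- random_seq(loop_len, c("A", "C"), prob = c(0.6, 0.4))
  f5 <- random_seq(flank, c("A", "C"), prob = c(0.55, 0.45))
  f3 <- random_seq(flank, c("A", "C"), prob = c(0.55, 0.45))
  if (arm == "5p") {
    precursor <- paste0(f5, mature, loop_core, star, f3)
    mature_start <- flank + 1L
    star_start <- flank + L + loop_len + 1L
  } else {
    precursor <- paste0(f5, star, loop_core, mature, f3)
    star_start <- flank + 1L
    mature_start <- flank + nchar(star) + loop_len + 1L
  }
  list(precursor = precursor,
       mature_seq = mature, star_seq = star,
       mature_start = mature_start, mature_end = mature_start + L - 1L,
       star_start = star_start, star_end = star_start + nchar(star) - 1L,
       arm = arm)
}

#' @export
print.planted_hairpin <- function(x, ...) {
  cat("planted hairpin (", x$arm, " arm): ", nchar(x$precursor), " nt precursor, ",
      "mature ", x$mature_start, "-", x$mature_end, ", star ", x$star_start, "-",
      x$star_end, ", mfe ", x$structure$mfe, " kcal/mol\n", sep = "")
  invisible(x)
}
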