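# RNA secondary structure via ViennaRNA's RNAfold, plus dot-bracket utilities.

rnafold_path <- function() {
  p <- Sys.which("RNAfold")
  if (!nzchar(p)) {
    stop("RNAfold (ViennaRNA) was not found on PATH; it is required for folding.",
         call. = FALSE)
  }
  p
}

#' Fold RNA sequences to their minimum-free-energy structure
#'
#' Thin, batched wrapper around ViennaRNA's `RNAfold`. Many sequences are
#' folded in a single subprocess call, which keeps genome-wide precursor
#' scans fast. Folding is deterministic for a given sequence, and invariant
#' to DNA vs RNA spelling (T is mapped to U).
#'
#' @param sequences character vector of RNA/DNA sequences (<= ~700 nt each).
#' @param constraints optional character vector of the same length as
#'   `sequences`; per-sequence hard constraints in RNAfold notation
#'   (`.` free, `x` forced unpaired). `NA` entries mean unconstrained.
#' @return a list of `secondary_structure` objects, each with elements
#'   `sequence` (RNA, uppercase), `dot_bracket` and `mfe` (kcal/mol).
#' @examples
#' \dontrun{
#' fold_many("GGGGAAAACCCC")[[1]]
#' }
#' @export
fold_many <- function(sequences, constraints = NULL) {
  if (length(sequences) == 0) return(list())
  check_nucleotides(sequences)
  seqs <- as_rna(sequences)
  if (any(nchar(seqs) < 1)) stop("empty sequence cannot be folded", call. = FALSE)
  use_constraints <- !is.null(constraints)
  if (use_constraints) {
    stopifnot(length(constraints) == length(seqs))
    constraints <- ifelse(is.na(constraints), strrep(".", nchar(seqs)), constraints)
    if (any(nchar(constraints) != nchar(seqs))) {
      stop("constraint strings must have the same length as their sequences",
           call. = FALSE)
    }
  }
  inp <- tempfile(fileext = ".fa")
  on.exit(unlink(inp), add = TRUE)
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, sprintf(">s%d", i), seqs[[i]],
               if (use_constraints) constraints[[i]])
  }
  writeLines(lines, inp)
  args <- c("--noPS", if (use_constraints) "-C")
  out <- suppressWarnings(
    system2(rnafold_path(), args, stdout = TRUE, stderr = FALSE,
            stdin = inp)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("RNAfold failed with status ", status, call. = FALSE)
  }
  # output is triplets: >name / sequence / structure ( mfe )
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs)) {
    stop("unexpected RNAfold output (", length(hdr), " records for ",
         length(seqs), " sequences)", call. = FALSE)
  }
  res <- vector("list", length(seqs))
  for (i in seq_along(hdr)) {
    sline <- out[hdr[i] + 2L]
    m <- regmatches(sline, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", sline))[[1]]
    if (length(m) != 3) stop("could not parse RNAfold output line: ", sline, call. = FALSE)
    res[[i]] <- structure(
      list(sequence = seqs[[i]], dot_bracket = m[[2]], mfe = as.numeric(m[[3]])),
      class = "secondary_structure")
  }
  res
}

#' Fold one RNA sequence
#'
#' @inheritParams fold_many
#' @param sequence a single RNA/DNA sequence.
#' @param constraint optional hard-constraint string (`x` = forced unpaired).
#' @return a `secondary_structure` object.
#' @export
fold <- function(sequence, constraint = NULL) {
  stopifnot(length(sequence) == 1)
  fold_many(sequence, constraints = if (!is.null(constraint)) constraint)[[1]]
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, " (", format(x$mfe, nsmall = 2), " kcal/mol)\n",
      sep = "")
  invisible(x)
}

#' Pairing table of a dot-bracket structure
#'
#' @param dot_bracket dot-bracket string (no pseudoknots).
#' @return integer vector `pt` with `pt[i]` = partner of position i, 0 if unpaired.
#' @export
pair_table <- function(dot_bracket) {
  ch <- chars(dot_bracket)
  if (any(!ch %in% c(".", "(", ")"))) {
    stop("dot-bracket string contains invalid characters", call. = FALSE)
  }
  n <- length(ch)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket string", call. = FALSE)
  pt
}
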