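# RPM normalisation, log2 fold changes vs seedlings, tissue-preference
# classes, and composition / miRNA* summaries.

#' Normalise counts to reads per million (RPM)
#'
#' @param counts numeric matrix (miRNAs x libraries) or vector.
#' @param denominators per-library totals (total miRNA-mapped reads by
#'   default convention); all must be positive.
#' @return matrix (or vector) of `count / denominator * 1e6`.
#' @export
rpm_normalize <- function(counts, denominators) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1,
                                          dimnames = list(NULL, names(counts)))
  stopifnot(ncol(counts) == length(denominators))
  bad <- which(denominators <= 0)
  if (length(bad)) {
    nm <- names(denominators)[bad[1]]
    if (is.null(nm) || is.na(nm)) nm <- colnames(counts)[bad[1]]
    if (is.null(nm) || is.na(nm)) nm <- bad[1]
    stop("zero denominator for library ", nm, call. = FALSE)
  }
  sweep(counts, 2, denominators, "/") * 1e6
}

#' Log2 fold change of a tissue RPM against the seedlings RPM
#'
#' Missing (NA) when either value is zero; the reporting convention rounds to
#' one decimal, half away from zero (use `report = TRUE`).
#'
#' @param rpm_tissue,rpm_seedlings non-negative RPM values (vectorised).
#' @param report round to 1 decimal for reporting.
#' @return numeric vector (NA where undefined).
#' @export
log2_fold_change <- function(rpm_tissue, rpm_seedlings, report = TRUE) {
  stopifnot(all(rpm_tissue >= 0, na.rm = TRUE),
            all(rpm_seedlings >= 0, na.rm = TRUE))
  out <- ifelse(rpm_tissue > 0 & rpm_seedlings > 0,
                log2(rpm_tissue / rpm_seedlings), NA_real_)
  if (report) round_half_up(out, 1) else out
}

#' Tissue-preference class of one expression profile
#'
#' Classes: `seed_specific` (no expression in seedlings or flag leaves, some
#' in at least one seed stage), `leaf_specific` (expressed only in flag
#' leaves), `seed_preferential` (best seed log2 fold change positive and
#' above the flag-leaf one), `leaf_preferential` (flag-leaf log2 fold change
#' positive and above every seed stage), else `none`. Missing fold changes
#' compare as -Inf.
#'
#' @param rpm numeric length-5 vector, ordered seedlings, flag leaves, 5-d,
#'   10-d, 20-d seeds.
#' @param presence_floor RPM strictly above this counts as detected (0).
#' @return class string.
#' @export
classify_tissue_preference <- function(rpm, presence_floor = 0) {
  stopifnot(length(rpm) == 5, all(rpm >= 0))
  pres <- rpm > presence_floor
  if (!pres[1] && !pres[2] && any(pres[3:5])) return("seed_specific")
  if (!pres[1] && pres[2] && !any(pres[3:5])) return("leaf_specific")
  fc <- log2_fold_change(rpm[2:5], rep(rpm[1], 4), report = FALSE)
  fc[is.na(fc)] <- -Inf
  flag <- fc[1]; seeds <- fc[2:4]
  if (max(seeds) > flag && max(seeds) > 0) return("seed_preferential")
  if (flag > max(seeds) && flag > 0) return("leaf_preferential")
  "none"
}

#' Expression profiles for a set of miRNAs or families
#'
#' Convenience wrapper building the full profile table: RPM, the four log2
#' fold changes vs seedlings, total RPM and the tissue-preference class.
#' Family totals are summed on unrounded RPM before fold changes.
#'
#' @param rpm numeric matrix (rows = miRNAs/families, 5 tissue columns
#'   ordered as in [classify_tissue_preference()]).
#' @return data.frame with `id`, per-tissue rpm, `total_rpm`, `log2fc_*`
#'   (1-decimal report values) and `class`.
#' @export
expression_profiles <- function(rpm) {
  stopifnot(ncol(rpm) == 5)
  ids <- rownames(rpm)
  if (is.null(ids)) ids <- sprintf("mirna_%03d", seq_len(nrow(rpm)))
  out <- data.frame(id = ids)
  colnames(rpm) <- TISSUES
  out <- cbind(out, as.data.frame(rpm, row.names = FALSE))
  out$total_rpm <- rowSums(rpm)
  for (t in 2:5) {
    out[[paste0("log2fc_", TISSUES[t])]] <- log2_fold_change(rpm[, t], rpm[, 1])
  }
  out$class <- apply(rpm, 1, classify_tissue_preference)
  rownames(out) <- NULL
  out
}

#' 5'-nucleotide and length composition of a mature miRNA set
#'
#' @param sequences character vector of mature sequences (non-empty).
#' @return list with `five_prime` (percentage by first nucleotide) and
#'   `length` (percentage by length), each a named numeric vector summing to
#'   100; percentages are exact (round for reporting).
#' @export
composition_stats <- function(sequences) {
  if (length(sequences) == 0) stop("empty sequence set", call. = FALSE)
  seqs <- as_rna(sequences)
  first <- substr(seqs, 1, 1)
  fp <- 100 * table(factor(first, levels = RNA_BASES)) / length(seqs)
  len <- table(nchar(seqs)) * 100 / length(seqs)
  list(five_prime = stats::setNames(as.numeric(fp), names(fp)),
       length = stats::setNames(as.numeric(len), names(len)))
}

#' Per-tissue miRNA* accumulation and star-only flags
#'
#' @param star_counts integer matrix (stars x 5 libraries) of redundant star
#'   read counts, rownames = star ids.
#' @param mature_counts matrix of the paired mature read counts, same
#'   rownames and columns.
#' @return data.frame of stars with at least one read: per-tissue counts,
#'   `total`, and `star_only` (mature partner absent from every library).
#' @export
star_accumulation <- function(star_counts, mature_counts) {
  stopifnot(identical(rownames(star_counts), rownames(mature_counts)),
            ncol(star_counts) == ncol(mature_counts))
  total <- rowSums(star_counts)
  keep <- total > 0
  out <- data.frame(id = rownames(star_counts)[keep])
  out <- cbind(out, as.data.frame(star_counts[keep, , drop = FALSE],
                                  row.names = FALSE))
  out$total <- total[keep]
  out$star_only <- rowSums(mature_counts[keep, , drop = FALSE]) == 0
  rownames(out) <- NULL
  out
}
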