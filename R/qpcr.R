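# Relative quantification from qPCR CT values (comparative CT method) and
# concordance between qPCR and sequencing expression profiles.

#' Relative expression by the comparative CT (delta-delta-CT) method
#'
#' Technical replicates are averaged (arithmetic mean CT) per
#' (miRNA, sample); delta-CT = CT(miRNA) - CT(reference gene). Per miRNA the
#' calibrator is the sample with the lowest mean delta-CT (the highest
#' expression); its relative expression is 1.0 and the others are
#' 2^-(delta-delta-CT), so every value lies in (0, 1].
#'
#' @param table data.frame with columns `mirna`, `sample`, `replicate`,
#'   `ct`, `ct_ref` (CT values in cycles, inside (0, 45)).
#' @return data.frame: `mirna`, `sample`, `dct` (mean delta-CT), `ddct`,
#'   `relative` (2^-ddct), `calibrator` (logical).
#' @export
delta_delta_ct <- function(table) {
  need <- c("mirna", "sample", "ct", "ct_ref")
  if (!all(need %in% names(table))) {
    stop("CT table must have columns mirna, sample, replicate, ct, ct_ref",
         call. = FALSE)
  }
  if (anyNA(table$ct_ref)) {
    bad <- which(is.na(table$ct_ref))[1]
    stop("missing reference CT in row ", bad, call. = FALSE)
  }
  if (any(table$ct <= 0 | table$ct >= 45 | table$ct_ref <= 0 | table$ct_ref >= 45)) {
    stop("CT values must lie in (0, 45)", call. = FALSE)
  }
  agg <- stats::aggregate(cbind(ct, ct_ref) ~ mirna + sample, data = table, FUN = mean)
  agg$dct <- agg$ct - agg$ct_ref
  out <- do.call(rbind, lapply(split(agg, agg$mirna), function(d) {
    cal <- which.min(d$dct)
    d$ddct <- d$dct - d$dct[cal]
    d$relative <- 2^(-d$ddct)
    d$calibrator <- seq_len(nrow(d)) == cal
    d
  }))
  rownames(out) <- NULL
  out[order(out$mirna, out$sample), c("mirna", "sample", "dct", "ddct",
                                      "relative", "calibrator")]
}

#' Concordance between qPCR and sequencing expression profiles
#'
#' The sequencing profile of each miRNA is scaled so its highest RPM across
#' the five samples is 1.0, matching the qPCR calibrator convention; pairs
#' are then pooled across miRNAs and the Pearson correlation computed.
#'
#' @param qpcr data.frame with `mirna`, `sample`, `relative` (from
#'   [delta_delta_ct()]).
#' @param rpm numeric matrix of sequencing RPM (miRNAs x samples; rownames
#'   and colnames must cover the qPCR grid).
#' @return list: `r` (Pearson), `r_squared`, `p_value`, `n` pairs. `r` is NA
#'   (with NA p) if either pooled vector is constant.
#' @export
platform_concordance <- function(qpcr, rpm) {
  stopifnot(all(c("mirna", "sample", "relative") %in% names(qpcr)))
  scaled <- t(apply(rpm, 1, function(x) {
    if (max(x) > 0) x / max(x) else x
  }))
  dimnames(scaled) <- dimnames(rpm)
  idx <- cbind(match(qpcr$mirna, rownames(scaled)),
               match(qpcr$sample, colnames(scaled)))
  if (anyNA(idx)) stop("qPCR grid names missing from the sequencing matrix",
                       call. = FALSE)
  x <- qpcr$relative
  y <- scaled[idx]
  if (length(x) < 3) stop("fewer than 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(x))
}

#' Read a CT table from CSV
#'
#' Expected header: `mirna,sample,replicate,ct,ct_ref`.
#' @param path CSV file.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
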