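# Accessors for the published summary tables shipped with the package:
# the per-family expression table of the known wheat miRNAs and the novel
# wheat miRNA catalogue with mature sequences, as printed in the study this
# pipeline reproduces. They serve as reference inputs for desk checks of
# the expression and composition operations.

#' Published per-family RPM table of known wheat miRNAs
#'
#' Columns: family, conservation class, number of miRNA species, RPM in the
#' five tissues (seedlings, flag leaves, 5-d, 10-d, 20-d seeds), printed
#' total and the printed 1-decimal log2 fold changes vs seedlings ("-" in
#' the source is NA here).
#'
#' @return data.frame with one row per family.
#' @export
wheat_known_family_rpm <- function() {
  path <- system.file("extdata", "wheat_known_family_rpm.tsv",
                      package = "wheatmir", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "-", check.names = FALSE)
  x
}

#' Published novel wheat miRNA catalogue
#'
#' The 55 novel mature miRNA sequences with their lengths and RPM abundances
#' in seedlings, flag leaves and developing seeds (pooled).
#'
#' @return data.frame with one row per novel miRNA.
#' @export
wheat_novel_mirna <- function() {
  path <- system.file("extdata", "wheat_novel_mirna.tsv",
                      package = "wheatmir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
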