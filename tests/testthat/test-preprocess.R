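ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

raw_tag <- function(insert, total = 50L, a3 = ADAPTER3) {
  substr(paste0(insert, strrep(a3, 4)), 1, total)
}

test_that("3' adapters are trimmed and length bounds applied", {
  insert21 <- "ACGTACGTACGTACGTACGTA"
  insert17 <- "ACGTACGTACGTACGTA"
  insert31 <- strrep("ACGT", 8)[1]  # 32 nt
  res <- trim_and_filter(c(raw_tag(insert21), raw_tag(insert17),
                           raw_tag(substr(insert31, 1, 32))),
                         adapter_3p = ADAPTER3)
  expect_identical(res$clean, insert21)
  expect_equal(unname(res$log["too_short"]), 1L)
  expect_equal(unname(res$log["too_long"]), 1L)
  # conservation: kept + discards = input
  expect_equal(unname(res$log["input"]),
               sum(res$log[setdiff(names(res$log), "input")]))
})

test_that("reads without a locatable 3' adapter are discarded by default", {
  clean21 <- "ACGTACGTACGTACGTACGTA"
  res <- trim_and_filter(clean21, adapter_3p = ADAPTER3)
  expect_length(res$clean, 0)
  expect_equal(unname(res$log["no_adapter"]), 1L)
  # and pass through unchanged when the boundary requirement is lifted
  res2 <- trim_and_filter(clean21, adapter_3p = ADAPTER3,
                          discard_no_adapter = FALSE)
  expect_identical(res2$clean, clean21)
  # idempotence: cleaning already-clean reads changes nothing
  res3 <- trim_and_filter(res2$clean, adapter_3p = ADAPTER3,
                          discard_no_adapter = FALSE)
  expect_identical(res3$clean, res2$clean)
})

test_that("5'-adapter contaminants and low-quality reads are removed", {
  good <- raw_tag("ACGTACGTACGTACGTACGTA")
  contam <- substr(paste0(ADAPTER5, good), 1, 50)
  res <- trim_and_filter(c(good, contam), adapter_3p = ADAPTER3,
                         adapter_5p = ADAPTER5)
  expect_length(res$clean, 1)
  expect_equal(unname(res$log["adapter5_contaminant"]), 1L)

  quals <- c(strrep("I", 50), strrep("#", 50))  # Phred 40 vs 2
  res <- trim_and_filter(c(good, good), qualities = quals,
                         adapter_3p = ADAPTER3)
  expect_length(res$clean, 1)
  expect_equal(unname(res$log["low_quality"]), 1L)
})

test_that("low-complexity reads are filtered by the 50% repeat rule", {
  # longest homopolymer run 14/22 = 63.6% > 50%: discarded
  homo <- "AAAAAAAAAAAAAAGCTGCCAG"
  # dinucleotide repeat 16/22 = 72.7% > 50%: discarded
  dinuc <- paste0(strrep("AC", 8), "GTTGCA")
  # balanced read passes
  ok <- "ACGTACGGTCAGTCAGTCACGT"
  res <- trim_and_filter(vapply(c(homo, dinuc, ok), raw_tag, character(1)),
                         adapter_3p = ADAPTER3)
  expect_identical(res$clean, ok)
  expect_equal(unname(res$log["low_complexity"]), 2L)
})

test_that("empty input yields empty output with a warning", {
  expect_warning(res <- trim_and_filter(character(0), adapter_3p = ADAPTER3),
                 "empty input")
  expect_length(res$clean, 0)
  expect_error(trim_and_filter("ACGT!ACGT", adapter_3p = ADAPTER3),
               "index 1")
})

test_that("unique-read collapsing preserves per-library counts", {
  libs <- list(A = c(rep("ACGTACGTACGTACGTAA", 3), "ACGTACGTACGTACGTAC"),
               B = rep("ACGTACGTACGTACGTAA", 2),
               C = character(0))
  ut <- collapse_unique(libs)
  expect_equal(nrow(ut), 2)                      # one-base difference: two rows
  row1 <- ut[ut$sequence == "ACGTACGTACGTACGTAA", ]
  expect_equal(unname(unlist(row1[c("A", "B", "C")])), c(3L, 2L, 0L))
  expect_equal(row1$total_count, 5L)
  # column sums reproduce each library's clean-read total
  expect_equal(unname(colSums(ut[c("A", "B", "C")])),
               unname(vapply(libs, length, integer(1))))
})

test_that("size distributions sum to 100% and handle ties and empties", {
  reads <- c("ACGTACGTACGTACGTACGTA", "TTGTACGTACGTACGTACGTA",
             "ACGTACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGTACGT")
  ut <- collapse_unique(list(L = reads))
  sd <- size_distribution(ut)
  r21 <- sd$redundant_pct[sd$length == 21]
  r24 <- sd$redundant_pct[sd$length == 24]
  expect_equal(r21, 50); expect_equal(r24, 50)
  # unique variant: sequences {21a, 21b, 24} -> 66.7% / 33.3%
  expect_equal(sd$unique_pct[sd$length == 21], 200 / 3)
  expect_equal(sd$unique_pct[sd$length == 24], 100 / 3)
  expect_equal(sum(sd$redundant_pct), 100)
  expect_equal(sum(sd$unique_pct), 100)
  # empty library: omitted, no division by zero
  sd2 <- size_distribution(collapse_unique(list(E = character(0))))
  expect_equal(nrow(sd2), 0)
})

test_that("FASTQ and collapsed FASTA inputs round-trip", {
  tf <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTAA", "+", strrep("I", 18)), tf)
  x <- read_raw_reads(tf)
  expect_identical(x$sequences, "ACGTACGTACGTACGTAA")
  expect_identical(x$qualities, strrep("I", 18))
  tf2 <- tempfile(fileext = ".fasta")
  writeLines(c(">tag1_3", "ACGTACGTACGTACGTAA"), tf2)
  y <- read_raw_reads(tf2)
  expect_identical(y$sequences, rep("ACGTACGTACGTACGTAA", 3))
})
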