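# Build a perfectly complementary target site for a miRNA (transcript
# orientation), then introduce controlled defects at given miRNA positions.
perfect_site <- function(mirna) revcomp(as_rna(mirna))

# mutate the site base pairing miRNA position k (1-based from miRNA 5' end)
site_with <- function(mirna, k, base) {
  s <- chars(perfect_site(mirna))
  s[nchar(mirna) - k + 1] <- base
  paste(s, collapse = "")
}

MIR <- "UGACAGAAGAGAGGGAGCACA"  # 21 nt

test_that("duplex expectation applies the penalty table with core doubling", {
  expect_equal(score_duplex(MIR, perfect_site(MIR))$expectation, 0)

  # G:U wobble at position 15 (outside the 2-13 core): 0.5
  stopifnot(substr(MIR, 15, 15) == "G")
  sc <- score_duplex(MIR, site_with(MIR, 15, "U"))
  expect_equal(sc$expectation, 0.5)
  expect_length(sc$penalty_positions, 0)   # wobble is not a mismatch

  # mismatch at position 5 (inside the core): 1.0 doubled to 2.0
  sc <- score_duplex(MIR, site_with(MIR, 5, "C"))
  expect_equal(sc$expectation, 2.0)
  expect_equal(sc$penalty_positions, 5L)

  # same mismatch outside the core (position 15): 1.0
  sc <- score_duplex(MIR, site_with(MIR, 15, "U")) # wobble, handled above
  sc <- score_duplex(MIR, site_with(MIR, 16, "G")) # pos 16 is A; A-G mismatch
  expect_equal(sc$expectation, 1.0)

  # a single-gap alignment carries the gap penalty (site one base short)
  s <- perfect_site(MIR)
  gap_site <- paste0(substr(s, 1, 3), substr(s, 5, nchar(s)))  # drop one base
  sc <- score_duplex(MIR, gap_site)
  expect_equal(sc$n_gaps, 1L)
  expect_gte(sc$expectation, 2.0)
  expect_error(score_duplex("ACGU!", "ACGU"), "non-nucleotide")
})

test_that("transcript scanning finds planted sites and obeys the cut-off", {
  set.seed(31)
  bg <- function(n) random_seq(n, c("A", "C", "G", "T"), c(.4, .3, .1, .2))
  tx <- paste0(bg(300), as_dna(perfect_site(MIR)), bg(200),
               as_dna(site_with(MIR, 16, "G")), bg(150))
  hits <- scan_transcripts(MIR, c(t1 = tx))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$start[1], 301)
  expect_equal(hits$expectation[1], 0)
  expect_equal(hits$expectation[2], 1.0)     # planted 1-mismatch at position 16
  expect_equal(hits$start[2], 300 + 21 + 200 + 1)

  # no qualifying site: empty result
  none <- scan_transcripts(MIR, c(t2 = bg(400)))
  expect_true(is.data.frame(none))

  # a site over the expectation threshold is excluded
  bad <- site_with(MIR, 5, "C")               # 2.0
  bad <- chars(bad); bad[3] <- "A"; bad <- paste(bad, collapse = "")
  tx3 <- paste0(bg(100), as_dna(bad), bg(100))
  h3 <- scan_transcripts(MIR, c(t3 = tx3), max_expectation = 1)
  expect_false(any(h3$start == 101))
})

test_that("scanning equals exhaustive position-by-position scoring", {
  set.seed(32)
  bg <- function(n) random_seq(n, c("A", "C", "G", "T"), c(.4, .3, .1, .2))
  tx <- paste0(bg(120), as_dna(perfect_site(MIR)), bg(90),
               as_dna(site_with(MIR, 10, "C")), bg(80),
               as_dna(site_with(MIR, 20, "A")), bg(60))
  hits <- scan_transcripts(MIR, c(t1 = tx))
  brute <- oracle_target_sites(as_rna(MIR), as_rna(tx))
  # every reported hit is in the brute-force qualifying set, same expectation
  for (r in seq_len(nrow(hits))) {
    b <- brute[brute$start == hits$start[r] & brute$end == hits$end[r], ]
    expect_equal(nrow(b), 1)
    expect_equal(hits$expectation[r], b$expectation)
  }
  # the best site is found, and every qualifying site overlaps a reported hit
  expect_equal(min(hits$expectation), min(brute$expectation))
  for (r in seq_len(nrow(brute))) {
    expect_true(any(brute$start[r] <= hits$end & brute$end[r] >= hits$start))
  }
})

test_that("UPE measures the energy needed to open the site", {
  # site inside an unstructured A/C region: already unpaired, UPE = 0
  open_tx <- paste0(strrep("CA", 30), strrep("A", 21), strrep("CA", 30))
  expect_equal(upe(open_tx, 61, 81), 0)
  # site forming a strong stem with its flank: UPE > 0
  stem <- "GGGGGCGGGGGCGGGGGGCAGC"
  tx <- paste0(strrep("CA", 10), stem, "GAAAA", revcomp(stem), strrep("CA", 10))
  site_start <- 20 + nchar(stem) + 5 + 1
  expect_gt(upe(tx, site_start, site_start + nchar(stem) - 1), 0)
})

test_that("the accessibility filter removes inaccessible sites", {
  stem <- as_dna(perfect_site(MIR))
  tx <- paste0(strrep("CA", 15), revcomp(stem), "GAAAA", stem, strrep("CA", 15))
  p <- target_params()
  hits_all <- predict_targets(c(m = MIR), c(t = tx),
                              params = utils::modifyList(p, list(max_upe = 1e6)))
  expect_gt(nrow(hits_all), 0)
  hits_strict <- predict_targets(c(m = MIR), c(t = tx),
                                 params = utils::modifyList(p, list(max_upe = 0.1)))
  expect_lt(nrow(hits_strict), nrow(hits_all))
})

test_that("central mismatches switch the inhibition mode to translation", {
  sc10 <- score_duplex(MIR, site_with(MIR, 10, "C"))
  expect_identical(inhibition_mode(sc10), "translation")
  expect_identical(inhibition_mode(score_duplex(MIR, perfect_site(MIR))),
                   "cleavage")
  sc12 <- score_duplex(MIR, site_with(MIR, 12, "C"))
  expect_equal(sc12$penalty_positions, 12L)
  expect_identical(inhibition_mode(sc12), "cleavage")  # outside 9-11
})
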