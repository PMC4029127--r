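ss <- function(sequence, dot_bracket, mfe = -30) {
  structure(list(sequence = gsub("T", "U", toupper(sequence)),
                 dot_bracket = dot_bracket, mfe = mfe),
            class = "secondary_structure")
}

test_that("duplex evaluation reads geometry off the dot-bracket", {
  # hand-drawn hairpin: 5' arm mature 1-10 (8 paired + 2-nt overhang),
  # perfect 8-bp stem, 6-nt loop
  db <- paste0("((((((((", "......", "))))))))", "..")
  seq <- paste0("GGGGCCCC", "AAAAAA", "GGGGCCCC", "AA")
  dm <- evaluate_duplex(ss(seq, db), 1, 10)
  expect_true(dm$valid)
  expect_equal(dm$arm, "5p")
  expect_equal(dm$paired_bases, 8L)
  expect_equal(dm$mismatches, 0L)
  expect_equal(dm$overhang_3p_mature, 2L)
  expect_equal(dm$star_start, 15L)   # partner of mature position 8
  expect_equal(dm$star_end, 24L)     # partner of position 1, plus 2-nt overhang

  # asymmetric internal loop: 2 unpaired on the mature side vs 0 on the star
  db2 <- "((((..((((....))))))))"
  dm2 <- evaluate_duplex(ss(strrep("A", 22), db2), 1, 12)
  expect_true(dm2$valid)
  expect_equal(dm2$n_asymmetric_bulges, 1L)
  expect_equal(dm2$asymmetry, 2L)
  expect_equal(dm2$mismatches, 0L)

  # mature spanning the terminal loop is rejected
  dm3 <- evaluate_duplex(ss(strrep("A", 22), db2), 8, 20)
  expect_false(dm3$valid)
  expect_match(dm3$reason, "loop-spanning")

  # fully unpaired mature is rejected
  dm4 <- evaluate_duplex(ss(strrep("A", 10), ".........."), 1, 8)
  expect_false(dm4$valid)
})

test_that("duplex evaluation equals the brute-force pairing-table walk", {
  set.seed(21)
  plans <- list(duplex_plan(0), duplex_plan(1), duplex_plan(2, 1L),
                duplex_plan(3), duplex_plan(0, 2L), duplex_plan(1, c(1L, 1L)))
  for (p in plans) {
    for (arm in c("5p", "3p")) {
      h <- make_hairpin(sample(20:23, 1), p, arm = arm)
      dm <- evaluate_duplex(h$structure, h$mature_start, h$mature_end)
      or <- oracle_duplex(h$structure$dot_bracket, h$mature_start, h$mature_end)
      expect_true(or$valid)
      expect_equal(dm$paired_bases, or$paired_bases)
      expect_equal(dm$mismatches, or$mismatches)
      expect_equal(sort(dm$bulge_sizes), sort(or$bulge_sizes))
      expect_equal(dm$star_start, or$star_start)
      expect_equal(dm$star_end, or$star_end)
    }
  }
})

metrics_stub <- function(paired = 19L, mismatches = 0L, bulges = integer(0),
                         span = 10L) {
  structure(list(valid = TRUE, reason = NA, arm = "5p",
                 paired_bases = paired, mismatches = mismatches,
                 bulge_sizes = bulges, n_asymmetric_bulges = length(bulges),
                 asymmetry = if (length(bulges)) max(bulges) else 0L,
                 overhang_3p_mature = 2L, overhang_3p_star = 2L,
                 star_start = 50L, star_end = 70L, star_seq = "",
                 mature_star_span = span),
            class = "duplex_metrics")
}
struct_stub <- function(mfe) ss(strrep("A", 10), "..........", mfe)

test_that("every precursor threshold is enforced at its stated boundary", {
  ok <- apply_mireap_criteria(21, struct_stub(-18.0), metrics_stub(16L))
  expect_true(ok$pass)                      # all thresholds met exactly

  f <- apply_mireap_criteria(21, struct_stub(-18), metrics_stub(15L))
  expect_match(f$reasons, "min base pairs \\(16\\)", all = FALSE)

  f <- apply_mireap_criteria(21, struct_stub(-17.2), metrics_stub())
  expect_match(f$reasons, "free energy", all = FALSE)

  expect_true(apply_mireap_criteria(21, struct_stub(-25),
                                    metrics_stub(bulges = 2L))$pass)
  f <- apply_mireap_criteria(21, struct_stub(-25), metrics_stub(bulges = 3L))
  expect_match(f$reasons, "bulge > 2|asymmetry > 2", all = FALSE)

  expect_true(apply_mireap_criteria(21, struct_stub(-25),
                                    metrics_stub(bulges = c(2L, 2L)))$pass)
  f <- apply_mireap_criteria(21, struct_stub(-25),
                             metrics_stub(bulges = c(1L, 1L, 1L)))
  expect_match(f$reasons, "more than 2 asymmetric bulges", all = FALSE)

  expect_true(apply_mireap_criteria(21, struct_stub(-25),
                                    metrics_stub(span = 300L))$pass)
  f <- apply_mireap_criteria(21, struct_stub(-25), metrics_stub(span = 301L))
  expect_match(f$reasons, "arm span > 300", all = FALSE)

  expect_true(apply_mireap_criteria(21, struct_stub(-25),
                                    metrics_stub(mismatches = 4L))$pass)
  f <- apply_mireap_criteria(21, struct_stub(-25), metrics_stub(mismatches = 5L))
  expect_match(f$reasons, "mismatches > 4", all = FALSE)
  # a detected star relaxes the mismatch cap from 4 to 5
  expect_true(apply_mireap_criteria(21, struct_stub(-25),
                                    metrics_stub(mismatches = 5L),
                                    star_detected = TRUE)$pass)

  f <- apply_mireap_criteria(19, struct_stub(-25), metrics_stub())
  expect_match(f$reasons, "mature length", all = FALSE)
  expect_true(apply_mireap_criteria(20, struct_stub(-25), metrics_stub())$pass)
  expect_true(apply_mireap_criteria(23, struct_stub(-25), metrics_stub())$pass)
})

test_that("weakening any single threshold never shrinks the pass set", {
  set.seed(22)
  cands <- replicate(60, list(
    len = sample(18:25, 1),
    st = struct_stub(-stats::runif(1, 10, 40)),
    dm = metrics_stub(paired = sample(12:20, 1),
                      mismatches = sample(0:7, 1),
                      bulges = sample(0:3, sample(0:3, 1), replace = TRUE),
                      span = sample(c(5:20, 295:305), 1))), simplify = FALSE)
  pass0 <- vapply(cands, function(cc) {
    apply_mireap_criteria(cc$len, cc$st, cc$dm)$pass
  }, logical(1))
  weaker <- list(list(min_paired = 14L), list(max_mfe = -10),
                 list(max_bulge = 4L), list(max_asym_bulges = 4L),
                 list(max_asymmetry = 4L), list(max_arm_span = 400L),
                 list(max_mismatch = 6L),
                 list(min_mature_len = 17L, max_mature_len = 26L))
  for (w in weaker) {
    p <- utils::modifyList(mireap_params(), w)
    pass_w <- vapply(cands, function(cc) {
      apply_mireap_criteria(cc$len, cc$st, cc$dm, params = p)$pass
    }, logical(1))
    expect_true(all(pass_w[pass0]))
  }
})

test_that("locus read partitioning applies the strict >95%/>75% rule", {
  prec <- paste0(strrep("CA", 10),
                 "GGGAATTCCGGAATTCCGGAA",    # mature 21-41
                 "TTTTTT",
                 "TTCCGGAATTCCGGAATTCCC",    # star-like arm 48-68
                 strrep("CA", 10))
  mature <- "GGGAATTCCGGAATTCCGGAA"
  star_span <- c(48L, 68L)
  outside <- substr(prec, 1, 18)
  star_read <- substr(prec, 48, 68)
  # 100 precursor reads: 80 exact mature + 16 on the star arm + 4 outside
  st <- partition_locus_reads(prec, mature, star_span,
                              c(mature, star_read, outside),
                              c(80L, 16L, 4L))
  expect_equal(st$frac_arm, 0.96)
  expect_equal(st$frac_reliable, 80 / 96, tolerance = 1e-12)
  expect_true(st$pass)
  # exactly 95% on the arms is NOT more than 95%
  st2 <- partition_locus_reads(prec, mature, star_span,
                               c(mature, outside), c(95L, 5L))
  expect_false(st2$pass)
  expect_match(st2$reason, "not > 0.95")
  # all reads exactly the mature: fractions 1.0, passes
  st3 <- partition_locus_reads(prec, mature, star_span, mature, 50L)
  expect_equal(st3$frac_arm, 1); expect_equal(st3$frac_reliable, 1)
  expect_true(st3$pass)
  # zero mapped reads: clean failure, no division by zero
  st4 <- partition_locus_reads(prec, mature, star_span,
                               "GGGGGGGGGGGGGGGGGGGG", 10L)
  expect_false(st4$pass)
  expect_match(st4$reason, "no precursor-mapped reads")
})

test_that("final status combines criteria, abundance and star evidence", {
  ok_crit <- list(pass = TRUE, reasons = character(0))
  ok_stats <- list(pass = TRUE, reason = NA_character_)
  expect_identical(
    classify_mirna(ok_crit, ok_stats, c(0, 2, 12, 3, 1), TRUE)$status, "novel")
  expect_identical(
    classify_mirna(ok_crit, ok_stats, c(0, 2, 8, 3, 1), FALSE)$status,
    "candidate")
  low <- classify_mirna(ok_crit, ok_stats, c(0, 1, 4.9, 2, 0), TRUE)
  expect_identical(low$status, "rejected")
  expect_match(low$reasons, "abundance < 5 RPM", all = FALSE)
})

test_that("precursor windows cover planted loci and respect the copy cap", {
  set.seed(23)
  h <- make_hairpin(21, duplex_plan(0), arm = "5p")
  prec <- as_dna(h$precursor)
  contig <- paste0(random_seq(400), prec, random_seq(400))
  genome <- c(ctg = contig)
  m_start <- 400 + h$mature_start
  hit <- data.frame(contig = "ctg", start = m_start, end = m_start + 20L,
                    strand = "+", n_loci = 1L)
  win <- extract_precursor_windows(hit, genome)
  expect_gt(nrow(win), 0)
  covers <- any(win$win_start <= 401 & win$win_end >= 400 + nchar(prec))
  expect_true(covers)
  # strand-adjusted window places the mature at the stated offset
  for (w in seq_len(nrow(win))) {
    expect_identical(substr(win$sequence[w], win$mature_offset[w],
                            win$mature_offset[w] + 20L),
                     substr(contig, m_start, m_start + 20L))
  }
  # reads hitting more than 20 loci are excluded with a reason
  hit25 <- transform(hit, n_loci = 25L)
  win25 <- extract_precursor_windows(hit25, genome)
  expect_equal(nrow(win25), 0)
  expect_match(attr(win25, "reason"), "copy number > 20")
  # windows at a contig edge are clipped and flagged
  hit_edge <- data.frame(contig = "ctg", start = 5L, end = 25L,
                         strand = "+", n_loci = 1L)
  win_edge <- extract_precursor_windows(hit_edge, genome)
  expect_true(any(win_edge$clipped))
  expect_true(all(win_edge$win_start >= 1))
})
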