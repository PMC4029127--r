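toy_genome <- function() {
  set.seed(5)
  g <- c(ctgA = random_seq(600), ctgB = random_seq(600))
  g
}

test_that("genome matching finds exact hits on both strands with copy counts", {
  g <- toy_genome()
  read_plus <- substr(g[["ctgA"]], 101, 121)
  read_minus <- revcomp(substr(g[["ctgB"]], 201, 222))
  triple <- "ACGTACGTACGTACGTACGTA"
  g[["ctgA"]] <- paste0(g[["ctgA"]], triple, "GG", triple)
  g[["ctgB"]] <- paste0(g[["ctgB"]], triple)
  absent <- "TTTTTTTTTTGGGGGGGGGGA"
  mg <- match_genome(c(read_plus, read_minus, triple, absent), g)
  h1 <- mg$hits[mg$hits$sequence == read_plus, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 101); expect_equal(h1$end, 121)
  expect_equal(h1$strand, "+")
  h2 <- mg$hits[mg$hits$sequence == read_minus, ]
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 201); expect_equal(h2$end, 222)
  expect_equal(unique(mg$hits$n_loci[mg$hits$sequence == triple]), 3L)
  expect_identical(mg$unmatched, absent)
  # every reported hit really is the strand-adjusted genome substring
  for (r in seq_len(nrow(mg$hits))) {
    hh <- mg$hits[r, ]
    sub <- substr(g[[hh$contig]], hh$start, hh$end)
    if (hh$strand == "-") sub <- revcomp(sub)
    expect_identical(sub, hh$sequence)
  }
  expect_error(match_genome("ACGT", character(0)), "empty genome")
})

test_that("genome matching agrees with a naive substring scan", {
  set.seed(6)
  g <- c(c1 = random_seq(800), c2 = random_seq(500))
  reads <- c(vapply(1:8, function(i) {
    s <- sample(750, 1)
    substr(g[["c1"]], s, s + sample(18:24, 1))
  }, character(1)),
  revcomp(substr(g[["c2"]], 100, 120)),
  vapply(1:4, function(i) random_seq(21), character(1)))
  mg <- match_genome(reads, g)
  oracle <- oracle_genome_scan(reads, g)
  key <- function(d) sort(paste(d$sequence, d$contig, d$start, d$end, d$strand))
  expect_identical(key(mg$hits), key(oracle))
})

test_that("ncRNA filtering removes reads above 90% identity to a reference", {
  set.seed(7)
  refs <- c(rrna = random_seq(300))
  frag <- substr(refs[["rrna"]], 50, 70)           # 21/21 = 100%
  mm2 <- frag; substr(mm2, 3, 3) <- flip_base(substr(mm2, 3, 3))
  substr(mm2, 10, 10) <- flip_base(substr(mm2, 10, 10))   # 19/21 = 90.5%
  mm3 <- mm2; substr(mm3, 15, 15) <- flip_base(substr(mm3, 15, 15)) # 18/21
  unrelated <- "TTTTTAAAAACCCCCGGGGGA"
  res <- filter_ncrna(c(frag, mm2, mm3, unrelated), refs)
  expect_setequal(res$removed, c(frag, mm2))
  expect_setequal(res$retained, c(mm3, unrelated))
  # partition: nothing lost, nothing duplicated
  expect_setequal(c(res$removed, res$retained), c(frag, mm2, mm3, unrelated))
  expect_length(intersect(res$removed, res$retained), 0)
  expect_error(filter_ncrna("ACGT", character(0)), "empty")
})

test_that("reverse-complement ncRNA fragments are also removed", {
  set.seed(8)
  refs <- c(trna = random_seq(120))
  frag <- revcomp(substr(refs[["trna"]], 10, 31))
  expect_identical(filter_ncrna(frag, refs)$removed, frag)
})

test_that("known assignment requires identical sequence and length", {
  cat <- data.frame(
    name = c("tae-miR156", "osa-miR444"),
    family = c("miR156", "miR444"),
    species = c("tae;rice;maize", "rice"),
    sequence = c("UGACAGAAGAGAGUGAGCACA", "UGCAGUUGUUGUUUGGCUCCU"))
  reads <- c("TGACAGAAGAGAGTGAGCACA",        # exact (DNA spelling)
             "TGACAGAAGAGAGTGAGCAC",         # last base missing: no match
             "TGCAGTTGTTGTTTGGCTCCT")        # non-wheat entry
  asn <- assign_known(reads, cat)
  expect_equal(nrow(asn), 2)
  expect_identical(asn$family, c("miR156", "miR444"))
  expect_identical(asn$needs_validation, c(FALSE, TRUE))
  expect_false("TGACAGAAGAGAGTGAGCAC" %in% asn$sequence)

  cat_bad <- rbind(cat, data.frame(name = "x", family = "miROther",
                                   species = "tae",
                                   sequence = "UGACAGAAGAGAGUGAGCACA"))
  expect_error(assign_known(reads, cat_bad), "conflicting families")
})

test_that("conservation classes follow the six-species rule", {
  six <- c("Arabidopsis", "soybean", "Populus", "rice", "maize", "Brachypodium")
  expect_identical(classify_conservation(six), "highly_conserved")
  expect_identical(classify_conservation(c("rice", "maize")),
                   "moderately_conserved")
  expect_identical(classify_conservation(character(0)), "non_conserved")
  expect_error(classify_conservation(c("rice", "wheat")), "unknown species")
})
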