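# Synthetic study generator: a toy genome with planted MIRNA hairpins and
# ncRNA loci, a known-miRNA catalogue, and five tissue sRNA libraries with
# per-read ground truth. All randomness flows from config$rng_seed, so the
# same configuration always produces byte-identical files.

#' Simulation configuration
#'
#' Defaults describe a small but realistic five-tissue wheat-style study:
#' four contigs, a mix of known, novel and star-less (candidate) MIRNA loci
#' including seed-specific and leaf-specific ones, an ncRNA degradation
#' background, Illumina-style 50-nt raw tags with the 3' adapter appended and
#' a small fraction of 5'-adapter contaminants, and mature-dominant locus
#' read composition (mature >> star >> loop).
#'
#' @param rng_seed integer seed driving the whole simulation.
#' @param n_contigs,contig_length toy genome dimensions.
#' @param n_known_loci,n_novel_loci,n_candidate_loci locus counts; candidate
#'   loci are planted without any star reads.
#' @param n_seed_specific,n_leaf_specific numbers of novel loci expressed only
#'   in seeds / only in flag leaves.
#' @param ncrna_fraction proportion of reads drawn verbatim from the ncRNA
#'   references.
#' @param adapter_3p,adapter_5p adapter sequences (DNA).
#' @param reads_per_library raw reads simulated per tissue library (>= 1000).
#' @param read_total_len raw tag length (insert + adapter, padded/truncated).
#' @param frac_5p_contam fraction of raw reads given a 5' adapter prefix.
#' @param isoform_fracs length-3 numeric (exact, 3' trimmed by 1, 3' extended
#'   by 1) mature read composition.
#' @param star_rel,loop_rel star and loop read rates relative to mature reads.
#' @param expr_range log10-uniform range of locus expression weights (RPM of
#'   miRNA-mapped reads) in expressed tissues.
#' @param error_rate optional uniform substitution rate (off by default; the
#'   downstream exact-match genome step assumes error-free tags dominate).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(rng_seed = 20140416L,
                              n_contigs = 4L, contig_length = 12000L,
                              n_known_loci = 6L, n_novel_loci = 12L,
                              n_candidate_loci = 4L,
                              n_seed_specific = 3L, n_leaf_specific = 2L,
                              ncrna_fraction = 0.15,
                              adapter_3p = "TCGTATGCCGTCTTCTGCTTG",
                              adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                              reads_per_library = 20000L,
                              read_total_len = 50L,
                              frac_5p_contam = 0.02,
                              isoform_fracs = c(exact = 0.90, trim1 = 0.06, ext1 = 0.04),
                              star_rel = 0.07, loop_rel = 0.012,
                              expr_range = c(100, 4000),
                              error_rate = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$reads_per_library >= 1000L,
            cfg$ncrna_fraction >= 0, cfg$ncrna_fraction <= 1,
            cfg$frac_5p_contam >= 0, cfg$frac_5p_contam <= 1,
            all(cfg$isoform_fracs >= 0), abs(sum(cfg$isoform_fracs) - 1) < 1e-8,
            cfg$n_contigs >= 1, cfg$contig_length >= 2000,
            cfg$n_known_loci >= 0, cfg$n_novel_loci >= 0, cfg$n_candidate_loci >= 0,
            cfg$n_seed_specific + cfg$n_leaf_specific <= cfg$n_novel_loci,
            nchar(cfg$adapter_3p) >= 8, nchar(cfg$adapter_5p) >= 8)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate the full synthetic dataset
#'
#' Plants hairpin loci and ncRNA reference sequences in a random genome,
#' writes the genome, ncRNA and known-catalogue FASTA files, simulates five
#' tissue FASTQ libraries, and writes a per-read ground-truth TSV.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `config`, `paths` (named file paths),
#'   `loci` (planted-locus table), `ground_truth` (per-read origin table) and
#'   `expression` (true per-tissue expression weights per locus).
#' @export
simulate_dataset <- function(config = simulation_config(), outdir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$rng_seed)

  loci <- plant_loci(config)
  genome <- build_genome(config, loci)
  ncrna <- make_ncrna_refs(config)
  genome <- embed_ncrna(genome, ncrna)

  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    ncrna = file.path(outdir, "ncrna.fasta"),
    catalogue = file.path(outdir, "known_mirnas.fasta"),
    ground_truth = file.path(outdir, "ground_truth.tsv"),
    loci = file.path(outdir, "planted_loci.tsv"))
  writeLines(fasta_lines(genome$contigs), paths$genome)
  writeLines(fasta_lines(ncrna), paths$ncrna)
  writeLines(catalogue_lines(loci), paths$catalogue)

  expr <- locus_expression(config, loci)
  lib <- simulate_libraries(genome, loci, ncrna, expr, config, outdir)
  paths$fastq <- lib$fastq

  gt <- lib$ground_truth
  utils::write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  loci_tab <- loci_table(loci, genome)
  utils::write.table(loci_tab, paths$loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(config = config, paths = paths, loci = loci_tab,
                 ground_truth = gt, expression = expr,
                 genome = genome$contigs))
}

# ---- internal builders -----------------------------------------------------

plant_loci <- function(config) {
  n <- config$n_known_loci + config$n_novel_loci + config$n_candidate_loci
  loci <- vector("list", n)
  kinds <- c(rep("known", config$n_known_loci),
             rep("novel", config$n_novel_loci),
             rep("candidate", config$n_candidate_loci))
  for (i in seq_len(n)) {
    len <- sample(20:23, 1, prob = c(0.15, 0.55, 0.2, 0.1))
    plan <- duplex_plan(
      mismatches = sample(0:min(3L, len - 2L - 16L), 1),
      bulges = if (stats::runif(1) < 0.3) sample(1:2, 1) else integer(0))
    arm <- sample(c("5p", "3p"), 1)
    hp <- make_hairpin(len, plan, arm = arm, loop_len = sample(6:12, 1))
    loci[[i]] <- list(locus_id = sprintf("locus_%02d", i), kind = kinds[i],
                      hairpin = hp)
  }
  # uniqueness of mature sequences across loci
  mats <- vapply(loci, function(l) l$hairpin$mature_seq, character(1))
  stopifnot(!anyDuplicated(mats))
  loci
}

build_genome <- function(config, loci) {
  contigs <- vapply(seq_len(config$n_contigs), function(i) {
    random_seq(config$contig_length, DNA_BASES)
  }, character(1))
  names(contigs) <- sprintf("contig_%02d", seq_len(config$n_contigs))
  # place precursors at non-overlapping slots
  placements <- data.frame(locus_id = character(0), contig = character(0),
                           start = integer(0), end = integer(0))
  slots <- list()
  for (i in seq_along(loci)) {
    prec <- as_dna(loci[[i]]$hairpin$precursor)
    plen <- nchar(prec)
    repeat {
      ci <- sample(seq_along(contigs), 1)
      pos <- sample(seq(100L, config$contig_length - plen - 100L), 1)
      key <- names(contigs)[ci]
      # wide separation so no precursor window of one locus reaches another
      clash <- any(vapply(slots, function(s) {
        s$contig == key && pos <= s$end + 700L && pos + plen - 1L >= s$start - 700L
      }, logical(1)))
      if (!clash) break
    }
    substr(contigs[ci], pos, pos + plen - 1L) <- prec
    slots[[length(slots) + 1L]] <- list(contig = key, start = pos,
                                        end = pos + plen - 1L)
    placements <- rbind(placements, data.frame(
      locus_id = loci[[i]]$locus_id, contig = key, start = pos,
      end = pos + plen - 1L))
  }
  list(contigs = contigs, placements = placements, slots = slots)
}

make_ncrna_refs <- function(config) {
  kinds <- c("rRNA_like_1", "rRNA_like_2", "tRNA_like_1", "snoRNA_like_1")
  refs <- vapply(kinds, function(k) random_seq(sample(150:400, 1), DNA_BASES),
                 character(1))
  names(refs) <- kinds
  refs
}

embed_ncrna <- function(genome, ncrna) {
  contigs <- genome$contigs
  for (i in seq_along(ncrna)) {
    rlen <- nchar(ncrna[i])
    repeat {
      ci <- sample(seq_along(contigs), 1)
      pos <- sample(seq(100L, nchar(contigs[ci]) - rlen - 100L), 1)
      key <- names(contigs)[ci]
      clash <- any(vapply(genome$slots, function(s) {
        s$contig == key && pos <= s$end + 700L && pos + rlen - 1L >= s$start - 700L
      }, logical(1)))
      if (!clash) break
    }
    substr(contigs[ci], pos, pos + rlen - 1L) <- ncrna[i]
    genome$slots[[length(genome$slots) + 1L]] <-
      list(contig = key, start = pos, end = pos + rlen - 1L)
  }
  genome$contigs <- contigs
  genome
}

# Toy known-miRNA catalogue: headers "name|family|species;..."; known loci are
# registered for wheat (tae) plus reference species so conservation classes
# are exercised; two extra non-wheat entries require precursor validation.
catalogue_lines <- function(loci) {
  known <- Filter(function(l) l$kind == "known", loci)
  six <- c("Arabidopsis", "soybean", "Populus", "rice", "maize", "Brachypodium")
  lines <- character(0)
  for (i in seq_along(known)) {
    fam <- sprintf("simfam%02d", i)
    presence <- if (i %% 3 == 1) six else if (i %% 3 == 2) {
      sample(six, sample(1:4, 1))
    } else character(0)
    species <- paste(c("tae", presence), collapse = ";")
    lines <- c(lines,
               sprintf(">sim-miR%03d|%s|%s", i, fam, species),
               as_rna(known[[i]]$hairpin$mature_seq))
  }
  lines
}

locus_expression <- function(config, loci) {
  n <- length(loci)
  base <- 10^stats::runif(n, log10(config$expr_range[1]), log10(config$expr_range[2]))
  expr <- matrix(0, nrow = n, ncol = 5, dimnames = list(
    vapply(loci, `[[`, character(1), "locus_id"), TISSUES))
  for (i in seq_len(n)) {
    expr[i, ] <- base[i] * stats::runif(5, 0.3, 1.7)
  }
  novel_idx <- which(vapply(loci, `[[`, character(1), "kind") == "novel")
  seed_specific <- novel_idx[seq_len(config$n_seed_specific)]
  leaf_specific <- novel_idx[config$n_seed_specific + seq_len(config$n_leaf_specific)]
  expr[seed_specific, c("seedlings", "flag_leaves")] <- 0
  expr[leaf_specific, c("seedlings", "seed_5d", "seed_10d", "seed_20d")] <- 0
  attr(expr, "seed_specific") <- rownames(expr)[seed_specific]
  attr(expr, "leaf_specific") <- rownames(expr)[leaf_specific]
  expr
}

#' Simulate the five tissue sRNA libraries
#'
#' Draws reads per library from a multinomial over ncRNA fragments and locus
#' reads weighted by the per-tissue expression matrix; locus reads are mature
#' isoforms, star reads (absent for candidate loci) and loop-spanning
#' degradation reads. Raw tags carry the 3' adapter (plus a 5' adapter for a
#' small contaminant fraction) and are padded/truncated to the raw tag length.
#'
#' @param genome output of the internal genome builder (list with `contigs`).
#' @param loci planted locus list.
#' @param ncrna named character vector of ncRNA reference sequences.
#' @param expression locus-by-tissue expression weight matrix.
#' @param config a [simulation_config()].
#' @param outdir where the FASTQ files are written.
#' @return list with `fastq` (named paths) and `ground_truth` (data.frame:
#'   read_id, library, origin, locus_id, insert).
#' @export
simulate_libraries <- function(genome, loci, ncrna, expression, config, outdir) {
  if (ncol(expression) != 5L) {
    stop("expression profile must have exactly 5 tissues", call. = FALSE)
  }
  fastq <- character(0)
  gt <- list()
  for (t in seq_along(TISSUES)) {
    tissue <- TISSUES[t]
    w <- expression[, t]
    p_loci <- if (sum(w) > 0) (1 - config$ncrna_fraction) * w / sum(w) else w
    probs <- c(ncrna = config$ncrna_fraction, p_loci)
    counts <- as.integer(stats::rmultinom(1, config$reads_per_library, probs))
    names(counts) <- names(probs)
    inserts <- character(0); origins <- character(0); locus_ids <- character(0)
    if (counts[["ncrna"]] > 0) {
      inserts <- c(inserts, sample_ncrna_fragments(ncrna, counts[["ncrna"]]))
      origins <- c(origins, rep("ncrna", counts[["ncrna"]]))
      locus_ids <- c(locus_ids, rep(NA_character_, counts[["ncrna"]]))
    }
    for (i in seq_along(loci)) {
      n_i <- counts[[loci[[i]]$locus_id]]
      if (n_i == 0) next
      li <- sample_locus_reads(loci[[i]], n_i, config)
      inserts <- c(inserts, li$insert)
      origins <- c(origins, li$origin)
      locus_ids <- c(locus_ids, rep(loci[[i]]$locus_id, n_i))
    }
    ord <- sample(length(inserts))
    inserts <- inserts[ord]; origins <- origins[ord]; locus_ids <- locus_ids[ord]
    if (config$error_rate > 0) inserts <- add_errors(inserts, config$error_rate)
    raw <- make_raw_tags(inserts, config)
    ids <- sprintf("%s_read_%06d", tissue, seq_along(inserts))
    path <- file.path(outdir, paste0(tissue, ".fastq"))
    write_fastq(ids, raw, path)
    fastq[tissue] <- path
    gt[[tissue]] <- data.frame(read_id = ids, library = tissue,
                               origin = origins, locus_id = locus_ids,
                               insert = inserts)
  }
  list(fastq = fastq, ground_truth = do.call(rbind, c(gt, make.row.names = FALSE)))
}

sample_ncrna_fragments <- function(ncrna, n) {
  vapply(seq_len(n), function(i) {
    ref <- ncrna[[sample(length(ncrna), 1)]]
    len <- sample(18:30, 1)
    s <- sample(nchar(ref) - len + 1L, 1)
    substr(ref, s, s + len - 1L)
  }, character(1))
}

sample_locus_reads <- function(locus, n, config) {
  hp <- locus$hairpin
  star_rel <- if (locus$kind == "candidate") 0 else config$star_rel
  comp <- c(mature = 1, star = star_rel, loop = config$loop_rel)
  kind <- sample(names(comp), n, replace = TRUE, prob = comp / sum(comp))
  prec <- hp$precursor
  insert <- character(n)
  for (j in seq_len(n)) {
    insert[j] <- switch(kind[j],
      mature = {
        iso <- sample(names(config$isoform_fracs), 1, prob = config$isoform_fracs)
        m1 <- hp$mature_start; m2 <- hp$mature_end
        if (iso == "trim1") m2 <- m2 - 1L
        if (iso == "ext1") m2 <- min(nchar(prec), m2 + 1L)
        substr(prec, m1, m2)
      },
      star = substr(prec, hp$star_start, hp$star_end),
      loop = {
        # degradation read spanning the terminal loop
        centre <- (min(hp$mature_end, hp$star_end) +
                     max(hp$mature_start, hp$star_start)) %/% 2L
        len <- sample(18:22, 1)
        s <- max(1L, centre - len %/% 2L)
        substr(prec, s, min(nchar(prec), s + len - 1L))
      })
  }
  list(insert = as_dna(insert), origin = kind)
}

add_errors <- function(inserts, rate) {
  vapply(inserts, function(s) {
    ch <- chars(s)
    hit <- stats::runif(length(ch)) < rate
    if (any(hit)) ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

make_raw_tags <- function(inserts, config) {
  tag <- paste0(inserts, config$adapter_3p)
  pad <- strrep(config$adapter_3p, ceiling(config$read_total_len / nchar(config$adapter_3p)) + 1L)
  tag <- substr(paste0(tag, pad), 1L, config$read_total_len)
  n5 <- round(config$frac_5p_contam * length(tag))
  if (n5 > 0) {
    idx <- sample(length(tag), n5)
    tag[idx] <- substr(paste0(config$adapter_5p, tag[idx]), 1L, config$read_total_len)
  }
  tag
}

#' Simulate a qPCR CT table from an expression matrix
#'
#' Generates replicate CT values whose implied relative expression tracks the
#' given per-tissue profile: delta-CT is `-log2(expression)` plus Gaussian
#' noise, with undetected tissues placed at a late-cycle detection limit.
#' Feeding the result to [delta_delta_ct()] recovers the profile up to the
#' noise.
#'
#' @param expression numeric matrix (miRNAs x samples), e.g. RPM; rownames
#'   and colnames are used as miRNA and sample ids.
#' @param noise_sd per-replicate CT noise (cycles).
#' @param replicates technical replicates per (miRNA, sample).
#' @param ct_ref reference-gene CT (cycles).
#' @param detection_limit CT assigned to undetected miRNA/sample pairs.
#' @return data.frame with columns mirna, sample, replicate, ct, ct_ref.
#' @export
simulate_ct_table <- function(expression, noise_sd = 0.15, replicates = 3L,
                              ct_ref = 20, detection_limit = 38) {
  stopifnot(!is.null(rownames(expression)), !is.null(colnames(expression)))
  rows <- list()
  for (m in rownames(expression)) {
    for (s in colnames(expression)) {
      e <- expression[m, s]
      ct_true <- if (e > 0) ct_ref + 18 - log2(e) else detection_limit
      ct_true <- min(ct_true, detection_limit)
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = m, sample = s, replicate = r,
          ct = ct_true + stats::rnorm(1, 0, noise_sd),
          ct_ref = ct_ref + stats::rnorm(1, 0, noise_sd / 2))
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

write_fastq <- function(ids, seqs, path) {
  qual <- strrep("I", nchar(seqs))
  out <- character(4L * length(ids))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
}

fasta_lines <- function(seqs) {
  as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
}

loci_table <- function(loci, genome) {
  pl <- genome$placements
  data.frame(
    locus_id = vapply(loci, `[[`, character(1), "locus_id"),
    kind = vapply(loci, `[[`, character(1), "kind"),
    contig = pl$contig[match(vapply(loci, `[[`, character(1), "locus_id"), pl$locus_id)],
    precursor_start = pl$start[match(vapply(loci, `[[`, character(1), "locus_id"), pl$locus_id)],
    precursor_end = pl$end[match(vapply(loci, `[[`, character(1), "locus_id"), pl$locus_id)],
    arm = vapply(loci, function(l) l$hairpin$arm, character(1)),
    mature_seq = vapply(loci, function(l) as_dna(l$hairpin$mature_seq), character(1)),
    star_seq = vapply(loci, function(l) as_dna(l$hairpin$star_seq), character(1)),
    mature_len = vapply(loci, function(l) nchar(l$hairpin$mature_seq), integer(1)),
    mfe = vapply(loci, function(l) l$hairpin$structure$mfe, numeric(1)))
}
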