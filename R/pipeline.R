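# Orchestration: one configuration drives simulation (optional),
# preprocessing, annotation, discovery, expression profiling and the
# optional target/qPCR stages, with JSONL logging and deterministic seeding.

#' Pipeline configuration
#'
#' Defaults reproduce the reference parameterization: 18-30 nt insert
#' lengths, mean Phred >= 20, 50% repeat cap, 90% ncRNA identity, the
#' precursor thresholds of [mireap_params()], 5 RPM abundance, expectation 3
#' and UPE 25 with 17/13 accessibility flanks. Overrides are echoed in the
#' run log.
#'
#' @param yaml optional path to a YAML file with fields named as below.
#' @param ... overrides (e.g. `rng_seed = 7`, `simulate = FALSE`,
#'   `fastq = c(...)`, `genome = "genome.fasta"`, nested lists `sim`,
#'   `preprocess`, `mireap`, `targets`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(yaml = NULL, ...) {
  cfg <- list(
    outdir = tempfile("wheatmir_run_"),
    rng_seed = 20140416L,
    simulate = TRUE,
    sim = list(),                    # overrides for simulation_config()
    fastq = NULL, genome = NULL, ncrna = NULL, catalogue = NULL,
    transcripts = NULL, ct_table = NULL,
    preprocess = list(min_len = 18L, max_len = 30L, quality_min = 20,
                      repeat_max = 0.5, seed_len = 8L,
                      discard_no_adapter = TRUE,
                      adapter_3p = NULL, adapter_5p = NULL),
    ncrna_identity = 0.90,
    mireap = mireap_params(),
    targets = target_params(),
    run_targets = FALSE)
  if (!is.null(yaml)) {
    y <- yaml::read_yaml(yaml)
    cfg <- utils::modifyList(cfg, y)
    cfg$overridden <- names(y)
  }
  dots <- list(...)
  cfg <- utils::modifyList(cfg, dots)
  cfg$overridden <- union(cfg$overridden, names(dots))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline
#'
#' Stages: (optional) simulation, read cleaning, unique-tag collapsing,
#' genome matching, ncRNA filtering, known-miRNA assignment, novel/candidate
#' discovery, RPM expression profiling and composition statistics, plus
#' target prediction and qPCR concordance when their inputs are configured.
#' All randomness flows from `config$rng_seed`; identical configurations
#' produce byte-identical outputs. On stage failure, partial outputs are
#' removed and the error names the stage.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `summary` (named counts and statistics),
#'   `tables` (the main data.frames) and `paths` (written files).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run_log.jsonl")
  unlink(logfile)
  log_event <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE)
  }
  fail <- function(stage, e) {
    unlink(file.path(outdir, "summary.json"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  if (length(config$overridden)) {
    log_event("config", overridden = config$overridden)
  }

  # --- simulate ------------------------------------------------------------
  sim <- NULL
  if (isTRUE(config$simulate)) {
    sim <- tryCatch({
      sim_cfg <- do.call(simulation_config,
                         utils::modifyList(list(rng_seed = config$rng_seed),
                                           config$sim))
      simulate_dataset(sim_cfg, file.path(outdir, "sim"))
    }, error = function(e) fail("simulate", e))
    config$fastq <- sim$paths$fastq
    config$genome <- sim$paths$genome
    config$ncrna <- sim$paths$ncrna
    config$catalogue <- sim$paths$catalogue
    if (is.null(config$preprocess$adapter_3p)) {
      config$preprocess$adapter_3p <- sim$config$adapter_3p
      config$preprocess$adapter_5p <- sim$config$adapter_5p
    }
    log_event("simulate", libraries = length(config$fastq),
              loci = nrow(sim$loci))
  }
  for (need in c("fastq", "genome", "ncrna", "catalogue")) {
    if (is.null(config[[need]])) {
      stop("pipeline input '", need, "' is not configured", call. = FALSE)
    }
  }

  # --- preprocess ----------------------------------------------------------
  pp <- config$preprocess
  clean <- tryCatch({
    out <- list()
    for (lib in names(config$fastq)) {
      raw <- read_raw_reads(config$fastq[[lib]])
      res <- trim_and_filter(raw, adapter_3p = pp$adapter_3p,
                             adapter_5p = pp$adapter_5p,
                             min_len = pp$min_len, max_len = pp$max_len,
                             quality_min = pp$quality_min,
                             repeat_max = pp$repeat_max,
                             seed_len = pp$seed_len,
                             discard_no_adapter = pp$discard_no_adapter)
      log_event("preprocess", library = lib, tally = as.list(res$log))
      out[[lib]] <- res$clean
    }
    out
  }, error = function(e) fail("preprocess", e))

  ut <- collapse_unique(clean)
  libs <- names(clean)
  sizes <- size_distribution(ut)

  # --- annotate ------------------------------------------------------------
  ann <- tryCatch({
    genome <- as_genome_set(read_fasta(config$genome))
    mg <- match_genome(ut$sequence, genome)
    matched_ut <- ut[ut$sequence %in% mg$matched, , drop = FALSE]
    nc <- filter_ncrna(matched_ut$sequence, read_fasta(config$ncrna),
                       min_identity = config$ncrna_identity)
    retained_ut <- matched_ut[matched_ut$sequence %in% nc$retained, , drop = FALSE]
    catalogue <- read_mirna_catalogue(config$catalogue)
    known <- assign_known(retained_ut$sequence, catalogue)
    log_event("annotate", unique_total = nrow(ut),
              genome_matched = length(mg$matched),
              ncrna_removed = length(nc$removed),
              known_assigned = nrow(known))
    list(genome = genome, mg = mg, matched_ut = matched_ut,
         retained_ut = retained_ut, known = known)
  }, error = function(e) fail("annotate", e))

  # --- discovery -----------------------------------------------------------
  disc <- tryCatch({
    discover_mirnas(ann$retained_ut, ann$genome,
                    known_sequences = ann$known$sequence,
                    params = config$mireap)
  }, error = function(e) fail("discovery", e))
  loci <- disc$loci
  passing <- loci[which(loci$structural_pass), , drop = FALSE]

  # --- expression ----------------------------------------------------------
  expr <- tryCatch({
    known_counts <- count_matrix(ut, ann$known$sequence, libs)
    rownames(known_counts) <- ann$known$name
    pass_counts <- count_matrix(ut, as_dna(passing$mature_seq), libs)
    rownames(pass_counts) <- passing$name
    denom <- colSums(known_counts) + colSums(pass_counts)
    if (any(denom == 0)) {
      stop("no miRNA-mapped reads in library ", libs[which(denom == 0)[1]])
    }
    known_rpm <- rpm_normalize(known_counts, denom)
    pass_rpm <- rpm_normalize(pass_counts, denom)
    status <- character(nrow(passing))
    for (i in seq_len(nrow(passing))) {
      cl <- classify_mirna(list(pass = TRUE, reasons = character(0)),
                           list(pass = TRUE, reason = NA_character_),
                           pass_rpm[i, ], passing$star_detected[i],
                           params = config$mireap)
      status[i] <- cl$status
    }
    log_event("expression", denominators = as.list(denom))
    list(denom = denom, known_rpm = known_rpm, pass_rpm = pass_rpm,
         status = status)
  }, error = function(e) fail("expression", e))

  novel_idx <- expr$status == "novel"
  cand_idx <- expr$status == "candidate"
  profiles <- rbind(
    if (nrow(expr$known_rpm)) expression_profiles(expr$known_rpm),
    if (nrow(expr$pass_rpm)) expression_profiles(expr$pass_rpm))
  comp <- if (any(novel_idx)) {
    composition_stats(passing$mature_seq[novel_idx])
  } else NULL

  # --- targets (optional) --------------------------------------------------
  targets <- NULL
  if (isTRUE(config$run_targets) && !is.null(config$transcripts)) {
    targets <- tryCatch({
      tx <- read_fasta(config$transcripts)
      mat <- stats::setNames(passing$mature_seq[novel_idx],
                             passing$name[novel_idx])
      predict_targets(mat, tx, params = config$targets)
    }, error = function(e) fail("targets", e))
  }

  # --- qPCR (optional) -----------------------------------------------------
  qpcr <- NULL
  if (!is.null(config$ct_table)) {
    qpcr <- tryCatch({
      ct <- read_ct_table(config$ct_table)
      rel <- delta_delta_ct(ct)
      rpm_all <- rbind(expr$known_rpm, expr$pass_rpm)
      conc <- platform_concordance(rel, rpm_all)
      list(relative = rel, concordance = conc)
    }, error = function(e) fail("qpcr", e))
  }

  # --- report --------------------------------------------------------------
  lib_stats <- data.frame(
    library = libs,
    clean_reads = vapply(clean, length, integer(1)),
    genome_matched_redundant = vapply(libs, function(l) {
      sum(ann$matched_ut[[l]])
    }, numeric(1)),
    genome_matched_unique = vapply(libs, function(l) {
      sum(ann$matched_ut[[l]] > 0)
    }, integer(1)))
  summary <- list(
    clean_reads_total = sum(lib_stats$clean_reads),
    unique_reads_total = nrow(ut),
    genome_matched_pct = round_half_up(
      100 * sum(lib_stats$genome_matched_redundant) /
        sum(lib_stats$clean_reads), 2),
    n_known = nrow(ann$known),
    n_loci_tested = nrow(loci),
    n_structural_pass = nrow(passing),
    n_novel = sum(novel_idx),
    n_candidate = sum(cand_idx),
    novel_5p_u_pct = if (!is.null(comp)) round_half_up(comp$five_prime[["U"]], 1),
    qpcr_r_squared = if (!is.null(qpcr)) qpcr$concordance$r_squared)
  paths <- list(
    library_stats = file.path(outdir, "library_stats.tsv"),
    unique_reads = file.path(outdir, "unique_reads.tsv"),
    size_distribution = file.path(outdir, "size_distribution.tsv"),
    known = file.path(outdir, "known_mirnas.tsv"),
    loci = file.path(outdir, "discovered_loci.tsv"),
    profiles = file.path(outdir, "expression_profiles.tsv"),
    summary = file.path(outdir, "summary.json"))
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(lib_stats, paths$library_stats)
  wt(ut, paths$unique_reads)
  wt(sizes, paths$size_distribution)
  wt(ann$known, paths$known)
  loci_out <- loci
  loci_out$status <- "rejected"
  loci_out$status[match(passing$name[novel_idx], loci_out$name)] <- "novel"
  loci_out$status[match(passing$name[cand_idx], loci_out$name)] <- "candidate"
  wt(loci_out, paths$loci)
  wt(profiles, paths$profiles)
  if (!is.null(targets)) {
    paths$targets <- file.path(outdir, "target_hits.tsv")
    wt(targets, paths$targets)
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_event("done", summary = summary)
  invisible(list(summary = summary,
                 tables = list(library_stats = lib_stats, unique_reads = ut,
                               known = ann$known, loci = loci_out,
                               profiles = profiles, targets = targets,
                               qpcr = qpcr),
                 paths = paths, sim = sim))
}

count_matrix <- function(ut, sequences, libs) {
  idx <- match(sequences, ut$sequence)
  m <- as.matrix(ut[idx, libs, drop = FALSE])
  m[is.na(m)] <- 0
  rownames(m) <- sequences
  storage.mode(m) <- "double"
  m
}

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*", "", names(x)))
}
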