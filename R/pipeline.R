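## End-to-end orchestration: simulate -> detect -> reorganize -> digest ->
## propagate, driven by a flat key-value config, with a machine-readable
## run manifest.

#' Default pipeline configuration
#'
#' All parameters with their defaults. A serialized config fully determines
#' a run given identical inputs. Keys:
#' stage toggles (`do_simulate`, `do_detect`, `do_reorganize`, `do_digest`,
#' `do_propagate`), simulator parameters (`strategy`, `genome_length`, `gc`,
#' `pac`, `headful_factor`, `headful_sd`, `series`, `dtr_length`,
#' `overhang_length`, `frag_mean`, `frag_sd`, `read_length`, `depth`),
#' detector thresholds (`min_top_count`, `min_ratio`, `p_tail`,
#' `dtr_coverage_factor`, `low_coverage_depth`), digest criteria
#' (`gel_min`, `gel_max`, `distinguish_tol`, `faint_max`), propagation
#' (`support_threshold`), inputs (`genome_fasta`, `alignments`, `tree`,
#' `tip_labels`, `enzyme_table`), `seed`, and output toggles (`write_fastq`,
#' `write_sam`).
#'
#' @return named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    do_simulate = TRUE, do_detect = TRUE, do_reorganize = TRUE,
    do_digest = TRUE, do_propagate = FALSE,
    strategy = "HEADFUL_PAC", genome_length = 86193, gc = 0.4907,
    pac = 1, headful_factor = 1.04, headful_sd = NA, series = 4,
    dtr_length = NA, overhang_length = 12,
    frag_mean = 550, frag_sd = 55, read_length = 251, depth = 200,
    min_top_count = 20, min_ratio = 5, p_tail = 1e-6,
    dtr_coverage_factor = 1.5, low_coverage_depth = 200,
    gel_min = 250, gel_max = 10000, distinguish_tol = 0.15, faint_max = 400,
    support_threshold = 95,
    genome_fasta = NA, alignments = NA, tree = NA, tip_labels = NA,
    enzyme_table = NA,
    seed = 1, write_fastq = FALSE, write_sam = FALSE)
}

#' Validate and complete a pipeline configuration
#'
#' @param raw a named list, YAML text, or a YAML file path; missing keys
#'   take their defaults, unknown keys are an error.
#' @return validated config list.
#' @export
validateConfig <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (file.exists(raw)) yaml::read_yaml(raw)
           else yaml::yaml.load(raw)
    if (is.null(raw)) raw <- list()
  }
  cfg <- defaultConfig()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(raw)] <- raw
  bad <- function(field, why) stop("config field '", field, "': ", why)
  if (!cfg$strategy %in% .STRATEGIES) bad("strategy", "unknown strategy")
  if (cfg$gc < 0 || cfg$gc > 1) bad("gc", "must lie in [0, 1]")
  if (cfg$genome_length < 1) bad("genome_length", "must be >= 1")
  if (cfg$headful_factor <= 1)
    bad("headful_factor", "H must exceed G (factor > 1)")
  if (cfg$pac < 1 || cfg$pac > cfg$genome_length)
    bad("pac", "must lie in 1..genome_length")
  if (cfg$depth <= 0) bad("depth", "must be positive")
  for (f in c("min_top_count", "min_ratio", "p_tail", "gel_min", "gel_max",
              "distinguish_tol", "faint_max", "frag_mean", "read_length"))
    if (cfg[[f]] <= 0) bad(f, "must be positive")
  if (cfg$support_threshold < 0 || cfg$support_threshold > 100)
    bad("support_threshold", "must lie in 0..100")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[pacscope] stage %-10s %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full inference pipeline
#'
#' Executes the enabled stages in order (simulate or load inputs, detect,
#' reorganize, digest, propagate), writes per-stage outputs under `outDir`
#' and returns (and writes) a run manifest with the headline results:
#' strategy call, pac position, peak ratios, top-ranked enzyme, propagation
#' summary and warnings. Re-running with an identical config reproduces
#' identical headline results.
#'
#' @param config list from [validateConfig()] (or anything it accepts).
#' @param outDir output directory, created if needed.
#' @return the manifest, invisibly also written to
#'   `file.path(outDir, "manifest.json")`.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("pacscope_run")) {
  cfg <- validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  manifest <- list(config = cfg, results = list(), warnings = character(0),
                   files = list())
  genome <- NULL
  alignments <- NULL
  truePac <- NA

  if (cfg$do_simulate) {
    sim <- .stage("simulate", {
      genome <- makeReference(cfg$genome_length, cfg$gc, seed = cfg$seed)
      spec <- PackagingSpec(
        cfg$strategy, genomeLength = cfg$genome_length,
        pacPosition = cfg$pac, headfulFactor = cfg$headful_factor,
        headfulSd = if (is.na(cfg$headful_sd)) NULL else cfg$headful_sd,
        seriesLength = cfg$series,
        dtrLength = if (is.na(cfg$dtr_length)) NULL else cfg$dtr_length,
        overhangLength = cfg$overhang_length)
      simulateShotgun(genome, spec, depth = cfg$depth,
                      fragMean = cfg$frag_mean, fragSd = cfg$frag_sd,
                      readLength = cfg$read_length, seed = cfg$seed,
                      withBases = cfg$write_fastq || cfg$write_sam)
    })
    genome <- simGenome(sim)
    alignments <- alignmentTable(sim)
    truePac <- cfg$pac
    fa <- file.path(outDir, "reference.fasta")
    writeGenomeFasta(genome, fa)
    writeMoleculeManifest(moleculeTable(sim),
                          file.path(outDir, "molecules.tsv"))
    writeAlignmentsTsv(alignments, file.path(outDir, "alignments.tsv"))
    if (cfg$write_sam)
      writeAlignmentsSam(readTable(sim), genome,
                         file.path(outDir, "reads.sam"))
    if (cfg$write_fastq)
      writeReadsFastq(readTable(sim), file.path(outDir, "reads_1.fastq"),
                      file.path(outDir, "reads_2.fastq"))
  } else {
    if (!is.na(cfg$genome_fasta))
      genome <- .stage("load_genome", readGenomeFasta(cfg$genome_fasta))
    if (!is.na(cfg$alignments)) {
      alignments <- .stage("load_alignments", {
        if (grepl("\\.tsv$", cfg$alignments))
          readAlignmentsTsv(cfg$alignments)
        else readAlignmentsSam(cfg$alignments,
                               if (is.null(genome)) NULL
                               else genomeLength(genome))
      })
    }
  }

  call <- NULL
  if (cfg$do_detect) {
    if (is.null(alignments)) stop("stage 'detect' failed: no alignments")
    G <- if (!is.null(genome)) genomeLength(genome) else cfg$genome_length
    profiles <- .stage("detect", computeSpc(alignments, G))
    params <- detectionParams(cfg$min_top_count, cfg$min_ratio, cfg$p_tail,
                              cfg$dtr_coverage_factor,
                              cfg$low_coverage_depth)
    call <- detectTermini(profiles, params)
    writeProfilesTsv(profiles, file.path(outDir, "spc_profiles.tsv"))
    writeTerminiCallJson(call, file.path(outDir, "termini_call.json"))
    manifest$results$strategy_call <- strategyCall(call)
    if (!is.null(pacSite(call))) {
      manifest$results$pac_position <- peakPosition(pacSite(call))
      manifest$results$pac_strand <- pacSite(call)@strand
      manifest$results$peak_ratio <- peakRatioValue(pacSite(call))
      manifest$results$junction_spanning_reads <-
        junctionSpanningReads(alignments, G, peakPosition(pacSite(call)))
    }
    manifest$results$mean_depth <- round(call@meanDepth, 2)
    if (call@lowCoverageWarning)
      manifest$warnings <- c(manifest$warnings,
                             "mean depth below 200x; pac detection unreliable")
    if (strategyCall(call) == "UNDETERMINED")
      manifest$warnings <- c(manifest$warnings, "zero alignments")
  }

  reorganized <- NULL
  if (cfg$do_reorganize && !is.null(call) && !is.null(pacSite(call)) &&
      !is.null(genome)) {
    reorganized <- .stage("reorganize", reorganize(
      genomeSequence(genome), peakPosition(pacSite(call)),
      pacSite(call)@strand))
    writeGenomeFasta(CircularGenome(reorganized,
                                    id = paste0(genome@id, "_pac")),
                     file.path(outDir, "reorganized.fasta"))
  }

  if (cfg$do_digest && !is.null(reorganized)) {
    reports <- .stage("digest", {
      enzymes <- if (!is.na(cfg$enzyme_table))
        readEnzymeTable(cfg$enzyme_table) else builtinEnzymes()
      selectEnzymes(reorganized, enzymes, gelMin = cfg$gel_min,
                    gelMax = cfg$gel_max,
                    distinguishTol = cfg$distinguish_tol,
                    faintMax = cfg$faint_max)
    })
    summ <- digestSummary(reports)
    write.table(summ, file.path(outDir, "digest_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summ, file.path(outDir, "digest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$results$chosen_enzyme <- summ$enzyme[1]
    manifest$results$chosen_pac_fragment <- summ$pac_fragment[1]
    if (any(summ$flags == "NO_SITES"))
      manifest$warnings <- c(manifest$warnings,
                             "an enzyme has no sites (NO_SITES)")
  }

  if (cfg$do_propagate && !is.na(cfg$tree)) {
    prop <- .stage("propagate", {
      labels <- read.table(cfg$tip_labels, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
      lt <- readLabeledTree(cfg$tree, labels)
      propagateLabels(lt, cfg$support_threshold)
    })
    rep <- cladeReport(prop, NULL)
    write.table(rep, file.path(outDir, "clade_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$results$propagation <- list(
      n_strategies = nrow(rep),
      n_conflicts = nrow(propagationConflicts(prop)),
      n_unassigned = length(unassignedTips(prop)))
    if (nrow(propagationConflicts(prop)) > 0)
      manifest$warnings <- c(manifest$warnings,
                             "impure strategy clade (no propagation)")
  }

  files <- list.files(outDir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
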