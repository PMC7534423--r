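#' Run the full terminus-validation workflow
#'
#' Wires the stages end to end: discover terminal repeat units on the
#' assembly (or accept a known unit), locate interstitial loci, build the
#' unique-k-mer anchor index, length-filter the reads, classify every read,
#' summarise per-arm telomere support, and call the assembly's own termini.
#' All outputs are deterministic given inputs and parameters.
#'
#' Files written to `out_dir`: `units.fa` (per-terminus consensus units),
#' `arrays.bed` (BED6 of assembly arrays; score = 1000 x identity),
#' `interstitial.tsv`, `classifications.tsv`, `table2.tsv` (per-arm support
#' with mean read length in kb), `termini.tsv`, `manifest.json`.
#'
#' If the assembly shows no terminal periodicity and no unit is supplied,
#' every read is reported as `no_array` and the run still succeeds.
#'
#' @param assembly Path to an assembly FASTA, or a named `DNAStringSet`.
#' @param reads Path to reads FASTA/FASTQ, or a named `DNAStringSet`.
#' @param out_dir Output directory (created if needed).
#' @param unit Optional known unit (character or [RepeatUnit-class]); skips
#'   discovery, as when validating with a published telomere repeat.
#' @param min_read_length Strict read length filter in bp (default 40,000).
#' @param window_bp,min_period,max_period,min_match Discovery parameters
#'   (see [discoverTerminalUnits()]).
#' @param terminal_tolerance_reads,terminal_tolerance_assembly Terminal
#'   tolerances in bp for reads (500) and assembly termini (1000).
#' @param interstitial_min_distance See [findInterstitialLoci()].
#' @param min_chimera_span,flank_window See [classifyRead()].
#' @param anchor_k Anchor k-mer size (default 21).
#' @param min_identity_reads,min_identity_assembly Array identity floors.
#' @param min_copies Array copy-number floor.
#' @param verbose Log progress to standard error.
#' @return Invisibly, a list with the in-memory results (`unit`, `units`,
#'   `arrays`, `interstitial`, `classifications`, `support`, `termini`) and
#'   `files` (the paths written).
#' @export
runPipeline <- function(assembly, reads, out_dir, unit = NULL,
                        min_read_length = 40000L, window_bp = 20000L,
                        min_period = 6L, max_period = 2000L, min_match = 0.8,
                        terminal_tolerance_reads = 500L,
                        terminal_tolerance_assembly = 1000L,
                        interstitial_min_distance = 10000L,
                        min_chimera_span = 10000L, flank_window = 5000L,
                        anchor_k = 21L, min_identity_reads = 0.75,
                        min_identity_assembly = 0.9, min_copies = 3,
                        verbose = TRUE) {
  log <- function(...) if (verbose) message("[telotru] ", ...)
  params <- list(min_read_length = min_read_length, window_bp = window_bp,
    min_period = min_period, max_period = max_period, min_match = min_match,
    terminal_tolerance_reads = terminal_tolerance_reads,
    terminal_tolerance_assembly = terminal_tolerance_assembly,
    interstitial_min_distance = interstitial_min_distance,
    min_chimera_span = min_chimera_span, flank_window = flank_window,
    anchor_k = anchor_k, min_identity_reads = min_identity_reads,
    min_identity_assembly = min_identity_assembly, min_copies = min_copies)

  inputDigests <- list()
  if (is.character(assembly)) {
    inputDigests$assembly <- fileDigest(assembly)
    assembly <- withStage("seq_io", readSequences(assembly))
  }
  if (is.character(reads)) {
    inputDigests$reads <- fileDigest(reads)
    reads <- withStage("seq_io", readSequences(reads))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(out_dir, x)

  if (!is.null(unit) && !is(unit, "RepeatUnit")) unit <- RepeatUnit(unit)
  units <- list()
  if (is.null(unit)) {
    log("discovering terminal repeat units")
    units <- withStage("discovery", discoverTerminalUnits(assembly,
      window_bp = window_bp, min_period = min_period,
      max_period = max_period, min_match = min_match))
    if (length(units)) {
      canon <- vapply(units, unitCanonical, character(1))
      tab <- sort(table(canon), decreasing = TRUE)
      unit <- RepeatUnit(names(tab)[1L],
        variants = unlist(lapply(units, unitVariants), use.names = FALSE))
      log("consensus unit: ", unitCanonical(unit), " (",
        unitLength(unit), " bp)")
    } else log("no terminal periodicity found")
  }
  if (length(units)) {
    us <- Biostrings::DNAStringSet(vapply(units, unitCanonical, character(1)))
    writeSequences(us, f("units.fa"))
  } else if (!is.null(unit)) {
    us <- Biostrings::DNAStringSet(stats::setNames(unitCanonical(unit),
      "unit"))
    writeSequences(us, f("units.fa"))
  } else file.create(f("units.fa"))

  readIds <- names(reads)
  if (is.null(readIds)) readIds <- paste0("read", seq_along(reads))
  readsF <- withStage("classification",
    filterReadsByLength(reads, min_read_length))
  log(length(readsF), " of ", length(reads), " reads pass the >",
    min_read_length, " bp filter")

  if (is.null(unit)) {
    arrays <- GenomicRanges::GRanges()
    interstitial <- GenomicRanges::GRanges()
    cls <- data.frame(read_id = names(readsF),
      read_length = Biostrings::width(readsF), label = "no_array",
      arm = NA_character_, array_start = NA_integer_,
      array_end = NA_integer_, copy_number = NA_real_, identity = NA_real_,
      segments = "", stringsAsFactors = FALSE)
    termini <- data.frame(seq_id = rep(names(assembly), each = 2L),
      which_end = rep(c("start", "end"), length(assembly)),
      has_terminal_array = FALSE, array_start = NA_integer_,
      array_end = NA_integer_, distance_to_terminus = NA_integer_,
      stringsAsFactors = FALSE)
  } else {
    log("annotating assembly arrays")
    arrays <- withStage("array_annotation", {
      perChrom <- lapply(seq_along(assembly), function(i)
        annotateArrays(assembly[[i]], unit,
          min_identity = min_identity_assembly, min_copies = min_copies,
          seq_id = names(assembly)[i]))
      perChrom <- perChrom[vapply(perChrom, length, integer(1)) > 0L]
      if (length(perChrom)) suppressWarnings(do.call(c, perChrom))
      else GenomicRanges::GRanges()
    })
    interstitial <- withStage("array_annotation", findInterstitialLoci(
      assembly, unit, interstitial_min_distance = interstitial_min_distance,
      min_identity = min_identity_assembly, min_copies = min_copies))
    log(length(interstitial), " interstitial locus/loci")
    log("building anchor index (k=", anchor_k, ")")
    index <- withStage("classification", buildAnchorIndex(assembly, anchor_k))
    log("classifying ", length(readsF), " reads")
    cls <- withStage("classification", classifyReads(readsF, unit, index,
      interstitial, terminal_tolerance = terminal_tolerance_reads,
      min_chimera_span = min_chimera_span, flank_window = flank_window,
      min_identity = min_identity_reads, min_copies = min_copies))
    termini <- withStage("discovery", callAssemblyTermini(assembly, unit,
      terminal_tolerance = terminal_tolerance_assembly,
      min_identity = min_identity_assembly, min_copies = min_copies))
  }
  support <- summarizeSupport(cls, arms = names(assembly),
    min_length_note = min_read_length)

  writeBed(arrays, f("arrays.bed"))
  writeTsv(grToTsv(interstitial), f("interstitial.tsv"))
  writeTsv(cls, f("classifications.tsv"))
  writeSupportTable(support, f("table2.tsv"))
  writeTsv(termini, f("termini.tsv"))
  manifest <- list(tool = "telotru",
    version = as.character(utils::packageVersion("telotru")),
    params = params, inputs = inputDigests,
    created = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  log("done; outputs in ", out_dir)
  invisible(list(unit = unit, units = units, arrays = arrays,
    interstitial = interstitial, classifications = cls, support = support,
    termini = termini,
    files = vapply(c("units.fa", "arrays.bed", "interstitial.tsv",
      "classifications.tsv", "table2.tsv", "termini.tsv", "manifest.json"),
      f, character(1))))
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE))
}

fileDigest <- function(path) {
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

grToTsv <- function(gr) {
  if (!length(gr))
    return(data.frame(seq_id = character(0), start = integer(0),
      end = integer(0), strand = character(0)))
  df <- as.data.frame(gr)
  names(df)[names(df) == "seqnames"] <- "seq_id"
  df$width <- NULL
  df
}

# per-arm support table in the published style: mean length in kb, 2 dp
writeSupportTable <- function(support, path) {
  out <- support
  out$mean_read_length_kb <- ifelse(is.na(out$mean_read_length), "",
    sprintf("%.2f", out$mean_read_length / 1000))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  fn <- attr(support, "footnote")
  if (!is.null(fn)) writeLines(paste0("# ", fn), con)
  invisible(path)
}
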