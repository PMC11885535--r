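#' Run the full screen analysis pipeline
#'
#' Executes demultiplex -> count -> score -> contrast, skipping stages
#' whose outputs are supplied directly (a precomputed count matrix skips
#' the read stages). Writes every intermediate as TSV into \code{outDir}
#' together with a JSON run manifest recording the package version, every
#' resolved parameter, input file digests, stage timings and all warnings
#' emitted — enough to replay the run exactly.
#'
#' @param config a named list (or path to a YAML file holding one) with
#'   entries: \code{manifest} (guide library TSV, required),
#'   \code{sample_sheet} (TSV, required), and either \code{counts} (count
#'   matrix TSV) or \code{fastq} (FASTQ path(s)); optional parameters
#'   \code{barcode_offset} (0), \code{max_mismatch} (0),
#'   \code{count_mode} ("scan" or an integer offset), \code{pseudocount}
#'   (1), \code{lfc_space} ("log2"), \code{z_population} ("all"),
#'   \code{ttest} ("welch"), \code{z_thresh} (1), \code{fdr_thresh}
#'   (0.05), \code{pool_cell_lines} (FALSE).
#' @param outDir output directory, created if needed.
#' @return Invisibly, a list with the \code{contrast} data.frame, the
#'   \linkS4class{GeneScores}, the \linkS4class{ScreenCounts} and the run
#'   manifest; all also on disk under \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(barcode_offset = 0L, max_mismatch = 0L,
                   count_mode = "scan", pseudocount = 1,
                   lfc_space = "log2", z_population = "all",
                   ttest = "welch", z_thresh = 1, fdr_thresh = 0.05,
                   pool_cell_lines = FALSE)
  config <- utils::modifyList(defaults, config)
  for (key in c("manifest", "sample_sheet"))
    if (is.null(config[[key]]))
      stop("config entry '", key, "' is required")
  if (is.null(config$counts) && is.null(config$fastq))
    stop("config must name either 'counts' or 'fastq'")

  warnings_seen <- character()
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      message("[warn] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lib <- timed("load_manifest", readGuideLibrary(config$manifest))
  design <- timed("load_sample_sheet", readSampleSheet(config$sample_sheet))

  if (!is.null(config$counts)) {
    counts <- timed("load_counts", readCountMatrix(config$counts, lib))
  } else {
    demux <- timed("demultiplex", demultiplexReads(
      config$fastq, design, barcodeOffset = config$barcode_offset,
      maxMismatch = config$max_mismatch))
    writeDemuxReport(demux$report, file.path(outDir, "demux_report.tsv"))
    mode <- config$count_mode
    if (!identical(mode, "scan")) mode <- as.integer(mode)
    counts <- timed("count", countScreen(demux, lib, design,
                                         spacerOffset = mode))
  }
  writeCountMatrix(counts, file.path(outDir, "counts.tsv"))

  scores <- timed("score", scoreScreen(
    counts, lib, design, pseudocount = config$pseudocount,
    space = config$lfc_space, zPopulation = config$z_population))
  writeGeneScores(scores, file.path(outDir, "gene"))

  result <- timed("contrast", contrastEnvironments(
    scores, design, zThresh = config$z_thresh,
    fdrThresh = config$fdr_thresh, ttest = config$ttest,
    poolCellLines = config$pool_cell_lines))
  writeContrastResult(result, file.path(outDir, "contrast.tsv"))
  utils::write.table(makeScatterData(result),
                     file.path(outDir, "scatter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  inputs <- unlist(config[c("manifest", "sample_sheet", "counts", "fastq")])
  manifest <- list(
    tool = "screendiff",
    version = as.character(utils::packageVersion("screendiff")),
    parameters = config[setdiff(names(config),
                                c("manifest", "sample_sheet", "counts",
                                  "fastq"))],
    inputs = lapply(stats::setNames(as.list(inputs), names(inputs)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    stage_seconds = timings,
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline complete: ", nrow(result), " (cell line, gene) rows")
  invisible(list(contrast = result, scores = scores, counts = counts,
                 manifest = manifest))
}

#' Write a contrast result table to TSV
#' @param result data.frame from [contrastEnvironments()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContrastResult <- function(result, path) {
  out <- result
  out$hit_class <- as.character(out$hit_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contrast result table written by [writeContrastResult()]
#' @param path TSV path.
#' @return data.frame with \code{hit_class} restored as a factor.
#' @export
readContrastResult <- function(path) {
  out <- utils::read.delim(path, header = TRUE)
  out$hit_class <- factor(out$hit_class, levels = HIT_CLASSES)
  out
}
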