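#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, guides as rows (rownames = guide IDs),
#'   samples as columns (colnames = sample IDs).
#' @param totalReads per-sample totals (all reads seen, assigned plus
#'   unassigned). Defaults to the column sums, i.e. no unassigned reads.
#' @param library optional \linkS4class{GuideLibrary}; when given, row
#'   order and annotation are taken from it and unknown guide IDs are an
#'   error.
#' @return A \linkS4class{ScreenCounts}.
#' @export
ScreenCounts <- function(counts, totalReads = colSums(counts),
                         library = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  rowdat <- DataFrame(guide_id = rownames(counts))
  if (!is.null(library)) {
    unknown <- setdiff(rownames(counts), library@guides$guide_id)
    if (length(unknown))
      stop("guide IDs not in manifest: ", paste(unknown, collapse = ", "))
    counts <- counts[match(library@guides$guide_id, rownames(counts)),
                     , drop = FALSE]
    counts[is.na(counts)] <- 0L
    rownames(counts) <- library@guides$guide_id
    rowdat <- library@guides
  }
  cd <- DataFrame(sample_id = colnames(counts),
                  total_reads = as.numeric(totalReads),
                  assigned_reads = as.numeric(colSums(counts)),
                  row.names = colnames(counts))
  new("ScreenCounts",
      SummarizedExperiment(assays = list(counts = counts),
                           rowData = rowdat, colData = cd))
}

#' @describeIn ScreenCounts the count assay
#' @param object a \linkS4class{ScreenCounts}.
#' @export
guideCounts <- function(object) assay(object, "counts")

#' @export
setMethod("show", "ScreenCounts", function(object) {
  cat("ScreenCounts:", nrow(object), "guides x", ncol(object), "samples;",
      "median assignment rate",
      sprintf("%.3f", stats::median(colData(object)$assigned_reads /
                                      pmax(colData(object)$total_reads, 1))),
      "\n")
})

## ---- FASTQ helpers ----

# Biostrings warns when metadata columns are dropped while it assembles a
# QualityScaledDNAStringSet from FASTQ; that drop is intended here.
muffleMcolsWarning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns .* dropped", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

readFastq <- function(path) {
  muffleMcolsWarning(Biostrings::readQualityScaledDNAStringSet(path))
}

writeFastq <- function(reads, path) {
  muffleMcolsWarning(
    Biostrings::writeXStringSet(reads, path, format = "fastq",
                                qualities = Biostrings::quality(reads)))
  invisible(path)
}

hammingToBarcode <- function(region, barcode) {
  L <- nchar(barcode)
  mism <- integer(length(region))
  for (i in seq_len(L))
    mism <- mism + (substr(region, i, i) != substr(barcode, i, i))
  mism[nchar(region) < L] <- L + 1L  # too-short reads never match
  mism
}

#' Demultiplex pooled screen reads by inline barcode
#'
#' Routes each read to the unique sample whose inline barcode matches the
#' read at \code{barcodeOffset} within \code{maxMismatch} mismatches.
#' Reads matching no barcode, or more than one within tolerance, go to the
#' \code{"unmatched"} stream. The report conserves reads exactly: the
#' per-sample tallies plus the unmatched tally sum to the input read count.
#'
#' @param fastq path(s) to FASTQ file(s) (plain or gzip), pooled reads.
#' @param design a \linkS4class{ScreenDesign} whose samples carry
#'   non-empty barcodes of one common length.
#' @param barcodeOffset 0-based offset of the barcode within the read.
#' @param maxMismatch 0 (default) or 1 mismatches tolerated per barcode.
#' @param outDir directory for per-sample FASTQ files (created); when
#'   \code{NULL} no files are written and reads are returned in memory.
#' @return A list with \code{assignments} (named list of
#'   \code{QualityScaledDNAStringSet}, one per sample plus
#'   \code{"unmatched"}), \code{files} (paths, when \code{outDir} given)
#'   and \code{report}: a data.frame of per-sample read tallies and
#'   assignment rates plus one \code{"unmatched"} row.
#' @export
demultiplexReads <- function(fastq, design, barcodeOffset = 0L,
                             maxMismatch = 0L, outDir = NULL) {
  stopifnot(is(design, "ScreenDesign"), barcodeOffset >= 0L,
            maxMismatch %in% c(0L, 1L))
  s <- sampleSheet(design)
  bcs <- s$barcode
  if (any(bcs == "")) stop("all samples need a barcode for demultiplexing")
  if (length(unique(nchar(bcs))) != 1L)
    stop("barcodes must all have the same length")
  L <- nchar(bcs[1L])

  reads <- do.call(c, lapply(fastq, readFastq))
  n <- length(reads)
  if (n == 0L) warning("no reads in input FASTQ")
  region <- substr(as.character(reads), barcodeOffset + 1L,
                   barcodeOffset + L)

  if (maxMismatch == 0L) {
    hit <- match(region, bcs)  # barcodes are unique, so at most one hit
  } else {
    mism <- vapply(bcs, function(b) hammingToBarcode(region, b),
                   integer(n))
    mism <- matrix(mism, nrow = n)
    within <- mism <= maxMismatch
    nhit <- rowSums(within)
    hit <- ifelse(nhit == 1L, max.col(within * 1L, ties.method = "first"), NA)
    hit[nhit != 1L] <- NA  # ambiguous or unmatched
  }

  groups <- c(s$sample_id, "unmatched")
  key <- ifelse(is.na(hit), "unmatched", s$sample_id[hit])
  assignments <- lapply(groups, function(g) reads[key == g])
  names(assignments) <- groups

  tallies <- vapply(assignments, length, integer(1))
  report <- data.frame(
    sample_id = groups,
    barcode = c(bcs, ""),
    reads = as.integer(tallies),
    assignment_rate = if (n > 0) as.numeric(tallies) / n else 0,
    row.names = NULL)
  stopifnot(sum(report$reads) == n)

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- stats::setNames(
      file.path(outDir, paste0(groups, ".fastq")), groups)
    for (g in groups) writeFastq(assignments[[g]], files[[g]])
  }
  list(assignments = assignments, files = files, report = report)
}

#' Count guide occurrences in one sample's reads
#'
#' Assigns reads to guides by exact (zero-mismatch) matching of the 20-nt
#' protospacer. In \code{"scan"} mode (default) every 20-mer window of the
#' read is searched, which tolerates variable-length vector flanks; in
#' fixed-offset mode only the 20-mer starting at \code{spacerOffset}
#' (0-based) is compared. A read increments exactly one guide; reads
#' matching no guide are tallied as unassigned and, in scan mode, reads
#' matching two or more guides are discarded as ambiguous. Reads shorter
#' than the required window are unassigned, never an error.
#'
#' @param reads a \code{DNAStringSet}/\code{QualityScaledDNAStringSet},
#'   character vector of read sequences, or path(s) to FASTQ file(s).
#' @param library a validated \linkS4class{GuideLibrary}.
#' @param spacerOffset \code{"scan"} (default) or a 0-based integer offset.
#' @param bothStrands also match the reverse complement of each read
#'   (default \code{FALSE}; amplicon orientation is fixed by the primer
#'   scheme).
#' @return A list: \code{counts} named integer vector over guides,
#'   \code{unassigned} and \code{ambiguous} read tallies, \code{total}
#'   input read count.
#' @export
countGuides <- function(reads, library, spacerOffset = "scan",
                        bothStrands = FALSE) {
  stopifnot(is(library, "GuideLibrary"))
  if (is.character(reads) && length(reads) &&
      all(file.exists(reads)) && any(grepl("\\.(fastq|fq)(\\.gz)?$", reads)))
    reads <- do.call(c, lapply(reads, function(p)
      Biostrings::readDNAStringSet(p, format = "fastq")))
  seqs <- as.character(reads)
  sp <- protospacers(library)
  n <- length(seqs)
  counts <- stats::setNames(integer(nGuides(library)), names(sp))
  if (n == 0L)
    return(list(counts = counts, unassigned = 0L, ambiguous = 0L, total = 0L))

  if (identical(spacerOffset, "scan")) {
    subject <- Biostrings::DNAStringSet(seqs)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(unname(sp)))
    hits <- Biostrings::vwhichPDict(pd, subject)
    if (bothStrands) {
      rc <- Biostrings::reverseComplement(subject)
      hits_rc <- Biostrings::vwhichPDict(pd, rc)
      hits <- mapply(function(a, b) unique(c(a, b)), hits, hits_rc,
                     SIMPLIFY = FALSE)
    }
    nhit <- lengths(hits)
    one <- nhit == 1L
    idx <- as.integer(unlist(hits[one], use.names = FALSE))
    tab <- tabulate(idx, nbins = length(sp))
    counts[] <- tab
    ambiguous <- sum(nhit > 1L)
    unassigned <- sum(nhit == 0L)
  } else {
    off <- as.integer(spacerOffset)
    stopifnot(off >= 0L)
    window <- substr(seqs, off + 1L, off + 20L)
    window[nchar(window) < 20L] <- NA
    hit <- match(window, unname(sp))
    if (bothStrands) {
      rcw <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(ifelse(is.na(window), strrep("N", 20),
                                        window))))
      hit2 <- match(rcw, unname(sp))
      hit <- ifelse(is.na(hit), hit2, hit)
    }
    tab <- tabulate(hit[!is.na(hit)], nbins = length(sp))
    counts[] <- tab
    ambiguous <- 0L
    unassigned <- sum(is.na(hit))
  }
  list(counts = counts, unassigned = as.integer(unassigned),
       ambiguous = as.integer(ambiguous), total = n)
}

#' Build a count matrix from demultiplexed reads
#'
#' Runs [countGuides()] per sample and assembles a
#' \linkS4class{ScreenCounts} whose \code{total_reads} are the per-sample
#' read totals seen by the demultiplexer (assigned plus unassigned).
#'
#' @param demux result of [demultiplexReads()] (or a named list of
#'   per-sample read sets; the \code{"unmatched"} entry is ignored).
#' @param library a \linkS4class{GuideLibrary}.
#' @param design a \linkS4class{ScreenDesign} giving sample order.
#' @param ... passed to [countGuides()].
#' @return A \linkS4class{ScreenCounts}.
#' @export
countScreen <- function(demux, library, design, ...) {
  reads <- if (is.list(demux) && !is.null(demux$assignments))
    demux$assignments else demux
  ids <- sampleSheet(design)$sample_id
  mat <- matrix(0L, nGuides(library), length(ids),
                dimnames = list(library@guides$guide_id, ids))
  totals <- stats::setNames(numeric(length(ids)), ids)
  for (sid in ids) {
    res <- countGuides(reads[[sid]], library, ...)
    mat[, sid] <- res$counts
    totals[sid] <- res$total
  }
  ScreenCounts(mat, totalReads = totals, library = library)
}

## ---- count matrix TSV I/O ----

#' Write a ScreenCounts matrix to TSV
#'
#' Guides as rows, a header row of sample IDs, and two trailing comment
#' lines \code{#total_reads} and \code{#assigned_reads} carrying the
#' per-sample totals.
#'
#' @param object a \linkS4class{ScreenCounts}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(object, path) {
  stopifnot(is(object, "ScreenCounts"))
  m <- guideCounts(object)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("guide_id", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE)
  cd <- colData(object)
  writeLines(paste(c("#total_reads", cd$total_reads), collapse = "\t"), con)
  writeLines(paste(c("#assigned_reads", cd$assigned_reads),
                   collapse = "\t"), con)
  invisible(path)
}

#' Read a guide-by-sample count matrix from TSV
#'
#' Accepts the format written by [writeCountMatrix()]: guides as rows,
#' header of sample IDs, optional \code{#total_reads} footer. When totals
#' are absent they default to the assigned (column-sum) reads with a
#' warning, since the unassigned fraction is then unknown.
#'
#' @param path TSV path.
#' @param library optional \linkS4class{GuideLibrary} used to validate and
#'   order guide IDs; unknown IDs are a hard error listing them.
#' @return A \linkS4class{ScreenCounts}.
#' @export
readCountMatrix <- function(path, library = NULL) {
  if (!file.exists(path)) stop("count matrix not found: ", path)
  lines <- readLines(path)
  foot <- grepl("^#", lines)
  body <- lines[!foot]
  tab <- utils::read.delim(text = body, header = TRUE, row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("count matrix cells must be non-negative integers")
  storage.mode(m) <- "integer"
  totals <- colSums(m)
  tot_line <- lines[grepl("^#total_reads\t", lines)]
  if (length(tot_line) == 1L) {
    vals <- strsplit(tot_line, "\t")[[1]][-1]
    totals <- as.numeric(vals)
  } else {
    warning("no #total_reads footer; assuming total_reads == assigned_reads")
  }
  ScreenCounts(m, totalReads = totals, library = library)
}

#' Write a demultiplexing report to TSV
#' @param report the \code{report} data.frame from [demultiplexReads()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDemuxReport <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
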