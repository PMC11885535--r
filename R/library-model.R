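#' Construct a GuideLibrary from a data frame
#'
#' @param guides data.frame (or DataFrame) with columns \code{guide_id},
#'   \code{gene}, \code{protospacer}, \code{is_control}. \code{is_control}
#'   may be logical or one of 0/1/"true"/"false". Extra columns are dropped
#'   with a warning.
#' @return A validated \linkS4class{GuideLibrary}.
#' @examples
#' lib <- GuideLibrary(data.frame(
#'   guide_id = c("g1", "g2"), gene = c("PTEN", "PTEN"),
#'   protospacer = c(strrep("A", 20), strrep("C", 20)),
#'   is_control = FALSE))
#' nGuides(lib)
#' @export
GuideLibrary <- function(guides) {
  guides <- as.data.frame(guides)
  need <- c("guide_id", "gene", "protospacer", "is_control")
  miss <- setdiff(need, colnames(guides))
  if (length(miss))
    stop("guide table is missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(guides), need)
  if (length(extra))
    warning("ignoring extra guide table columns: ",
            paste(extra, collapse = ", "))
  guides <- guides[, need]
  guides$guide_id <- as.character(guides$guide_id)
  guides$gene <- as.character(guides$gene)
  guides$protospacer <- toupper(as.character(guides$protospacer))
  guides$is_control <- parseFlag(guides$is_control)
  new("GuideLibrary", guides = DataFrame(guides))
}

parseFlag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out)) stop("is_control values must be 0/1/true/false")
  out
}

#' Read an sgRNA library manifest from TSV
#'
#' The manifest is a tab-separated file with a header row naming
#' \code{guide_id}, \code{gene}, \code{protospacer} and \code{is_control}.
#' Malformed protospacers are reported with their line numbers; duplicate
#' identifiers or protospacers are hard errors naming the offenders.
#'
#' @param path path to the TSV manifest.
#' @return A validated \linkS4class{GuideLibrary}.
#' @seealso [writeGuideLibrary()] for the inverse.
#' @export
readGuideLibrary <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  need <- c("guide_id", "gene", "protospacer", "is_control")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("manifest header must name ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "))
  sp <- toupper(tab$protospacer)
  bad <- which(nchar(sp) != 20L | grepl("[^ACGT]", sp))
  if (length(bad))
    stop("malformed protospacer (must be 20 bases of A/C/G/T) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  GuideLibrary(tab)
}

#' Write a GuideLibrary manifest to TSV
#' @param library a \linkS4class{GuideLibrary}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGuideLibrary <- function(library, path) {
  stopifnot(is(library, "GuideLibrary"))
  tab <- as.data.frame(library@guides)
  tab$is_control <- ifelse(tab$is_control, "true", "false")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the exact-match reference for guide assignment
#'
#' One FASTA record per guide, ID the guide identifier and sequence its
#' 20-nt protospacer. Reads are later assigned by exact (zero-mismatch)
#' matching against these sequences, which for unique 20-mers is equivalent
#' to ungapped alignment with no mismatches allowed.
#'
#' @param library a \linkS4class{GuideLibrary}; refusing empty libraries.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeGuideReference <- function(library, path) {
  stopifnot(is(library, "GuideLibrary"))
  if (nGuides(library) == 0L)
    stop("refusing to write an empty reference")
  seqs <- Biostrings::DNAStringSet(protospacers(library))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

## ---- accessors ----

#' @describeIn GuideLibrary-accessors number of guides in the library
#' @export
nGuides <- function(library) nrow(library@guides)

#' Accessors for GuideLibrary
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @name GuideLibrary-accessors
#' @return \code{nGuides}/\code{nGenes}/\code{guidesPerGene}/\code{nControls}
#'   return integers; \code{protospacers} a named character vector
#'   (names are guide IDs); \code{guideGenes} the per-guide gene labels with
#'   controls grouped into pseudo-genes; \code{isControl} the logical
#'   control flag per guide.
NULL

#' @describeIn GuideLibrary-accessors number of targeting genes
#' @export
nGenes <- function(library) {
  length(unique(library@guides$gene[!library@guides$is_control]))
}

#' @describeIn GuideLibrary-accessors guides per targeting gene
#' @export
guidesPerGene <- function(library) {
  g <- library@guides
  if (all(g$is_control)) return(0L)
  as.integer(table(g$gene[!g$is_control])[1L])
}

#' @describeIn GuideLibrary-accessors number of non-targeting control guides
#' @export
nControls <- function(library) sum(library@guides$is_control)

#' @describeIn GuideLibrary-accessors named protospacer vector
#' @export
protospacers <- function(library) {
  stats::setNames(library@guides$protospacer, library@guides$guide_id)
}

#' @describeIn GuideLibrary-accessors logical control flag per guide
#' @export
isControl <- function(library) {
  stats::setNames(library@guides$is_control, library@guides$guide_id)
}

#' @describeIn GuideLibrary-accessors per-guide gene label with controls
#'   grouped into pseudo-genes (\code{CTRL_PG01}, ...) of
#'   \code{guidesPerGene} guides each, in manifest order
#' @export
guideGenes <- function(library) {
  g <- library@guides
  gene <- g$gene
  k <- guidesPerGene(library)
  if (k == 0L) k <- sum(g$is_control)  # all-control library: one pseudo-gene
  ctrl <- which(g$is_control)
  if (length(ctrl)) {
    block <- ceiling(seq_along(ctrl) / k)
    gene[ctrl] <- sprintf("CTRL_PG%02d", block)
  }
  stats::setNames(gene, g$guide_id)
}

#' @export
setMethod("show", "GuideLibrary", function(object) {
  cat("GuideLibrary with", nGuides(object), "guides:",
      nGenes(object), "genes x", guidesPerGene(object), "guides +",
      nControls(object), "non-targeting controls\n")
})

## ---- sample sheet ----

#' Construct a ScreenDesign from a data frame
#'
#' @param samples data.frame (or DataFrame) with columns \code{sample_id},
#'   \code{cell_line}, \code{environment} (one of initial/in_vitro/in_vivo),
#'   \code{replicate}, \code{barcode}, \code{paired_initial_id}.
#' @return A validated \linkS4class{ScreenDesign}.
#' @export
ScreenDesign <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "cell_line", "environment", "replicate",
            "barcode", "paired_initial_id")
  miss <- setdiff(need, colnames(samples))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  samples <- samples[, need]
  for (col in c("sample_id", "cell_line", "environment", "barcode",
                "paired_initial_id")) {
    samples[[col]] <- as.character(samples[[col]])
    samples[[col]][is.na(samples[[col]])] <- ""
  }
  samples$barcode <- toupper(samples$barcode)
  samples$replicate <- as.integer(samples$replicate)
  new("ScreenDesign", samples = DataFrame(samples))
}

#' Read a sample sheet from TSV
#'
#' @param path TSV with header columns \code{sample_id}, \code{cell_line},
#'   \code{environment}, \code{replicate}, \code{barcode},
#'   \code{paired_initial_id} (empty for initial samples).
#' @return A validated \linkS4class{ScreenDesign}.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  ScreenDesign(tab)
}

#' Write a ScreenDesign to TSV
#' @param design a \linkS4class{ScreenDesign}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(design, path) {
  stopifnot(is(design, "ScreenDesign"))
  utils::write.table(as.data.frame(design@samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a full multi-environment screen design
#'
#' Builds the sample sheet for a screen in which each cell line is
#' independently infected in \code{replicates} replicate cultures; each
#' replicate yields one initial sample (harvested before selection), one
#' in vitro sample (after continued culture) and \code{micePerReplicate}
#' in vivo samples (one per xenograft). Every selected sample is paired to
#' its replicate's initial sample. Inline barcodes are assigned
#' deterministically with pairwise Hamming distance of at least 3.
#'
#' @param cellLines character vector of cell line names.
#' @param replicates replicate infections per cell line.
#' @param micePerReplicate xenografts seeded per replicate culture.
#' @param barcodeLength length of the generated inline barcodes.
#' @return A \linkS4class{ScreenDesign} with
#'   \code{length(cellLines) * replicates} initial and in vitro samples and
#'   \code{length(cellLines) * replicates * micePerReplicate} in vivo
#'   samples.
#' @examples
#' d <- makeScreenDesign(c("BXPC3", "PANC1"), replicates = 2,
#'                       micePerReplicate = 2)
#' table(sampleSheet(d)$environment)
#' @export
makeScreenDesign <- function(cellLines, replicates = 4L,
                             micePerReplicate = 2L, barcodeLength = 6L) {
  stopifnot(length(cellLines) >= 1L, replicates >= 1L, micePerReplicate >= 0L)
  rows <- list()
  for (cl in cellLines) {
    for (r in seq_len(replicates)) {
      init_id <- sprintf("%s_r%d_initial", cl, r)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = init_id, cell_line = cl, environment = "initial",
        replicate = r, paired_initial_id = "")
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d_vitro", cl, r), cell_line = cl,
        environment = "in_vitro", replicate = r, paired_initial_id = init_id)
      for (m in seq_len(micePerReplicate))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_r%d_vivo_m%d", cl, r, m), cell_line = cl,
          environment = "in_vivo", replicate = r, paired_initial_id = init_id)
    }
  }
  tab <- do.call(rbind, rows)
  tab$barcode <- makeBarcodes(nrow(tab), barcodeLength)
  ScreenDesign(tab)
}

# Deterministic barcode set: greedy scan of k-mers in lexicographic order,
# keeping those at Hamming distance >= 3 from all kept so far. If the
# requested width cannot host n such barcodes, the width grows by one.
makeBarcodes <- function(n, width = 6L) {
  alphabet <- c("A", "C", "G", "T")
  if (width > 12L)
    stop("cannot generate ", n, " barcodes at Hamming distance >= 3")
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), width), stringsAsFactors = FALSE))
  cand <- do.call(paste0, grid[, rev(seq_len(width)), drop = FALSE])
  kept <- character(0)
  kept_mat <- NULL
  cand_mat <- do.call(rbind, strsplit(cand, ""))
  for (i in seq_along(cand)) {
    if (is.null(kept_mat) ||
        all(rowSums(kept_mat != matrix(cand_mat[i, ], nrow(kept_mat),
                                       width, byrow = TRUE)) >= 3L)) {
      kept <- c(kept, cand[i])
      kept_mat <- rbind(kept_mat, cand_mat[i, ])
      if (length(kept) == n) return(kept)
    }
  }
  makeBarcodes(n, width + 1L)
}

## ---- design accessors ----

#' Accessors for ScreenDesign
#' @param design a \linkS4class{ScreenDesign}.
#' @return \code{sampleSheet} returns the sample table as a data.frame;
#'   \code{selectedSamples} the non-initial rows; \code{pairedInitial} a
#'   named vector mapping each selected sample to its initial sample.
#' @name ScreenDesign-accessors
NULL

#' @describeIn ScreenDesign-accessors the full sample table
#' @export
sampleSheet <- function(design) as.data.frame(design@samples)

#' @describeIn ScreenDesign-accessors rows for in_vitro/in_vivo samples
#' @export
selectedSamples <- function(design) {
  s <- sampleSheet(design)
  s[s$environment != "initial", , drop = FALSE]
}

#' @describeIn ScreenDesign-accessors named map selected -> initial sample
#' @export
pairedInitial <- function(design) {
  s <- selectedSamples(design)
  stats::setNames(s$paired_initial_id, s$sample_id)
}

#' @export
setMethod("show", "ScreenDesign", function(object) {
  s <- sampleSheet(object)
  env <- table(factor(s$environment, ENVIRONMENTS))
  cat("ScreenDesign with", nrow(s), "samples across",
      length(unique(s$cell_line)), "cell line(s):",
      paste(sprintf("%d %s", env, names(env)), collapse = ", "), "\n")
})
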