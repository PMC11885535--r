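#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   colData rowData colData<- rowData<- assays<-
NULL

GENE_CONTROL <- "CTRL"
ENVIRONMENTS <- c("initial", "in_vitro", "in_vivo")
HIT_CLASSES <- c("none", "in_vitro_depleted", "in_vivo_enriched",
                 "opposite_suppressor", "opposite_essential")

#' GuideLibrary: an sgRNA library manifest
#'
#' Holds the guide catalogue of a pooled CRISPR screen: one row per sgRNA
#' with its unique identifier, target gene symbol, 20-nt protospacer and a
#' control flag. Non-targeting controls carry the reserved gene label
#' \code{"CTRL"}; for gene-level statistics they are grouped, in manifest
#' order, into pseudo-genes of the same size as targeting genes so that
#' control gene scores are distributionally comparable to targeting genes.
#'
#' Validity requires: protospacers exactly 20 bases over A/C/G/T, unique
#' guide identifiers and unique protospacers, every targeting gene carrying
#' the same number of guides, and \code{is_control} true exactly when the
#' gene label is \code{"CTRL"}.
#'
#' @slot guides \code{DataFrame} with columns \code{guide_id}, \code{gene},
#'   \code{protospacer}, \code{is_control}, in library order.
#'
#' @seealso [GuideLibrary()], [readGuideLibrary()], [writeGuideReference()]
#' @export
setClass("GuideLibrary", slots = c(guides = "DataFrame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  need <- c("guide_id", "gene", "protospacer", "is_control")
  if (!all(need %in% colnames(g)))
    return(paste("guides must have columns", paste(need, collapse = ", ")))
  errs <- character()
  bad_len <- which(nchar(g$protospacer) != 20L |
                     grepl("[^ACGT]", g$protospacer))
  if (length(bad_len))
    errs <- c(errs, paste0("protospacers must be 20 bases of A/C/G/T; bad: ",
                           paste(g$guide_id[head(bad_len, 5)], collapse = ", ")))
  dup_id <- g$guide_id[duplicated(g$guide_id)]
  if (length(dup_id))
    errs <- c(errs, paste0("duplicate guide_id: ",
                           paste(unique(dup_id), collapse = ", ")))
  dup_sp <- unique(g$protospacer[duplicated(g$protospacer)])
  if (length(dup_sp)) {
    offenders <- g$guide_id[g$protospacer %in% dup_sp]
    errs <- c(errs, paste0("duplicate protospacers shared by guides: ",
                           paste(offenders, collapse = ", ")))
  }
  if (!identical(unname(g$is_control), unname(g$gene == GENE_CONTROL)))
    errs <- c(errs, "is_control must be TRUE exactly when gene == \"CTRL\"")
  per_gene <- table(g$gene[!g$is_control])
  if (length(per_gene) && length(unique(as.integer(per_gene))) > 1L) {
    k <- as.integer(stats::median(per_gene))
    uneven <- names(per_gene)[per_gene != k]
    errs <- c(errs, paste0("uneven guides per gene: ",
                           paste(uneven, collapse = ", ")))
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' ScreenDesign: sample sheet for a multi-environment screen
#'
#' One row per sequenced sample: sample identifier, cell line, growth
#' environment (\code{initial}, \code{in_vitro} or \code{in_vivo}),
#' replicate number, the inline barcode used for demultiplexing (may be
#' empty when counts are supplied directly), and for every selected sample
#' the identifier of its paired initial sample — the denominator of all
#' fold changes.
#'
#' Validity requires referential integrity of the pairing: each selected
#' sample names an existing initial sample of the same cell line and
#' replicate; non-empty barcodes are unique and of one common length.
#'
#' @slot samples \code{DataFrame} with columns \code{sample_id},
#'   \code{cell_line}, \code{environment}, \code{replicate},
#'   \code{barcode}, \code{paired_initial_id}.
#'
#' @seealso [ScreenDesign()], [readSampleSheet()], [makeScreenDesign()]
#' @export
setClass("ScreenDesign", slots = c(samples = "DataFrame"))

setValidity("ScreenDesign", function(object) {
  s <- object@samples
  need <- c("sample_id", "cell_line", "environment", "replicate",
            "barcode", "paired_initial_id")
  if (!all(need %in% colnames(s)))
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  errs <- character()
  if (anyDuplicated(s$sample_id))
    errs <- c(errs, paste0("duplicate sample_id: ",
                           paste(unique(s$sample_id[duplicated(s$sample_id)]),
                                 collapse = ", ")))
  if (!all(s$environment %in% ENVIRONMENTS))
    errs <- c(errs, paste0("environment must be one of ",
                           paste(ENVIRONMENTS, collapse = "/")))
  if (any(s$replicate < 1L))
    errs <- c(errs, "replicate must be >= 1")
  sel <- s$environment != "initial"
  init_ids <- s$sample_id[s$environment == "initial"]
  dangle <- which(sel & !(s$paired_initial_id %in% init_ids))
  if (length(dangle))
    errs <- c(errs, paste0("selected samples with missing/dangling ",
                           "paired_initial_id: ",
                           paste(s$sample_id[dangle], collapse = ", ")))
  ok <- sel & (s$paired_initial_id %in% init_ids)
  if (any(ok)) {
    idx <- match(s$paired_initial_id[ok], s$sample_id)
    mism <- which(s$cell_line[ok] != s$cell_line[idx] |
                    s$replicate[ok] != s$replicate[idx])
    if (length(mism))
      errs <- c(errs, paste0("pairing crosses cell_line/replicate for: ",
                             paste(s$sample_id[ok][mism], collapse = ", ")))
  }
  bc <- s$barcode[!is.na(s$barcode) & s$barcode != ""]
  if (length(bc)) {
    if (anyDuplicated(bc))
      errs <- c(errs, paste0("duplicate barcodes in pool: ",
                             paste(unique(bc[duplicated(bc)]), collapse = ", ")))
    if (length(unique(nchar(bc))) > 1L)
      errs <- c(errs, "barcodes must all have the same length")
    if (any(grepl("[^ACGT]", bc)))
      errs <- c(errs, "barcodes must be A/C/G/T only")
  }
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' ScreenCounts: guide-by-sample read counts
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"counts"} assay of
#' non-negative integer guide-by-sample read counts, guide annotation in
#' \code{rowData} and, in \code{colData}, the per-sample bookkeeping the
#' normalisation step requires: \code{total_reads} (all reads seen for the
#' sample, assigned plus unassigned) and \code{assigned_reads} (the column
#' sum of the count assay). Normalisation is to total reads per sample, so
#' totals are carried alongside the matrix rather than recomputed from it.
#'
#' @seealso [ScreenCounts()], [readCountMatrix()], [normalizeCounts()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay \"counts\" is required")
  m <- assay(object, "counts")
  errs <- character()
  if (any(m < 0) || any(m != round(m)))
    errs <- c(errs, "counts must be non-negative integers")
  cd <- colData(object)
  if (!all(c("total_reads", "assigned_reads") %in% colnames(cd)))
    return("colData needs total_reads and assigned_reads")
  if (!isTRUE(all.equal(unname(colSums(m)), as.numeric(cd$assigned_reads))))
    errs <- c(errs, "assigned_reads must equal column sums of counts")
  if (any(cd$assigned_reads > cd$total_reads))
    errs <- c(errs, "assigned_reads must be <= total_reads")
  if (length(errs)) paste(errs, collapse = "; ") else TRUE
})

#' GeneScores: gene-level enrichment scores and control-centred z-scores
#'
#' A \linkS4class{SummarizedExperiment} over genes (targeting genes plus
#' control pseudo-genes) by selected samples, with assays \code{"score"}
#' (mean of the gene's guide log2 fold changes versus the paired initial
#' sample) and \code{"z"} (score minus the sample's mean control-guide
#' fold change, divided by the within-sample standard deviation of centred
#' scores). Audit values \code{control_mean} and \code{score_sd} are kept
#' per sample in \code{colData}; \code{rowData$is_control} flags control
#' pseudo-genes.
#'
#' @seealso [scoreScreen()], [centerAndZ()], [contrastEnvironments()]
#' @export
setClass("GeneScores", contains = "SummarizedExperiment")

setValidity("GeneScores", function(object) {
  if (!"score" %in% names(assays(object)))
    return("assay \"score\" is required")
  if (!"is_control" %in% colnames(rowData(object)))
    return("rowData needs is_control")
  if ("z" %in% names(assays(object))) {
    cd <- colData(object)
    if (!all(c("control_mean", "score_sd") %in% colnames(cd)))
      return("colData needs control_mean and score_sd once z is filled")
    if (any(cd$score_sd <= 0)) return("score_sd must be > 0")
  }
  TRUE
})
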