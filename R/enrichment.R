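#' Normalise guide counts to reads-per-million of total reads
#'
#' Per-sample depth normalisation against the sample's total read count
#' (assigned plus unassigned), so a sample's column sums to
#' \code{1e6 * assigned_reads / total_reads}.
#'
#' @param object a \linkS4class{ScreenCounts}.
#' @return A \code{SummarizedExperiment} with assay \code{"rpm"}:
#'   \code{rpm[g, s] = counts[g, s] * 1e6 / total_reads[s]}.
#' @export
normalizeCounts <- function(object) {
  stopifnot(is(object, "ScreenCounts"))
  totals <- colData(object)$total_reads
  zero <- which(totals <= 0)
  if (length(zero))
    stop("zero total reads for sample(s): ",
         paste(colnames(object)[zero], collapse = ", "))
  rpm <- sweep(guideCounts(object), 2L, totals, function(x, t) x * 1e6 / t)
  SummarizedExperiment(assays = list(rpm = rpm),
                       rowData = rowData(object),
                       colData = colData(object))
}

#' Paired guide log2 fold changes versus the initial sample
#'
#' For every selected (in vitro / in vivo) sample, the log2 ratio of each
#' guide's normalised abundance to the same guide in the sample's paired
#' initial sample. A pseudocount (in RPM units) is added to numerator and
#' denominator, guaranteeing finite values for dropout guides.
#'
#' @param norm the \code{SummarizedExperiment} from [normalizeCounts()].
#' @param design a \linkS4class{ScreenDesign}; all its selected samples
#'   must be columns of \code{norm}, as must their paired initial samples.
#' @param pseudocount positive RPM offset; default 1.
#' @param space \code{"log2"} (default) or \code{"linear"} fold changes.
#'   All downstream statistics are defined on the log2 scale; the linear
#'   option is provided for direct ratio inspection.
#' @return A \code{SummarizedExperiment} over guides by selected samples
#'   with assay \code{"lfc"}; the pseudocount and space used are recorded
#'   in \code{metadata()}.
#' @export
guideLogFC <- function(norm, design, pseudocount = 1, space = c("log2", "linear")) {
  stopifnot(is(design, "ScreenDesign"), pseudocount > 0)
  space <- match.arg(space)
  rpm <- assay(norm, "rpm")
  sel <- selectedSamples(design)
  missing_sel <- setdiff(c(sel$sample_id, sel$paired_initial_id),
                         colnames(rpm))
  if (length(missing_sel))
    stop("samples in design but not in matrix: ",
         paste(missing_sel, collapse = ", "))
  ratio <- (rpm[, sel$sample_id, drop = FALSE] + pseudocount) /
    (rpm[, sel$paired_initial_id, drop = FALSE] + pseudocount)
  lfc <- if (space == "log2") log2(ratio) else ratio
  colnames(lfc) <- sel$sample_id
  out <- SummarizedExperiment(
    assays = list(lfc = lfc),
    rowData = rowData(norm),
    colData = DataFrame(sel, row.names = sel$sample_id))
  metadata(out) <- list(pseudocount = pseudocount, space = space)
  out
}

#' Gene-level enrichment scores: mean of guide fold changes
#'
#' Averages each gene's guide log2 fold changes within a sample. Control
#' guides are grouped into pseudo-genes of \code{guidesPerGene} guides in
#' manifest order (see \linkS4class{GuideLibrary}) so that their scores
#' are distributionally comparable to targeting genes.
#'
#' @param lfc the \code{SummarizedExperiment} from [guideLogFC()].
#' @param library the \linkS4class{GuideLibrary}.
#' @return A \linkS4class{GeneScores} with assay \code{"score"} only
#'   (z-scores are added by [centerAndZ()]).
#' @export
geneScores <- function(lfc, library) {
  stopifnot(is(library, "GuideLibrary"))
  m <- assay(lfc, "lfc")
  if (any(!is.finite(m))) stop("guide lfc must be finite")
  groups <- guideGenes(library)[rownames(m)]
  if (anyNA(groups)) stop("lfc rows not covered by the guide library")
  glev <- unique(groups)
  agg <- rowsum(m, group = factor(groups, glev)) /
    as.vector(table(factor(groups, glev)))
  rowdat <- DataFrame(gene = glev,
                      is_control = startsWith(glev, "CTRL_PG"),
                      row.names = glev)
  out <- SummarizedExperiment(assays = list(score = agg),
                              rowData = rowdat, colData = colData(lfc))
  metadata(out) <- c(metadata(lfc),
                     list(control_grouping = "pseudo-genes in manifest order"))
  new("GeneScores", out)
}

#' Control-centred z-scores per sample
#'
#' Centres every sample's gene scores on the sample's mean non-targeting
#' control guide fold change, then scales by the within-sample standard
#' deviation of the centred scores: \code{z[gene, s] = (score[gene, s] -
#' c_s) / sd_s}. By default the standard deviation is taken over all
#' genes and control pseudo-genes in the sample (\code{zPopulation =
#' "all"}); \code{"targeting"} excludes the control pseudo-genes from the
#' scale estimate. \code{c_s} and \code{sd_s} are recorded in
#' \code{colData} for audit.
#'
#' @param scores a \linkS4class{GeneScores} from [geneScores()].
#' @param lfc the guide-level \code{SummarizedExperiment} from
#'   [guideLogFC()] (used for the control-guide mean \code{c_s}).
#' @param library the \linkS4class{GuideLibrary}.
#' @param zPopulation \code{"all"} (default) or \code{"targeting"}.
#' @return The \linkS4class{GeneScores} with assay \code{"z"} filled and
#'   \code{control_mean}/\code{score_sd} in \code{colData}.
#' @export
centerAndZ <- function(scores, lfc, library,
                       zPopulation = c("all", "targeting")) {
  stopifnot(is(scores, "GeneScores"), is(library, "GuideLibrary"))
  zPopulation <- match.arg(zPopulation)
  if (nControls(library) < 2L)
    stop("need at least 2 control guides for centering")
  if (nrow(scores) < 3L)
    stop("need at least 3 genes for a within-sample scale")
  ctrl <- isControl(library)
  lfc_m <- assay(lfc, "lfc")
  ctrl_rows <- rownames(lfc_m)[ctrl[rownames(lfc_m)]]
  c_s <- colMeans(lfc_m[ctrl_rows, colnames(scores), drop = FALSE])
  centered <- sweep(assay(scores, "score"), 2L, c_s)
  pop <- if (zPopulation == "all") rep(TRUE, nrow(centered))
         else !rowData(scores)$is_control
  sd_s <- apply(centered[pop, , drop = FALSE], 2L, stats::sd)
  if (any(sd_s <= 0 | !is.finite(sd_s)))
    stop("degenerate sample (zero score dispersion): ",
         paste(colnames(scores)[sd_s <= 0 | !is.finite(sd_s)],
               collapse = ", "))
  z <- sweep(centered, 2L, sd_s, "/")
  assays(scores)$z <- z
  colData(scores)$control_mean <- unname(c_s)
  colData(scores)$score_sd <- unname(sd_s)
  metadata(scores)$z_population <- zPopulation
  validObject(scores)
  scores
}

#' Run the full scoring chain on a count matrix
#'
#' Convenience wrapper: [normalizeCounts()] then [guideLogFC()] then
#' [geneScores()] then [centerAndZ()].
#'
#' @inheritParams guideLogFC
#' @inheritParams centerAndZ
#' @param counts a \linkS4class{ScreenCounts}.
#' @param library the \linkS4class{GuideLibrary}.
#' @return A \linkS4class{GeneScores} with \code{"score"} and \code{"z"}.
#' @examples
#' sim <- simulateScreen(simConfig(nGenes = 10, nControls = 10,
#'                                 cellLines = "A", seed = 1))
#' gs <- scoreScreen(sim$counts, sim$library, sim$design)
#' head(assay(gs, "z")[, 1:3])
#' @export
scoreScreen <- function(counts, library, design, pseudocount = 1,
                        space = "log2", zPopulation = "all") {
  norm <- normalizeCounts(counts)
  lfc <- guideLogFC(norm, design, pseudocount = pseudocount, space = space)
  gs <- geneScores(lfc, library)
  centerAndZ(gs, lfc, library, zPopulation = zPopulation)
}

#' @export
setMethod("show", "GeneScores", function(object) {
  cat("GeneScores:", nrow(object), "genes (",
      sum(rowData(object)$is_control), "control pseudo-genes) x",
      ncol(object), "selected samples; assays:",
      paste(names(assays(object)), collapse = ", "), "\n")
})

#' Write gene scores and z-scores to TSV
#'
#' Two files: \code{<prefix>_scores.tsv} with gene-by-sample score and z
#' matrices stacked long, and \code{<prefix>_sample_audit.tsv} with the
#' per-sample \code{control_mean} and \code{score_sd}.
#'
#' @param scores a \linkS4class{GeneScores} with \code{"z"} filled.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
writeGeneScores <- function(scores, prefix) {
  sc <- assay(scores, "score"); z <- assay(scores, "z")
  long <- data.frame(
    gene = rep(rownames(sc), ncol(sc)),
    is_control = rep(rowData(scores)$is_control, ncol(sc)),
    sample_id = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc), z = as.vector(z))
  p1 <- paste0(prefix, "_scores.tsv")
  utils::write.table(long, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- data.frame(sample_id = colnames(sc),
                      control_mean = colData(scores)$control_mean,
                      score_sd = colData(scores)$score_sd)
  p2 <- paste0(prefix, "_sample_audit.tsv")
  utils::write.table(audit, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
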