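#' Collect replicate z-scores per cell line, environment and gene
#'
#' Each selected sample contributes one entry, so a design with two
#' xenografts per replicate infection yields twice as many in vivo entries
#' as in vitro ones. Cell lines with fewer than two replicates in either
#' environment are dropped with a warning; no contrast can be formed there.
#'
#' @param scores a \linkS4class{GeneScores} with assay \code{"z"}.
#' @param design the \linkS4class{ScreenDesign}.
#' @return A list keyed by cell line; each element has \code{vitro} and
#'   \code{vivo}: gene-by-sample z matrices (one column per sample).
#' @export
aggregateReplicates <- function(scores, design) {
  stopifnot(is(scores, "GeneScores"))
  sel <- selectedSamples(design)
  sel <- sel[sel$sample_id %in% colnames(scores), , drop = FALSE]
  z <- assay(scores, "z")
  out <- list()
  for (cl in unique(sel$cell_line)) {
    vit <- sel$sample_id[sel$cell_line == cl & sel$environment == "in_vitro"]
    viv <- sel$sample_id[sel$cell_line == cl & sel$environment == "in_vivo"]
    if (length(vit) < 2L || length(viv) < 2L) {
      warning("cell line ", cl, " has <2 replicates in an environment; ",
              "excluded from contrast")
      next
    }
    out[[cl]] <- list(vitro = z[, vit, drop = FALSE],
                      vivo = z[, viv, drop = FALSE])
  }
  out
}

#' Two-sided t-test between environments for one gene
#'
#' Welch (unequal variance) by default: the engraftment bottleneck makes
#' in vivo replicate variance exceed in vitro variance by design. The sign
#' convention is positive \code{t} when the in vivo mean exceeds the
#' in vitro mean. When both groups are constant the statistic degenerates:
#' equal means give \code{t = 0, p = 1}, unequal means \code{|t| = Inf,
#' p = 0}.
#'
#' @param zVitro,zVivo numeric vectors of replicate z-scores, each of
#'   length >= 2.
#' @param method \code{"welch"} (default) or \code{"student"}.
#' @return \code{c(t_stat =, p_value =)}.
#' @export
environmentTTest <- function(zVitro, zVivo, method = c("welch", "student")) {
  method <- match.arg(method)
  stopifnot(length(zVitro) >= 2L, length(zVivo) >= 2L,
            all(is.finite(zVitro)), all(is.finite(zVivo)))
  if (stats::sd(zVitro) == 0 && stats::sd(zVivo) == 0) {
    if (mean(zVitro) == mean(zVivo))
      return(c(t_stat = 0, p_value = 1))
    return(c(t_stat = sign(mean(zVivo) - mean(zVitro)) * Inf, p_value = 0))
  }
  ht <- stats::t.test(zVivo, zVitro, var.equal = (method == "student"))
  c(t_stat = unname(ht$statistic), p_value = ht$p.value)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment across the supplied p-values; invariant under input
#' order permutation. \code{NA} p-values propagate as \code{NA} with a
#' warning.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return FDR vector of the same length and order.
#' @export
adjustFDR <- function(p) {
  if (anyNA(p)) warning("NA p-values propagated as NA FDR")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify environment-dependent hits
#'
#' A gene is a hit only at \code{fdr < fdrThresh}. Among hits:
#' \code{opposite_suppressor} when the in vitro mean z is below
#' \code{-zThresh} and the in vivo mean above \code{+zThresh} (essential
#' in culture, tumour-suppressive in vivo — the sign-reversing phenotype);
#' \code{opposite_essential} is its mirror image. When only one
#' environment clears \code{|z| > zThresh} the class is the one-sided
#' \code{in_vitro_depleted} (vitro below threshold) or
#' \code{in_vivo_enriched} (vivo above threshold); everything else is
#' \code{none}.
#'
#' @param zVitroMean,zVivoMean per-gene mean z-scores.
#' @param fdr per-gene FDR.
#' @param zThresh z magnitude threshold (default 1).
#' @param fdrThresh FDR threshold (default 0.05).
#' @return Character vector of hit classes.
#' @export
classifyHits <- function(zVitroMean, zVivoMean, fdr, zThresh = 1,
                         fdrThresh = 0.05) {
  n <- length(zVitroMean)
  stopifnot(length(zVivoMean) == n, length(fdr) == n)
  cls <- rep("none", n)
  sig <- !is.na(fdr) & fdr < fdrThresh
  lo_vit <- zVitroMean < -zThresh
  hi_vit <- zVitroMean > zThresh
  lo_viv <- zVivoMean < -zThresh
  hi_viv <- zVivoMean > zThresh
  cls[sig & lo_vit & hi_viv] <- "opposite_suppressor"
  cls[sig & hi_vit & lo_viv] <- "opposite_essential"
  one_sided <- sig & cls == "none"
  cls[one_sided & lo_vit & !lo_viv & !hi_viv] <- "in_vitro_depleted"
  cls[one_sided & hi_viv & !lo_vit & !hi_vit] <- "in_vivo_enriched"
  factor(cls, levels = HIT_CLASSES)
}

#' In vitro versus in vivo differential essentiality contrast
#'
#' For every (cell line, gene): averages replicate z-scores per
#' environment, tests the environments against each other with a
#' two-sided t-test (Welch by default), adjusts p-values by
#' Benjamini-Hochberg FDR — per cell line across targeting genes, or
#' pooled across cell lines with \code{poolCellLines = TRUE} — and
#' classifies hits. Control pseudo-genes are excluded from the FDR
#' ranking but reported with \code{NA} FDR.
#'
#' @param scores a \linkS4class{GeneScores} with assay \code{"z"}.
#' @param design the \linkS4class{ScreenDesign}.
#' @param zThresh,fdrThresh hit thresholds, recorded in the result.
#' @param ttest \code{"welch"} (default) or \code{"student"}.
#' @param poolCellLines adjust FDR across all cell lines jointly instead
#'   of within each cell line.
#' @return A data.frame with one row per (cell_line, gene):
#'   \code{z_vitro_mean}, \code{z_vivo_mean}, \code{n_vitro},
#'   \code{n_vivo}, \code{t_stat}, \code{p_value}, \code{fdr},
#'   \code{is_control}, \code{hit_class}; thresholds and test choice in
#'   \code{attr(, "parameters")}.
#' @export
contrastEnvironments <- function(scores, design, zThresh = 1,
                                 fdrThresh = 0.05,
                                 ttest = c("welch", "student"),
                                 poolCellLines = FALSE) {
  ttest <- match.arg(ttest)
  agg <- aggregateReplicates(scores, design)
  if (!length(agg)) stop("no cell line has >=2 replicates per environment")
  is_ctrl <- stats::setNames(rowData(scores)$is_control, rownames(scores))
  res <- list()
  for (cl in names(agg)) {
    zv <- agg[[cl]]$vitro
    zw <- agg[[cl]]$vivo
    tests <- t(vapply(rownames(zv), function(g)
      environmentTTest(zv[g, ], zw[g, ], method = ttest), numeric(2)))
    res[[cl]] <- data.frame(
      cell_line = cl, gene = rownames(zv),
      z_vitro_mean = rowMeans(zv), z_vivo_mean = rowMeans(zw),
      n_vitro = ncol(zv), n_vivo = ncol(zw),
      t_stat = tests[, "t_stat"], p_value = tests[, "p_value"],
      is_control = unname(is_ctrl[rownames(zv)]),
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  targ <- !out$is_control
  if (poolCellLines) {
    out$fdr[targ] <- adjustFDR(out$p_value[targ])
  } else {
    for (cl in unique(out$cell_line)) {
      i <- targ & out$cell_line == cl
      out$fdr[i] <- adjustFDR(out$p_value[i])
    }
  }
  out$hit_class <- classifyHits(out$z_vitro_mean, out$z_vivo_mean, out$fdr,
                                zThresh = zThresh, fdrThresh = fdrThresh)
  attr(out, "parameters") <- list(z_thresh = zThresh,
                                  fdr_thresh = fdrThresh, ttest = ttest,
                                  pool_cell_lines = poolCellLines)
  out
}

#' Scatter-plot table of per-gene environment z-scores
#'
#' One row per (cell line, gene) with the in vitro and in vivo mean
#' z-scores, FDR and hit class — the data behind the screen's z-score
#' scatter, with controls flagged in a dedicated column.
#'
#' @param result the data.frame from [contrastEnvironments()].
#' @return data.frame with columns cell_line, gene, z_vitro_mean,
#'   z_vivo_mean, fdr, is_control, hit_class.
#' @export
makeScatterData <- function(result) {
  result[, c("cell_line", "gene", "z_vitro_mean", "z_vivo_mean", "fdr",
             "is_control", "hit_class")]
}

#' Plot the in vitro versus in vivo z-score scatter
#'
#' @param result the data.frame from [contrastEnvironments()].
#' @param file optional path (pdf/png by extension); when \code{NULL} the
#'   ggplot object is returned.
#' @return A ggplot object, invisibly when written to file.
#' @export
plotScreenScatter <- function(result, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  dat <- makeScatterData(result)
  dat$size <- -log10(pmax(dat$fdr, 1e-6))
  dat$size[is.na(dat$size)] <- 0
  p <- ggplot2::ggplot(dat, ggplot2::aes(
        x = z_vitro_mean, y = z_vivo_mean,
        colour = hit_class, size = size)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~cell_line) +
    ggplot2::scale_size_continuous(name = "-log10 FDR", range = c(0.5, 4)) +
    ggplot2::labs(x = "in vitro mean z", y = "in vivo mean z") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 6)
    return(invisible(p))
  }
  p
}
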