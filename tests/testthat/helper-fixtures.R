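suppressPackageStartupMessages({
  library(SummarizedExperiment)
})

# deterministic toy library: nGenes genes x k guides + nCtrl controls,
# protospacers enumerated (not random) so fixtures are stable
toyLibrary <- function(nGenes = 3, k = 2, nCtrl = 4) {
  alphabet <- c("A", "C", "G", "T")
  n <- nGenes * k + nCtrl
  sp <- vapply(seq_len(n), function(i) {
    digits <- (i %/% 4^(0:9)) %% 4 + 1   # i in base 4 over 10 positions
    paste0(paste(alphabet[digits], collapse = ""), strrep("A", 10))
  }, character(1))
  stopifnot(!anyDuplicated(sp))
  GuideLibrary(data.frame(
    guide_id = c(sprintf("G%02d_g%d", rep(seq_len(nGenes), each = k),
                         seq_len(k)),
                 sprintf("CTRL_c%02d", seq_len(nCtrl))),
    gene = c(rep(sprintf("GENE%02d", seq_len(nGenes)), each = k),
             rep("CTRL", nCtrl)),
    protospacer = sp,
    is_control = rep(c(FALSE, TRUE), c(nGenes * k, nCtrl))))
}

toyDesign <- function(cellLines = "A", replicates = 2, mice = 1) {
  makeScreenDesign(cellLines, replicates, mice)
}

# ---- independent brute-force oracles ----

# per-read Hamming scan over every (read, barcode) pair
oracleDemux <- function(seqs, barcodes, offset = 0, maxMismatch = 0) {
  L <- nchar(barcodes[1])
  vapply(seqs, function(r) {
    region <- substr(r, offset + 1, offset + L)
    if (nchar(region) < L) return(NA_integer_)
    d <- vapply(barcodes, function(b) {
      sum(strsplit(region, "")[[1]] != strsplit(b, "")[[1]])
    }, integer(1))
    hits <- which(d <= maxMismatch)
    if (length(hits) == 1L) hits else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

# substring search of every protospacer in every read
oracleScanCounts <- function(seqs, protospacers) {
  hits <- vapply(protospacers, function(p)
    grepl(p, seqs, fixed = TRUE), logical(length(seqs)))
  hits <- matrix(hits, nrow = length(seqs))
  nhit <- rowSums(hits)
  counts <- colSums(hits[nhit == 1L, , drop = FALSE])
  list(counts = stats::setNames(as.integer(counts), names(protospacers)),
       unassigned = sum(nhit == 0L), ambiguous = sum(nhit > 1L))
}

# explicit-loop recomputation of the score/z chain from a count matrix
oracleScoreChain <- function(counts, totals, design, library,
                             pseudocount = 1) {
  rpm <- counts
  for (s in colnames(counts)) rpm[, s] <- counts[, s] * 1e6 / totals[s]
  sel <- selectedSamples(design)
  lfc <- matrix(NA_real_, nrow(counts), nrow(sel),
                dimnames = list(rownames(counts), sel$sample_id))
  for (i in seq_len(nrow(sel)))
    for (g in rownames(counts))
      lfc[g, i] <- log2((rpm[g, sel$sample_id[i]] + pseudocount) /
                          (rpm[g, sel$paired_initial_id[i]] + pseudocount))
  groups <- guideGenes(library)
  glev <- unique(unname(groups))
  score <- matrix(NA_real_, length(glev), ncol(lfc),
                  dimnames = list(glev, colnames(lfc)))
  for (ge in glev)
    for (s in colnames(lfc))
      score[ge, s] <- mean(lfc[names(groups)[groups == ge], s])
  ctrl_guides <- names(which(isControl(library)))
  z <- score
  c_s <- sd_s <- numeric(ncol(score))
  for (j in seq_len(ncol(score))) {
    c_s[j] <- mean(lfc[ctrl_guides, j])
    centered <- score[, j] - c_s[j]
    sd_s[j] <- sqrt(sum((centered - mean(centered))^2) /
                      (length(centered) - 1))
    z[, j] <- centered / sd_s[j]
  }
  list(rpm = rpm, lfc = lfc, score = score, z = z,
       control_mean = c_s, score_sd = sd_s)
}

# closed-form two-sided Welch t-test (vivo - vitro sign convention)
oracleWelch <- function(x_vitro, y_vivo) {
  n1 <- length(y_vivo); n2 <- length(x_vitro)
  v1 <- stats::var(y_vivo); v2 <- stats::var(x_vitro)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(y_vivo) - mean(x_vitro)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  c(t_stat = t, p_value = 2 * stats::pt(-abs(t), df))
}

# BH step-up: fdr_(i) = min over j >= i of p_(j) * m / j
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  fdr_sorted <- vapply(seq_len(m), function(i)
    min(pmin(ps[i:m] * m / (i:m), 1)), numeric(1))
  out <- numeric(m)
  out[o] <- fdr_sorted
  out
}

countsFromMatrix <- function(m, design = NULL, totals = colSums(m),
                             library = NULL) {
  ScreenCounts(m, totalReads = totals, library = library)
}
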