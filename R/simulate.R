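#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the screen design the analysis targets: a 660-guide
#' library (112 genes x 5 guides + 100 non-targeting controls), five cell
#' lines each infected in quadruplicate, two xenografts per replicate
#' culture, one million reads per sample, log-normal library
#' representation, negative-binomial count noise and a multinomial
#' engraftment bottleneck for in vivo samples.
#'
#' @param nGenes targeting genes in the library.
#' @param guidesPerGene guides per targeting gene.
#' @param nControls non-targeting control guides.
#' @param cellLines character vector of cell line names, or an integer
#'   count (names are generated).
#' @param replicates replicate infections per cell line.
#' @param micePerReplicate xenografts per replicate culture.
#' @param depth expected sequencing reads per sample.
#' @param initialAbundanceSd log-space (natural log) standard deviation of
#'   the library's guide representation.
#' @param guideJitterSd per-guide efficacy jitter, in lfc units, around
#'   the gene effect (targeting guides only; applied identically in both
#'   selected environments).
#' @param noiseDispersion negative-binomial overdispersion of observed
#'   counts (variance = mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param bottleneckSize cells engrafting per xenograft.
#' @param effects optional data.frame of planted selection effects with
#'   columns \code{gene}, \code{cell_line} (or \code{"all"}),
#'   \code{environment} (\code{in_vitro}/\code{in_vivo}), \code{effect}
#'   (lfc units); genes absent from the table are neutral. See
#'   [plantOppositeEffects()].
#' @param seed master seed; one seed reproduces every artifact exactly.
#' @return A validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(nGenes = 112L, guidesPerGene = 5L, nControls = 100L,
                      cellLines = c("BXPC3", "PANC1", "MIAPACA2",
                                    "CFPAC1", "HPAFII"),
                      replicates = 4L, micePerReplicate = 2L,
                      depth = 1e6, initialAbundanceSd = 0.5,
                      guideJitterSd = 0.2, noiseDispersion = 0.05,
                      bottleneckSize = 1e5, effects = NULL, seed = 1L) {
  if (is.numeric(cellLines) && length(cellLines) == 1L)
    cellLines <- sprintf("CL%d", seq_len(cellLines))
  cfg <- list(nGenes = as.integer(nGenes),
              guidesPerGene = as.integer(guidesPerGene),
              nControls = as.integer(nControls),
              cellLines = cellLines,
              replicates = as.integer(replicates),
              micePerReplicate = as.integer(micePerReplicate),
              depth = depth,
              initialAbundanceSd = initialAbundanceSd,
              guideJitterSd = guideJitterSd,
              noiseDispersion = noiseDispersion,
              bottleneckSize = bottleneckSize,
              effects = effects, seed = as.integer(seed))
  if (cfg$nGenes < 1L || cfg$guidesPerGene < 1L || cfg$nControls < 0L)
    stop("library dimensions must be positive")
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$bottleneckSize < 1) stop("bottleneckSize must be >= 1")
  if (cfg$noiseDispersion < 0) stop("noiseDispersion must be >= 0")
  if (!is.null(effects)) {
    need <- c("gene", "cell_line", "environment", "effect")
    if (!all(need %in% colnames(effects)))
      stop("effects needs columns ", paste(need, collapse = ", "))
    if (!all(effects$environment %in% c("in_vitro", "in_vivo")))
      stop("effect environment must be in_vitro or in_vivo")
  }
  class(cfg) <- "simConfig"
  cfg
}

#' Build an effect table planting sign-reversing genes
#'
#' Marks \code{nSuppressor} genes as opposite suppressors (depleted in
#' vitro, enriched in vivo: effects \code{-effectSize}/\code{+effectSize})
#' and \code{nEssential} genes as the mirrored opposite-essential class,
#' in all cell lines.
#'
#' @param genes gene names eligible for planting (first ones are used).
#' @param nSuppressor,nEssential number of genes per opposite class.
#' @param effectSize magnitude in lfc units (default 1.5).
#' @return data.frame suitable for [simConfig()]'s \code{effects}.
#' @export
plantOppositeEffects <- function(genes, nSuppressor = 5L, nEssential = 0L,
                                 effectSize = 1.5) {
  stopifnot(nSuppressor + nEssential <= length(genes))
  sup <- genes[seq_len(nSuppressor)]
  ess <- genes[nSuppressor + seq_len(nEssential)]
  rbind(
    if (nSuppressor) data.frame(
      gene = rep(sup, 2), cell_line = "all",
      environment = rep(c("in_vitro", "in_vivo"), each = nSuppressor),
      effect = rep(c(-effectSize, effectSize), each = nSuppressor)),
    if (nEssential) data.frame(
      gene = rep(ess, 2), cell_line = "all",
      environment = rep(c("in_vitro", "in_vivo"), each = nEssential),
      effect = rep(c(effectSize, -effectSize), each = nEssential)))
}

simGeneNames <- function(n) sprintf("GENE%03d", seq_len(n))

randomProtospacers <- function(n) {
  repeat {
    sp <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(sp)) return(sp)
  }
}

effectLookup <- function(effects, genes, cellLines, environment) {
  out <- matrix(0, length(genes), length(cellLines),
                dimnames = list(genes, cellLines))
  if (is.null(effects)) return(out)
  sub <- effects[effects$environment == environment, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    cl <- if (sub$cell_line[i] == "all") cellLines else sub$cell_line[i]
    out[sub$gene[i], cl] <- sub$effect[i]
  }
  out
}

rcounts <- function(mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(length(mu), mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a multi-environment pooled CRISPR screen
#'
#' Generative model: guide library abundance \code{a_g ~ LogNormal(0,
#' initialAbundanceSd)} (one draw for the plasmid pool, shared by all
#' samples); per-guide selection effect = planted gene effect + guide
#' efficacy jitter; expected selected abundance \code{a_g * 2^effect}.
#' In vivo samples first pass a multinomial engraftment bottleneck of
#' \code{bottleneckSize} cells drawn from the library abundances, then
#' apply effects. Observed counts are negative-binomial around
#' \code{depth * relative abundance}. Non-targeting controls have zero
#' effect by construction. The same seed reproduces every artifact
#' bit-identically.
#'
#' @param config a [simConfig()].
#' @return A list: \code{library} (\linkS4class{GuideLibrary}),
#'   \code{design} (\linkS4class{ScreenDesign}), \code{counts}
#'   (\linkS4class{ScreenCounts}) and \code{truth} — a list with
#'   \code{classes} (data.frame per gene x cell line: true class) and
#'   \code{expected} (guide-by-sample matrix of expected read counts).
#' @export
simulateScreen <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  genes <- simGeneNames(config$nGenes)
  guide_tab <- data.frame(
    guide_id = c(sprintf("%s_g%d", rep(genes, each = config$guidesPerGene),
                         seq_len(config$guidesPerGene)),
                 sprintf("CTRL_c%03d", seq_len(config$nControls))),
    gene = c(rep(genes, each = config$guidesPerGene),
             rep(GENE_CONTROL, config$nControls)),
    protospacer = NA,
    is_control = c(rep(FALSE, config$nGenes * config$guidesPerGene),
                   rep(TRUE, config$nControls)))
  guide_tab$protospacer <- randomProtospacers(nrow(guide_tab))
  lib <- GuideLibrary(guide_tab)
  design <- makeScreenDesign(config$cellLines, config$replicates,
                             config$micePerReplicate)

  G <- nGuides(lib)
  gname <- guide_tab$gene
  targeting <- !guide_tab$is_control

  a <- stats::rlnorm(G, 0, config$initialAbundanceSd)
  jitter <- numeric(G)
  jitter[targeting] <- stats::rnorm(sum(targeting), 0, config$guideJitterSd)

  effV <- effectLookup(config$effects, genes, config$cellLines, "in_vitro")
  effW <- effectLookup(config$effects, genes, config$cellLines, "in_vivo")
  guideEffV <- matrix(0, G, length(config$cellLines),
                      dimnames = list(guide_tab$guide_id, config$cellLines))
  guideEffW <- guideEffV
  guideEffV[targeting, ] <- effV[gname[targeting], , drop = FALSE] +
    jitter[targeting]
  guideEffW[targeting, ] <- effW[gname[targeting], , drop = FALSE] +
    jitter[targeting]

  s <- sampleSheet(design)
  counts <- matrix(0L, G, nrow(s),
                   dimnames = list(guide_tab$guide_id, s$sample_id))
  expected <- matrix(0, G, nrow(s), dimnames = dimnames(counts))
  p0 <- a / sum(a)
  for (i in seq_len(nrow(s))) {
    cl <- s$cell_line[i]
    mu <- switch(s$environment[i],
      initial = config$depth * p0,
      in_vitro = {
        sel <- a * 2^guideEffV[, cl]
        config$depth * sel / sum(sel)
      },
      in_vivo = {
        cells <- as.vector(stats::rmultinom(1, config$bottleneckSize, p0))
        sel <- cells * 2^guideEffW[, cl]
        config$depth * sel / sum(sel)
      })
    expected[, i] <- mu
    counts[, i] <- rcounts(mu, config$noiseDispersion)
  }

  truth_cls <- expand.grid(gene = genes, cell_line = config$cellLines,
                           stringsAsFactors = FALSE)
  v <- effV[cbind(truth_cls$gene, truth_cls$cell_line)]
  w <- effW[cbind(truth_cls$gene, truth_cls$cell_line)]
  truth_cls$effect_vitro <- v
  truth_cls$effect_vivo <- w
  truth_cls$class <- ifelse(v < 0 & w > 0, "opposite_suppressor",
                     ifelse(v > 0 & w < 0, "opposite_essential",
                     ifelse(v < 0 & w <= 0, "essential_in_vitro",
                            "neutral")))

  list(library = lib, design = design,
       counts = ScreenCounts(counts, library = lib),
       truth = list(classes = truth_cls, expected = expected))
}

#' Emit synthetic FASTQ reads for a count matrix
#'
#' Each read is \code{barcode + flank5 + protospacer + flank3}, emitted
#' with multiplicity equal to the guide's count in the sample, pooled
#' across samples and deterministically shuffled. Optionally a fraction of
#' reads have one protospacer base corrupted (still demultiplexable but
#' unassignable at zero mismatches); corrupted reads are excluded from the
#' returned ground-truth tallies.
#'
#' @param counts a \linkS4class{ScreenCounts} (keep it small: one read is
#'   emitted per counted read).
#' @param library the \linkS4class{GuideLibrary}.
#' @param design the \linkS4class{ScreenDesign} supplying barcodes.
#' @param path output FASTQ path.
#' @param flank5,flank3 vector-derived constant sequences flanking the
#'   protospacer; they must not contain any protospacer as a substring.
#' @param corruptFraction fraction of reads with a mutated protospacer
#'   base (default 0).
#' @param seed shuffle/corruption seed.
#' @return A list: \code{path}, \code{n_reads}, and \code{truth} — a
#'   data.frame of (sample_id, guide_id, reads) for intact reads plus a
#'   per-sample corrupted tally.
#' @export
simulateFastq <- function(counts, library, design, path,
                          flank5 = "TATCTTGTGGAAAGGACGAAACACCG",
                          flank3 = "GTTTTAGAGCTAGAAATAGCAAGTT",
                          corruptFraction = 0, seed = 1L) {
  stopifnot(is(counts, "ScreenCounts"), is(library, "GuideLibrary"))
  sp <- protospacers(library)
  flank_hit <- vapply(sp, function(p)
    grepl(p, flank5, fixed = TRUE) || grepl(p, flank3, fixed = TRUE),
    logical(1))
  if (any(flank_hit))
    stop("flank contains protospacer(s): ",
         paste(names(sp)[flank_hit], collapse = ", "))
  s <- sampleSheet(design)
  bc <- stats::setNames(s$barcode, s$sample_id)
  m <- guideCounts(counts)
  set.seed(seed)
  recs <- list()
  for (sid in colnames(m)) {
    cnt <- m[, sid]
    gid <- rep(names(cnt), cnt)
    if (!length(gid)) next
    recs[[sid]] <- data.frame(sample_id = sid, guide_id = gid)
  }
  tab <- do.call(rbind, recs)
  if (is.null(tab)) stop("count matrix is empty; nothing to emit")
  tab <- tab[sample(nrow(tab)), , drop = FALSE]
  tab$corrupt <- stats::runif(nrow(tab)) < corruptFraction
  spacer <- unname(sp[tab$guide_id])
  if (any(tab$corrupt)) {
    pos <- sample(20L, sum(tab$corrupt), replace = TRUE)
    orig <- substr(spacer[tab$corrupt], pos, pos)
    repl <- vapply(orig, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    substr(spacer[tab$corrupt], pos, pos) <- repl
  }
  seqs <- paste0(bc[tab$sample_id], flank5, spacer, flank3)
  reads <- muffleMcolsWarning(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(strrep("I", nchar(seqs)))))
  names(reads) <- sprintf("read_%06d %s", seq_along(seqs), tab$guide_id)
  writeFastq(reads, path)
  intact <- tab[!tab$corrupt, , drop = FALSE]
  truth <- as.data.frame(table(sample_id = intact$sample_id,
                               guide_id = intact$guide_id),
                         responseName = "reads", stringsAsFactors = FALSE)
  truth <- truth[truth$reads > 0, , drop = FALSE]
  corrupted <- as.data.frame(table(sample_id = tab$sample_id[tab$corrupt]),
                             responseName = "reads",
                             stringsAsFactors = FALSE)
  list(path = path, n_reads = length(reads),
       truth = list(assigned = truth, corrupted = corrupted))
}

#' Recovery and calibration experiment over replicate simulations
#'
#' Runs the full scoring and contrast pipeline on \code{nSeeds}
#' independent simulations of one configuration and summarises, against
#' the simulator's ground truth: sensitivity for planted opposite-class
#' genes (classified as the correct \code{opposite_*} class with the
#' correct signs), the false-opposite classification rate among neutral
#' genes, the fraction of neutral genes with p < 0.05, and the mean z per
#' true class.
#'
#' @param config a [simConfig()]; seeds used are \code{config$seed +
#'   0:(nSeeds-1)}.
#' @param nSeeds number of independent simulations.
#' @param zThresh,fdrThresh classification thresholds.
#' @return A list with \code{per_seed} (one row per seed) and
#'   \code{summary} (means and sds across seeds).
#' @export
recoveryExperiment <- function(config, nSeeds = 20L, zThresh = 1,
                               fdrThresh = 0.05) {
  stopifnot(inherits(config, "simConfig"), nSeeds >= 1L)
  rows <- vector("list", nSeeds)
  for (k in seq_len(nSeeds)) {
    cfg <- config
    cfg$seed <- config$seed + k - 1L
    sim <- simulateScreen(cfg)
    gs <- scoreScreen(sim$counts, sim$library, sim$design)
    res <- contrastEnvironments(gs, sim$design, zThresh = zThresh,
                                fdrThresh = fdrThresh)
    res <- merge(res, sim$truth$classes,
                 by = c("gene", "cell_line"), all.x = TRUE)
    res <- res[!res$is_control, , drop = FALSE]
    neutral <- res$class == "neutral"
    planted <- res$class %in% c("opposite_suppressor", "opposite_essential")
    correct <- planted & as.character(res$hit_class) == res$class &
      ifelse(res$class == "opposite_suppressor",
             res$z_vitro_mean < 0 & res$z_vivo_mean > 0,
             res$z_vitro_mean > 0 & res$z_vivo_mean < 0)
    rows[[k]] <- data.frame(
      seed = cfg$seed,
      n_planted = sum(planted),
      sensitivity = if (any(planted)) mean(correct[planted]) else NA_real_,
      false_opposite_rate = mean(
        res$hit_class[neutral] %in% c("opposite_suppressor",
                                      "opposite_essential")),
      frac_null_p_lt_05 = mean(res$p_value[neutral] < 0.05),
      mean_z_vitro_neutral = mean(res$z_vitro_mean[neutral]),
      mean_z_vivo_neutral = mean(res$z_vivo_mean[neutral]))
  }
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, setdiff(colnames(per_seed), "seed"), drop = FALSE]
  summary <- data.frame(metric = colnames(num),
                        mean = colMeans(num, na.rm = TRUE),
                        sd = apply(num, 2, stats::sd, na.rm = TRUE),
                        row.names = NULL)
  list(per_seed = per_seed, summary = summary)
}
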