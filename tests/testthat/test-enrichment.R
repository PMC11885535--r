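# small seeded count fixture over the toy library and a 2-replicate design
toyCounts <- function(seed = 1, lib = toyLibrary(4, 2, 4),
                      design = toyDesign("A", 2, 1), depth = 1000) {
  set.seed(seed)
  s <- sampleSheet(design)
  m <- matrix(rpois(nGuides(lib) * nrow(s), depth / nGuides(lib)),
              nGuides(lib), nrow(s),
              dimnames = list(as.data.frame(lib@guides)$guide_id,
                              s$sample_id))
  storage.mode(m) <- "integer"
  ScreenCounts(m, totalReads = colSums(m) + seq_len(ncol(m)), library = lib)
}

test_that("normalisation is counts * 1e6 / total_reads", {
  lib <- toyLibrary(1, 3, 0)
  m <- matrix(c(10L, 30L, 60L), 3, 1,
              dimnames = list(as.data.frame(lib@guides)$guide_id, "s1"))
  sc <- ScreenCounts(m, totalReads = 100, library = lib)
  norm <- normalizeCounts(sc)
  expect_equal(unname(assay(norm, "rpm")[, 1]), c(1e5, 3e5, 6e5))
  # all-zero guide row stays zero; zero-total sample is a named hard error
  m2 <- m; m2[2, ] <- 0L
  norm2 <- normalizeCounts(ScreenCounts(m2, totalReads = 100, library = lib))
  expect_equal(unname(assay(norm2, "rpm")[2, 1]), 0)
  sc0 <- ScreenCounts(m * 0L, totalReads = 0, library = lib)
  expect_error(normalizeCounts(sc0), "s1")
})

test_that("normalised column sums equal 1e6 * assigned/total", {
  sc <- toyCounts(5)
  norm <- normalizeCounts(sc)
  expect_equal(unname(colSums(assay(norm, "rpm"))),
               unname(1e6 * colData(sc)$assigned_reads /
                        colData(sc)$total_reads),
               tolerance = 1e-9)
})

test_that("paired log2 fold changes follow the closed form", {
  lib <- toyLibrary(1, 1, 0)
  d <- ScreenDesign(data.frame(
    sample_id = c("init", "sel"), cell_line = "A",
    environment = c("initial", "in_vitro"), replicate = 1L, barcode = "",
    paired_initial_id = c("", "init")))
  mk <- function(init_rpm, sel_rpm) {
    rpm <- matrix(c(init_rpm, sel_rpm), 1, 2,
                  dimnames = list("G01_g1", c("init", "sel")))
    SummarizedExperiment(assays = list(rpm = rpm))
  }
  # equal abundance -> lfc 0
  expect_equal(unname(assay(guideLogFC(mk(100, 100), d), "lfc")[1, 1]), 0)
  # 400 vs 100 with vanishing pseudocount -> 2
  expect_equal(unname(assay(guideLogFC(mk(100, 400), d,
                                       pseudocount = 1e-9), "lfc")[1, 1]),
               2, tolerance = 1e-6)
  # dropout guide: 0 vs 100 with pseudocount 1 -> log2(1/101)
  expect_equal(unname(assay(guideLogFC(mk(100, 0), d), "lfc")[1, 1]),
               log2(1 / 101))
  expect_equal(log2(1 / 101), -6.658211, tolerance = 1e-6)
  # selected sample without a pair is a hard error
  d_bad <- ScreenDesign(data.frame(
    sample_id = c("other", "sel"), cell_line = "A",
    environment = c("initial", "in_vitro"), replicate = 1L, barcode = "",
    paired_initial_id = c("", "other")))
  expect_error(guideLogFC(mk(1, 1), d_bad), "other")
})

test_that("gene scores are the mean of guide fold changes", {
  lib <- toyLibrary(1, 5, 0)
  sel <- data.frame(sample_id = "s", cell_line = "A",
                    environment = "in_vitro", replicate = 1L,
                    barcode = "", paired_initial_id = "i")
  lfc <- SummarizedExperiment(
    assays = list(lfc = matrix(1:5, 5, 1,
      dimnames = list(as.data.frame(lib@guides)$guide_id, "s"))),
    colData = S4Vectors::DataFrame(sel, row.names = "s"))
  gs <- geneScores(lfc, lib)
  expect_equal(unname(assay(gs, "score")[1, 1]), 3)
  # a single-guide gene passes its lfc through
  lib1 <- toyLibrary(2, 1, 0)
  lfc1 <- SummarizedExperiment(
    assays = list(lfc = matrix(c(0.7, -1.2), 2, 1,
      dimnames = list(as.data.frame(lib1@guides)$guide_id, "s"))),
    colData = S4Vectors::DataFrame(sel, row.names = "s"))
  expect_equal(unname(assay(geneScores(lfc1, lib1), "score")[, 1]),
               c(0.7, -1.2))
})

test_that("whole score/z chain matches an explicit-loop oracle", {
  lib <- toyLibrary(20, 3, 9)
  design <- toyDesign("A", 2, 2)
  sc <- toyCounts(7, lib, design, depth = 5000)
  gs <- scoreScreen(sc, lib, design)
  oracle <- oracleScoreChain(guideCounts(sc),
                             setNames(colData(sc)$total_reads, colnames(sc)),
                             design, lib)
  sel_ids <- colnames(gs)
  expect_equal(assay(gs, "score"), oracle$score[rownames(gs), sel_ids],
               tolerance = 1e-9)
  expect_equal(assay(gs, "z"), oracle$z[rownames(gs), sel_ids],
               tolerance = 1e-9)
  expect_equal(unname(colData(gs)$control_mean), oracle$control_mean,
               tolerance = 1e-9)
  expect_equal(unname(colData(gs)$score_sd), oracle$score_sd,
               tolerance = 1e-9)
})

test_that("centering zeroes genes sitting at the control mean", {
  # control guides all at lfc 0.5 and a gene scoring 0.5 -> z = 0
  lib <- toyLibrary(3, 2, 4)
  ids <- as.data.frame(lib@guides)$guide_id
  lfc_m <- matrix(c(0.5, 0.5, 1.5, 2.5, -1.0, 0.25,
                    rep(0.5, 4)), 10, 1, dimnames = list(ids, "s"))
  sel <- data.frame(sample_id = "s", cell_line = "A",
                    environment = "in_vitro", replicate = 1L,
                    barcode = "", paired_initial_id = "i")
  lfc <- SummarizedExperiment(assays = list(lfc = lfc_m),
                              colData = S4Vectors::DataFrame(sel,
                                                             row.names = "s"))
  gs <- centerAndZ(geneScores(lfc, lib), lfc, lib)
  expect_equal(unname(assay(gs, "z")["GENE01", 1]), 0)
})

test_that("z-scores are invariant to per-sample location and scale of lfc", {
  lib <- toyLibrary(10, 2, 6)
  design <- toyDesign("A", 2, 1)
  sc <- toyCounts(9, lib, design)
  norm <- normalizeCounts(sc)
  lfc <- guideLogFC(norm, design)
  base_z <- assay(centerAndZ(geneScores(lfc, lib), lfc, lib), "z")
  for (f in list(function(x) x + 2.5, function(x) x * 3)) {
    lfc2 <- lfc
    assay(lfc2, "lfc") <- f(assay(lfc, "lfc"))
    z2 <- assay(centerAndZ(geneScores(lfc2, lib), lfc2, lib), "z")
    expect_equal(z2, base_z, tolerance = 1e-9)
  }
})

test_that("control pseudo-gene z averages to zero in every sample", {
  lib <- toyLibrary(15, 5, 20)
  design <- toyDesign("A", 3, 1)
  gs <- scoreScreen(toyCounts(13, lib, design, depth = 8000), lib, design)
  ctrl_z <- assay(gs, "z")[rowData(gs)$is_control, , drop = FALSE]
  expect_lt(max(abs(colMeans(ctrl_z))), 1e-9)
})

test_that("degenerate samples and too-small libraries are refused", {
  lib <- toyLibrary(3, 2, 4)
  design <- toyDesign("A", 2, 1)
  sc <- toyCounts(3, lib, design)
  norm <- normalizeCounts(sc)
  lfc <- guideLogFC(norm, design)
  assay(lfc, "lfc")[] <- 1  # constant scores -> zero dispersion
  gs <- geneScores(lfc, lib)
  expect_error(centerAndZ(gs, lfc, lib), "degenerate")
})

test_that("null simulation gives centred, unit-scale z distributions", {
  # The per-sample mean z carries two sampling errors: the mean over genes
  # (variance 1/n_genes) and the control-centering offset, whose variance
  # is that of a mean over the control pseudo-genes and does not shrink
  # with gene count. Both terms enter the 3-sigma bound.
  for (seed in c(2, 12)) {
    sim <- simulateScreen(simConfig(cellLines = "A", seed = seed))
    gs <- scoreScreen(sim$counts, sim$library, sim$design)
    z <- assay(gs, "z")
    ctrl <- rowData(gs)$is_control
    se <- sqrt(1 / nrow(z) +
                 mean(apply(z[ctrl, , drop = FALSE], 2, var)) / sum(ctrl))
    expect_lt(max(abs(colMeans(z))), 3 * se)
    expect_true(all(apply(z, 2, sd) > 0.9 & apply(z, 2, sd) < 1.1))
  }
})
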