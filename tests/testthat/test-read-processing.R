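makeFastq <- function(seqs, path) {
  writeLines(as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

test_that("exact-barcode demultiplexing routes reads and conserves totals", {
  d <- ScreenDesign(data.frame(
    sample_id = c("s1", "s2"), cell_line = "A",
    environment = c("initial", "in_vitro"), replicate = 1L,
    barcode = c("AAAA", "CCCC"), paired_initial_id = c("", "s1")))
  fq <- withr::local_tempfile(fileext = ".fastq")
  makeFastq(paste0(c("AAAA", "AAAA", "CCCC", "AAAT"), strrep("G", 30)), fq)
  dm <- demultiplexReads(fq, d, barcodeOffset = 0, maxMismatch = 0)
  tallies <- stats::setNames(dm$report$reads, dm$report$sample_id)
  expect_equal(unname(tallies[c("s1", "s2", "unmatched")]), c(2L, 1L, 1L))
  expect_equal(sum(dm$report$reads), 4L)
  # one mismatch tolerated when asked
  dm1 <- demultiplexReads(fq, d, maxMismatch = 1)
  expect_equal(dm1$report$reads[dm1$report$sample_id == "s1"], 3L)
})

test_that("demultiplexing matches a brute-force per-read Hamming oracle", {
  cfg <- simConfig(nGenes = 8, nControls = 4, cellLines = "A",
                   replicates = 2, micePerReplicate = 1, depth = 400,
                   seed = 11)
  sim <- simulateScreen(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  out <- simulateFastq(sim$counts, sim$library, sim$design, fq,
                       corruptFraction = 0.05, seed = 5)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  bcs <- sampleSheet(sim$design)$barcode
  for (mm in 0:1) {
    dm <- demultiplexReads(fq, sim$design, maxMismatch = mm)
    oracle <- oracleDemux(reads, bcs, offset = 0, maxMismatch = mm)
    expected <- table(factor(sampleSheet(sim$design)$sample_id[oracle],
                             sampleSheet(sim$design)$sample_id))
    got <- stats::setNames(dm$report$reads, dm$report$sample_id)
    expect_equal(unname(got[names(expected)]), unname(as.integer(expected)))
    expect_equal(got[["unmatched"]], sum(is.na(oracle)))
  }
})

test_that("zero-mismatch counting: fixed offset and scan agree with examples", {
  lib <- toyLibrary(2, 1, 0)  # guides G01_g1, G02_g1
  sp <- protospacers(lib)
  reads <- c(paste0("ACGT", sp[[1]], "GG"),
             paste0("ACGT", sp[[1]], "GG"),
             paste0("ACGT", sp[[2]], "GG"))
  for (mode in list(4L, "scan")) {
    res <- countGuides(reads, lib, spacerOffset = mode)
    expect_equal(unname(res$counts), c(2L, 1L))
    expect_equal(res$unassigned, 0L)
  }
  # one mismatch in the protospacer -> unassigned under the 0-mismatch rule
  mut <- sub("^(ACGT.)(.)", "\\1N", reads[1])
  res <- countGuides(mut, lib, spacerOffset = "scan")
  expect_equal(sum(res$counts), 0L)
  expect_equal(res$unassigned, 1L)
  # reads shorter than the window are unassigned, not an error
  res <- countGuides("ACGTAC", lib, spacerOffset = "scan")
  expect_equal(res$unassigned, 1L)
})

test_that("scan-mode counting matches the brute-force substring oracle", {
  cfg <- simConfig(nGenes = 10, nControls = 5, cellLines = "A",
                   replicates = 2, micePerReplicate = 1, depth = 800,
                   seed = 21)
  sim <- simulateScreen(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulateFastq(sim$counts, sim$library, sim$design, fq,
                corruptFraction = 0.1, seed = 2)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  res <- countGuides(reads, sim$library, spacerOffset = "scan")
  oracle <- oracleScanCounts(reads, protospacers(sim$library))
  expect_identical(res$counts, oracle$counts)
  expect_identical(res$unassigned, oracle$unassigned)
  expect_identical(res$ambiguous, oracle$ambiguous)
})

test_that("counting is invariant to read order", {
  cfg <- simConfig(nGenes = 6, nControls = 4, cellLines = "A",
                   replicates = 2, micePerReplicate = 1, depth = 300,
                   seed = 31)
  sim <- simulateScreen(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  simulateFastq(sim$counts, sim$library, sim$design, fq, seed = 3)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  shuffled <- reads[rev(seq_along(reads))]
  expect_identical(countGuides(reads, sim$library)$counts,
                   countGuides(shuffled, sim$library)$counts)
})

test_that("counting per demultiplexed sample reproduces simulator tallies", {
  cfg <- simConfig(nGenes = 8, nControls = 4, cellLines = "A",
                   replicates = 2, micePerReplicate = 1, depth = 500,
                   seed = 41)
  sim <- simulateScreen(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  out <- simulateFastq(sim$counts, sim$library, sim$design, fq, seed = 4)
  dm <- demultiplexReads(fq, sim$design)
  cts <- countScreen(dm, sim$library, sim$design)
  expect_identical(guideCounts(cts), guideCounts(sim$counts))
  # demux totals (not just assigned) are carried as total_reads
  expect_equal(sum(colData(cts)$total_reads), out$n_reads)
})

test_that("count matrix TSV round-trips with totals footer", {
  lib <- toyLibrary(2, 2, 2)
  m <- matrix(c(10L, 0L, 5L, 7L, 1L, 2L), nrow = 6, ncol = 1,
              dimnames = list(as.data.frame(lib@guides)$guide_id, "s1"))
  m <- cbind(m, s2 = c(0L, 3L, 2L, 8L, 0L, 1L))
  sc <- ScreenCounts(m, totalReads = c(40, 20), library = lib)
  expect_equal(unname(colData(sc)$assigned_reads), c(25, 14))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(sc, path)
  sc2 <- readCountMatrix(path, lib)
  expect_identical(guideCounts(sc2), guideCounts(sc))
  expect_equal(colData(sc2)$total_reads, colData(sc)$total_reads)
})

test_that("count matrix loader validates guides and totals", {
  lib <- toyLibrary(2, 1, 0)
  m <- matrix(1:2, 2, 1, dimnames = list(c("G01_g1", "NOT_A_GUIDE"), "s1"))
  expect_error(ScreenCounts(m, library = lib), "NOT_A_GUIDE")
  # totals absent -> assigned with a warning
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("guide_id\ts1", "G01_g1\t3", "G02_g1\t4"), path)
  expect_warning(sc <- readCountMatrix(path, lib), "total_reads")
  expect_equal(unname(colData(sc)$total_reads), 7)
  # negative / non-integer cells are hard errors
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("guide_id\ts1", "G01_g1\t-3", "G02_g1\t4"), path2)
  expect_error(readCountMatrix(path2, lib), "non-negative")
})
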