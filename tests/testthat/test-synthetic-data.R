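test_that("genome generation places every window and is byte-deterministic", {
  spec <- synthSpec(nGenes = 10L, upBp = 2500L, downBp = 2500L,
                    chromLength = 200000L, seed = 41)
  ds <- generateGenome(spec)
  expect_identical(nrow(ds$peaks), 10L)
  expect_identical(Biostrings::width(ds$genome)[[1]], 200000L)
  full <- plantAndLabel(ds)
  expect_identical(unname(nchar(full$windows)), rep(5000L, 10))

  d1 <- tempfile(); d2 <- tempfile()
  writeDataset(plantAndLabel(generateGenome(spec)), d1)
  writeDataset(plantAndLabel(generateGenome(spec)), d2)
  for (f in c("genome.fa", "peaks.tsv", "halflife.tsv", "tf.tsv", "labels.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }

  expect_error(generateGenome(synthSpec(nGenes = 100L, chromLength = 1000L)),
               "infeasible placement")
})

test_that("the background base composition is uniform (chi-squared at alpha = 0.01)", {
  spec <- synthSpec(nGenes = 1L, upBp = 50000L, downBp = 50000L, seed = 42)
  ds <- generateGenome(spec)
  counts <- Biostrings::alphabetFrequency(ds$genome)[1, c("A", "C", "G", "T")]
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("with zero noise and zero aux effects, labels equal effect-weighted scan counts", {
  spec <- synthSpec(nGenes = 25L, upBp = 800L, downBp = 400L,
                    motifs = list(
                      list(motif = "TGACGTCATTGGCCAATCAG", effect = 0.5,
                           meanCopies = 6),
                      list(motif = "GGGCGGGGCGGGAATTCCTC", effect = -0.25,
                           meanCopies = 3)),
                    halflifeEffect = numeric(8), tfEffect = numeric(181),
                    noiseSd = 0, seed = 43)
  ds <- simulateDataset(spec)
  # independent oracle: Biostrings pattern counting on the oriented windows
  win <- Biostrings::DNAStringSet(ds$windows)
  c1 <- Biostrings::vcountPattern("TGACGTCATTGGCCAATCAG", win)
  c2 <- Biostrings::vcountPattern("GGGCGGGGCGGGAATTCCTC", win)
  expect_equal(unname(ds$labels[, 1]), 0.5 * c1 - 0.25 * c2)
  expect_identical(unname(ds$motifCounts[, 1]), c1)
  expect_identical(unname(ds$motifCounts[, 2]), c2)
  # planted counts behave like the Poisson intensity they were drawn from
  expect_gt(mean(c1), 3); expect_lt(mean(c1), 9)
})

test_that("with zero motif effect and zero noise, labels are a pure half-life function", {
  spec <- synthSpec(nGenes = 20L, upBp = 400L, downBp = 200L,
                    motifs = list(list(motif = "TGACGTCA", effect = 0,
                                       meanCopies = 3)),
                    tfEffect = numeric(181), noiseSd = 0, seed = 44)
  ds <- simulateDataset(spec)
  expect_equal(unname(ds$labels[, 1]),
               as.numeric(ds$halflife %*% spec$halflifeEffect))
})

test_that("the closed-form R-squared ceiling matches the true generative predictor empirically", {
  spec <- ablationSpec(seed = 45)
  ds <- simulateDataset(spec)
  latent <- as.numeric(
    ds$motifCounts %*% vapply(spec$motifs, `[[`, 0, "effect") +
      ds$halflife %*% spec$halflifeEffect + ds$tf %*% spec$tfEffect)
  empirical <- rSquared(ds$labels[, 1], latent)
  expect_lt(abs(empirical - plantedR2Ceiling(spec)), 0.03)
  # and the ceiling decomposes monotonically over feature groups
  expect_lt(plantedR2Ceiling(spec, "dna"),
            plantedR2Ceiling(spec, c("dna", "halflife")))
  expect_lt(plantedR2Ceiling(spec, c("dna", "halflife")),
            plantedR2Ceiling(spec))
})

test_that("written datasets round-trip losslessly through gene-table assembly", {
  spec <- synthSpec(nGenes = 8L, upBp = 350L, downBp = 250L,
                    motifs = list(list(motif = seq2expr:::DEFAULT_MOTIF,
                                       effect = 0.2, meanCopies = 5)),
                    seed = 46)
  ds <- simulateDataset(spec)
  outDir <- tempfile()
  paths <- writeDataset(ds, outDir)
  gt <- assembleGeneTable(paths[["peaks"]], paths[["genome"]],
                          windowSpecs = list(main = c(spec$upBp, spec$downBp)),
                          labelPath = paths[["labels"]],
                          halflifePath = paths[["halflife"]],
                          tfPath = paths[["tf"]])
  expect_identical(length(geneIds(gt)), 8L)
  expect_identical(geneIds(gt), ds$peaks$gene_id)
  # windows re-extracted from FASTA equal the generator's oriented windows
  expect_identical(windowSequences(gt), unname(ds$windows))
  expect_equal(unname(expressionLabels(gt)), unname(ds$labels))
  expect_equal(unname(halfLife(gt)), unname(ds$halflife))
  expect_equal(unname(tfTargets(gt)), unname(ds$tf))
  # and the in-memory builder agrees with the file route
  gtMem <- synthGeneTable(ds)
  expect_identical(windowSequences(gtMem), windowSequences(gt))
})

test_that("multi-label mode emits one column per tissue with heterogeneous noise", {
  spec <- synthSpec(nGenes = 40L, upBp = 300L, downBp = 150L, nLabels = 57L,
                    motifs = list(list(motif = seq2expr:::DEFAULT_MOTIF,
                                       effect = 0.2, meanCopies = 4)),
                    seed = 47)
  ds <- simulateDataset(spec)
  expect_identical(dim(ds$labels), c(40L, 57L))
  paths <- writeDataset(ds, tempfile())
  lab <- utils::read.delim(paths[["labels"]])
  expect_identical(ncol(lab), 58L)   # gene_id + 57 tissues
  # labels share a latent signal but differ across tissues
  expect_gt(stats::cor(ds$labels[, 1], ds$labels[, 2]), 0.2)
  expect_false(identical(ds$labels[, 1], ds$labels[, 2]))
})

test_that("degenerate motif specifications are rejected", {
  expect_error(
    simulateDataset(synthSpec(nGenes = 3L, upBp = 10L, downBp = 5L,
                              halflifeEffect = numeric(8),
                              tfEffect = numeric(181), noiseSd = 0,
                              seed = 48)),
    "longer than")
  # density too high to place without overlap
  expect_error(
    simulateDataset(synthSpec(nGenes = 3L, upBp = 60L, downBp = 40L,
                              motifs = list(list(motif = strrep("ACGT", 10),
                                                 effect = 1, meanCopies = 40)),
                              halflifeEffect = numeric(8),
                              tfEffect = numeric(181), noiseSd = 0,
                              seed = 49)),
    "infeasible placement")
})
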