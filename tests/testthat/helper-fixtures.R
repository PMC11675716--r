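# Shared fixture builders; everything is generated in code at test time.

randomSeq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent reverse-complement oracle (no Biostrings, no package internals).
oracleRevComp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

writeTempPeaks <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

writeTempTable <- function(ids, mat, colPrefix = "v") {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = ids, mat, check.names = FALSE)
  colnames(df) <- c("gene_id", paste0(colPrefix, seq_len(ncol(mat))))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# A deliberately tiny planted dataset for fast training bookkeeping tests.
tinyLearnableData <- function(nGenes = 120L, seed = 7L, dim = 8L) {
  spec <- synthSpec(nGenes = nGenes, upBp = 1200L, downBp = 600L,
                    motifs = list(list(motif = seq2expr:::DEFAULT_MOTIF,
                                       effect = 0.3, meanCopies = 10)),
                    halflifeEffect = numeric(8), tfEffect = numeric(181),
                    seed = seed)
  ds <- simulateDataset(spec)
  gt <- synthGeneTable(ds)
  be <- mockEmbedder("token_chunk", dim = dim, seed = 0)
  list(spec = spec, ds = ds, gt = gt,
       data = assembleBundles(gt, list(list(backend = be, window = "main"))))
}
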