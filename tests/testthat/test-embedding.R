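test_that("mock token embeddings are deterministic and key-sensitive", {
  a1 <- mockEmbedToken("ACGTTC", 768, 0)
  a2 <- mockEmbedToken("ACGTTC", 768, 0)
  expect_identical(a1, a2)
  expect_length(a1, 768L)
  expect_false(identical(a1, mockEmbedToken("ACGTTG", 768, 0)))
  expect_false(identical(a1, mockEmbedToken("ACGTTC", 768, 1)))
  # embedding must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(mockEmbedToken("AAAAAA", 16, 0)); after <- runif(1)
  expect_identical(before, after)
})

test_that("fragment embedding yields one row per content token and respects capacity", {
  be <- mockEmbedder("token_chunk", dim = 16, seed = 0)
  frag <- chunkTokens(kmerTokenize(randomSeq(505, seed = 21), 6), 500)[[1]]
  m1 <- embedFragment(be, frag)
  expect_identical(dim(m1), c(500L, 16L))
  expect_identical(m1, embedFragment(be, frag))    # bitwise repeatable
  expect_true(all(is.finite(m1)))

  tiny <- mockEmbedder("token_chunk", dim = 4, maxTokens = 10, seed = 0)
  expect_error(embedFragment(tiny, frag), "capacity.*re-chunk")
})

test_that("mean pooling is the exact column mean", {
  expect_identical(meanPool(rbind(c(0, 2), c(2, 0))), c(1, 1))
  v <- c(0.3, -1, 2, 0.5, 7)
  expect_identical(meanPool(matrix(rep(v, each = 4), 4, 5)), v)
  set.seed(22)
  m <- matrix(rnorm(35), 7, 5)
  # brute-force oracle
  oracle <- numeric(5)
  for (j in 1:5) { s <- 0; for (i in 1:7) s <- s + m[i, j]; oracle[j] <- s / 7 }
  expect_equal(meanPool(m), oracle)
  expect_error(meanPool(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("pooled mock embeddings depend only on the token multiset", {
  be <- mockEmbedder("token_chunk", dim = 8, seed = 3)
  toks <- kmerTokenize(randomSeq(40, seed = 23), 6)
  fragA <- seq2expr:::newFragment("token_chunk", 0, 40, tokens = toks)
  set.seed(24)
  fragB <- seq2expr:::newFragment("token_chunk", 0, 40, tokens = sample(toks))
  expect_equal(meanPool(embedFragment(be, fragA)),
               meanPool(embedFragment(be, fragB)))
})

test_that("pooled mock embedding is linear in token counts (count x embedding oracle)", {
  be <- mockEmbedder("token_chunk", dim = 8, seed = 0)
  s <- randomSeq(30, seed = 25)
  toks <- kmerTokenize(s, 6)
  em <- sequenceEmbedding(be, s, geneId = "toy")
  # oracle: count vector over unique tokens times per-token embedding matrix
  uniq <- unique(toks)
  counts <- as.numeric(table(factor(toks, levels = uniq)))
  E <- t(vapply(uniq, function(t) mockEmbedToken(t, 8, 0), numeric(8)))
  oracle <- as.numeric(counts %*% E) / length(toks)
  expect_equal(as.numeric(embeddingMatrix(em)[1, ]), oracle)
})

test_that("sequence embedding produces the fragment counts the tokenization module predicts", {
  beK <- mockEmbedder("token_chunk", dim = 8, seed = 0)
  beB <- mockEmbedder("bp_window", dim = 8, seed = 0)
  set.seed(26)
  for (L in c(505, sample(600:5000, 4))) {
    s <- randomSeq(L)
    expect_identical(nrow(embeddingMatrix(sequenceEmbedding(beK, s))),
                     tokenChunkCount(L, 6, 500))
    expect_identical(nrow(embeddingMatrix(sequenceEmbedding(beB, s))),
                     bpWindowCount(L, 2000, 500))
  }
})

test_that("pooled components lie within the column range of the token matrix", {
  be <- mockEmbedder("token_chunk", dim = 6, seed = 5)
  frag <- chunkTokens(kmerTokenize(randomSeq(80, seed = 27), 6), 30)[[1]]
  m <- embedFragment(be, frag)
  pooled <- meanPool(m)
  expect_true(all(pooled >= apply(m, 2, min) - 1e-12))
  expect_true(all(pooled <= apply(m, 2, max) + 1e-12))
})

test_that("embedding cache round-trips losslessly and distinguishes miss from I/O failure", {
  be <- mockEmbedder("token_chunk", dim = 8, seed = 0)
  cacheDir <- file.path(tempfile(), "cache")
  ems <- lapply(1:20, function(i) {
    sequenceEmbedding(be, randomSeq(150, seed = 300 + i),
                      geneId = sprintf("g%02d", i))
  })
  for (e in ems) cacheStore(cacheDir, e)

  set.seed(28)
  for (i in sample(20)) {
    back <- cacheLoad(cacheDir, sprintf("g%02d", i), be)
    expect_identical(embeddingMatrix(back), embeddingMatrix(ems[[i]]))
    expect_identical(back@spans, ems[[i]]@spans)
  }
  expect_true(cacheContains(cacheDir, "g01", be))
  expect_false(cacheContains(cacheDir, "nope", be))
  expect_error(cacheLoad(cacheDir, "nope", be), class = "cacheMissError")
  expect_error(cacheLoad(file.path(tempdir(), "no-such-cache"), "g01", be),
               class = "cacheIOError")
  mf <- cacheManifest(cacheDir)
  expect_identical(nrow(mf), 20L)
  expect_identical(unique(mf$dim), 8L)
})

test_that("cachePopulate fills a cache usable by bundle assembly", {
  spec <- synthSpec(nGenes = 6L, upBp = 300L, downBp = 200L,
                    halflifeEffect = numeric(8), tfEffect = numeric(181),
                    motifs = list(list(motif = "TGACGTCA", effect = 0.3,
                                       meanCopies = 4)),
                    seed = 31)
  gt <- synthGeneTable(simulateDataset(spec))
  be <- mockEmbedder("token_chunk", dim = 8, seed = 0)
  cacheDir <- tempfile()
  cachePopulate(gt, be, cacheDir)
  data <- assembleBundles(gt, list(list(backend = be@name)), cache = cacheDir)
  expect_identical(dim(data$branches[[1]]), c(6L, 1L, 8L))
  # cache miss names the offending gene
  expect_error(cacheLoad(cacheDir, "g9999", be), "g9999")
})
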