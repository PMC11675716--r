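test_that("R-squared matches its defining identities and a hand-computed case", {
  y <- c(0.4, 1.1, -2, 3.3, 0)
  expect_identical(rSquared(y, y), 1)
  expect_identical(rSquared(y, rep(mean(y), 5)), 0)
  # SS_res = 1, SS_tot = 2
  expect_identical(rSquared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(rSquared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(rSquared(1:3, 1:4), "length")
})

test_that("the learning-rate schedule steps from 0.002 to 0.0002 after epoch 10", {
  cfg <- trainConfig()
  expect_identical(lrAtEpoch(cfg, 1), 0.002)
  expect_identical(lrAtEpoch(cfg, 10), 0.002)
  expect_identical(lrAtEpoch(cfg, 11), 0.0002)
  expect_identical(lrAtEpoch(cfg, 100), 0.0002)
})

test_that("training configuration validates its invariants", {
  expect_error(trainConfig(epochs = 10, patience = 20), "patience")
  expect_error(trainConfig(split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(trainConfig(split = list(a = 1:3)), "train/val/test")
  expect_silent(trainConfig(split = list(train = 1:8, val = 9:10, test = 11:12)))
})

test_that("k-fold partitions are disjoint, exhaustive, balanced and seed-deterministic", {
  f100 <- kfold(100, 10, seed = 1)
  expect_length(f100, 10L)
  expect_true(all(lengths(f100) == 10L))

  f57 <- kfold(57, 10, seed = 2)
  expect_true(all(lengths(f57) %in% c(5L, 6L)))
  expect_identical(sum(lengths(f57)), 57L)

  set.seed(3)
  for (i in 1:5) {
    n <- sample(10:80, 1); k <- sample(2:10, 1)
    f <- kfold(n, k, seed = i)
    expect_identical(sort(unname(unlist(f))), seq_len(n))        # partition law
    expect_lte(max(lengths(f)) - min(lengths(f)), 1L)
  }
  expect_identical(kfold(30, 5, seed = 9), kfold(30, 5, seed = 9))
  expect_error(kfold(5, 10), "folds")
})

test_that("training keeps history, restores the best-validation weights and stops early", {
  fix <- tinyLearnableData()
  m <- buildModel10500(useDnabert = TRUE, useDnabert2 = FALSE,
                       dnabertShape = dim(fix$data$branches[[1]])[2:3],
                       seed = 1)
  cfg <- trainConfig(epochs = 5, batchSize = 32, patience = 5, seed = 1)
  out <- trainModel(m, fix$data, cfg)
  expect_lte(nrow(out$history), 5L)
  expect_identical(out$history$epoch, seq_len(nrow(out$history)))
  expect_true(out$report$bestEpoch %in% out$history$epoch)
  # best weights: returned validation loss equals the minimum seen
  expect_identical(out$report$bestValLoss, min(out$history$valLoss))
  expect_true(all(c("trainLoss", "valLoss", "valR2", "lr") %in%
                    names(out$history)))
  # split is disjoint and covers all genes
  sp <- out$report$split
  expect_identical(sort(unname(unlist(sp))), seq_len(nrow(fix$data$labels)))
})

test_that("identical seeds give identical training histories", {
  fix <- tinyLearnableData()
  runOnce <- function() {
    m <- buildModel10500(useDnabert = TRUE, useDnabert2 = FALSE,
                         dnabertShape = dim(fix$data$branches[[1]])[2:3],
                         seed = 5)
    trainModel(m, fix$data, trainConfig(epochs = 4, batchSize = 32, seed = 5,
                                        patience = 4))
  }
  a <- runOnce(); b <- runOnce()
  expect_identical(a$history, b$history)
  expect_identical(a$report$testR2, b$report$testR2)
  expect_identical(a$model@params, b$model@params)
})

test_that("early stopping halts after patience epochs without improvement", {
  fix <- tinyLearnableData(nGenes = 80L, seed = 9)
  m <- buildModel10500(useDnabert = TRUE, useDnabert2 = FALSE,
                       dnabertShape = dim(fix$data$branches[[1]])[2:3],
                       seed = 2)
  cfg <- trainConfig(epochs = 40, batchSize = 32, patience = 3, seed = 2)
  out <- trainModel(m, fix$data, cfg)
  h <- out$history
  if (nrow(h) < 40) {
    # stopped early: the last `patience` epochs did not improve on the best
    tail3 <- h$valLoss[(nrow(h) - 2):nrow(h)]
    expect_true(all(tail3 >= min(h$valLoss) - 1e-12))
    expect_identical(out$report$bestEpoch, which.min(h$valLoss))
  } else {
    succeed()   # ran to completion; early stopping had nothing to do
  }
})

test_that("experiment harness reports min <= avg <= max per condition over seeded runs", {
  fix <- tinyLearnableData(nGenes = 100L, seed = 12)
  rep <- runExperiment(fix$gt,
                       list(list(backend = mockEmbedder("token_chunk", dim = 8,
                                                        seed = 0),
                                 window = "main")),
                       featureSets = list("dna", c("dna", "halflife")),
                       nRuns = 2,
                       config = trainConfig(epochs = 3, batchSize = 32,
                                            patience = 3, seed = 50))
  runs <- reportRuns(rep)
  agg <- reportAggregate(rep)
  expect_identical(nrow(runs), 4L)                 # 2 feature sets x 2 runs
  expect_identical(runs$seed, c(50L, 51L, 50L, 51L))
  expect_identical(agg$condition, c("dna", "dna+halflife"))
  expect_true(all(agg$min <= agg$avg & agg$avg <= agg$max))
})

test_that("per-tissue mode trains one model per label column and flags unknown columns", {
  spec <- synthSpec(nGenes = 90L, upBp = 800L, downBp = 400L, nLabels = 4L,
                    motifs = list(list(motif = seq2expr:::DEFAULT_MOTIF,
                                       effect = 0.2, meanCopies = 5)),
                    seed = 33)
  gt <- synthGeneTable(simulateDataset(spec))
  be <- mockEmbedder("token_chunk", dim = 8, seed = 0)
  rep <- runExperiment(gt, list(list(backend = be, window = "main")),
                       featureSets = list(c("dna", "halflife", "tf")),
                       nRuns = 1,
                       config = trainConfig(epochs = 2, batchSize = 32,
                                            patience = 2, seed = 1),
                       labelColumns = c("tissue01", "tissue03"))
  agg <- reportAggregate(rep)
  expect_identical(agg$condition, c("tissue01", "tissue03"))
  expect_identical(nrow(reportRuns(rep)), 2L)
  expect_error(
    runExperiment(gt, list(list(backend = be, window = "main")),
                  nRuns = 1, labelColumns = "kidney"),
    "unknown label column")
})
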