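defaultBuilder <- function(data, reduce = "max", channels = 64L,
                           fcUnits = 64L) {
  shapes <- lapply(data$branches, function(a) dim(a)[2:3])
  force(reduce); force(channels); force(fcUnits)
  function(auxDims, nOutputs, seed) {
    if (length(shapes) == 1L) {
      buildModel10500(useDnabert = TRUE, useDnabert2 = FALSE,
                      auxDims = auxDims, nOutputs = nOutputs,
                      dnabertShape = shapes[[1L]], channels = channels,
                      fcUnits = fcUnits, reduce = reduce, seed = seed)
    } else if (length(shapes) == 2L) {
      buildModel10500(auxDims = auxDims, nOutputs = nOutputs,
                      dnabertShape = shapes[[1L]], dnabert2Shape = shapes[[2L]],
                      channels = channels, fcUnits = fcUnits,
                      reduce = reduce, seed = seed)
    } else if (length(shapes) == 4L) {
      buildModel50000(auxDims = auxDims, nOutputs = nOutputs, shapes = shapes,
                      channels = channels, fcUnits = fcUnits,
                      reduce = reduce, seed = seed)
    } else {
      stop("no default architecture for ", length(shapes), " branches")
    }
  }
}

featureSetLabel <- function(fs) {
  paste(c("dna", intersect(c("halflife", "tf"), fs)), collapse = "+")
}

#' Run a repeated-training experiment with feature ablations
#'
#' Mirrors the evaluation protocol of the expression-regression study: for
#' every condition (a feature set, or a label column in per-tissue mode) the
#' model is trained `nRuns` times with consecutive seeds `seed + 0 ...
#' seed + nRuns - 1`, and the minimum, average and maximum held-out test
#' R-squared over the runs are reported.
#'
#' @param geneTable a [GeneTable-class].
#' @param branchSpecs branch descriptors as in [assembleBundles()].
#' @param cache optional embedding cache path.
#' @param featureSets list of feature sets; each is a character vector
#'   containing `"dna"` and optionally `"halflife"` and `"tf"`.
#' @param nRuns training runs per condition.
#' @param config base [trainConfig()]; each run r overrides the seed with
#'   `config$seed + r - 1`.
#' @param labelColumns optional label column names/indices: per-tissue mode,
#'   training one model per label (using `featureSets[[1]]`).
#' @param reduce,channels,fcUnits forwarded to the default model builder.
#' @param builder optional `function(auxDims, nOutputs, seed)` returning an
#'   [ExpressionCNN-class], replacing the default architecture.
#' @return an [EvalReport-class].
#' @export
runExperiment <- function(geneTable, branchSpecs, cache = NULL,
                          featureSets = list(c("dna"),
                                             c("dna", "halflife"),
                                             c("dna", "halflife", "tf")),
                          nRuns = 10L, config = trainConfig(),
                          labelColumns = NULL,
                          reduce = "max", channels = 64L, fcUnits = 64L,
                          builder = NULL) {
  nRuns <- as.integer(nRuns)
  baseData <- assembleBundles(geneTable, branchSpecs, cache = cache,
                              features = unique(unlist(featureSets)))
  perTissue <- !is.null(labelColumns)

  runOne <- function(data, nOutputs, runSeed) {
    cfg <- config
    cfg$seed <- as.integer(runSeed)
    bld <- if (is.null(builder)) {
      defaultBuilder(data, reduce = reduce, channels = channels,
                     fcUnits = fcUnits)
    } else builder
    model <- bld(auxDims = data$auxDims, nOutputs = nOutputs, seed = cfg$seed)
    trainModel(model, data, cfg)$report$testR2
  }

  subsetAux <- function(fs) {
    feats <- intersect(c("halflife", "tf"), fs)
    aux <- NULL; auxDims <- integer(0)
    if ("halflife" %in% feats) {
      aux <- cbind(aux, halfLife(geneTable)); auxDims <- c(auxDims, 8L)
    }
    if ("tf" %in% feats) {
      aux <- cbind(aux, tfTargets(geneTable)); auxDims <- c(auxDims, 181L)
    }
    d <- baseData
    d["aux"] <- list(aux)   # keep the element even when NULL
    d$auxDims <- auxDims
    d
  }

  runs <- list()
  if (!perTissue) {
    for (fs in featureSets) {
      data <- subsetAux(fs)
      for (r in seq_len(nRuns)) {
        s <- config$seed + r - 1L
        runs[[length(runs) + 1L]] <- data.frame(
          condition = featureSetLabel(fs), run = r, seed = s,
          testR2 = runOne(data, ncol(data$labels), s),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    labels <- expressionLabels(geneTable)
    if (is.character(labelColumns) &&
        !all(labelColumns %in% colnames(labels))) {
      stop("unknown label column(s): ",
           paste(setdiff(labelColumns, colnames(labels)), collapse = ", "))
    }
    if (is.numeric(labelColumns) && any(labelColumns > ncol(labels))) {
      stop("label column index out of range")
    }
    data0 <- subsetAux(featureSets[[1L]])
    for (lc in labelColumns) {
      nm <- if (is.character(lc)) lc else colnames(labels)[lc]
      if (is.null(nm) || is.na(nm)) nm <- paste0("label", lc)
      data <- data0
      data$labels <- labels[, lc, drop = FALSE]
      for (r in seq_len(nRuns)) {
        s <- config$seed + r - 1L
        runs[[length(runs) + 1L]] <- data.frame(
          condition = nm, run = r, seed = s,
          testR2 = runOne(data, 1L, s), stringsAsFactors = FALSE)
      }
    }
  }

  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$condition), function(g) {
    data.frame(condition = g$condition[1L], min = min(g$testR2),
               avg = mean(g$testR2), max = max(g$testR2),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[match(unique(runs$condition), agg$condition), , drop = FALSE]
  rownames(agg) <- NULL
  perLabel <- if (perTissue) agg else
    data.frame(condition = character(0), min = numeric(0),
               avg = numeric(0), max = numeric(0))
  new("EvalReport", runs = runs, aggregate = agg, perLabel = perLabel,
      nRuns = nRuns)
}

#' EvalReport accessors
#' @param report an [EvalReport-class].
#' @return `reportRuns` the per-run data.frame; `reportAggregate` the
#'   min/avg/max table.
#' @name report-accessors
NULL

#' @rdname report-accessors
#' @export
reportRuns <- function(report) report@runs

#' @rdname report-accessors
#' @export
reportAggregate <- function(report) report@aggregate

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d condition(s), %d run(s) each\n",
              nrow(object@aggregate), object@nRuns))
  print(object@aggregate, row.names = FALSE, digits = 3)
})
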