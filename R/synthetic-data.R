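## Default planted regulatory element: a 30-bp composite carrying CREB-,
## CCAAT- and AP-1-like boxes. Long enough that it never arises by chance in
## an i.i.d. background and contributes 25 deterministic 6-mer tokens per
## copy, which keeps the planted signal identifiable through a low-dimensional
## random-projection embedding (see the methods vignette for the SNR budget).
DEFAULT_MOTIF <- "TGACGTCATTGGCCAATCAGGCGTGACTCA"

defaultHalflifeEffect <- function() c(0.6, -0.4, 0.3, 0.3, -0.2, 0.2, 0.1, -0.1)

defaultTfEffect <- function() {
  g <- numeric(181)
  g[seq_len(24L)] <- rep(c(0.6, -0.6), 12L)
  g
}

#' Specification of a planted-signal synthetic dataset
#'
#' Describes a miniature dataset with the structure of the real inputs —
#' genome FASTA, peak anchors, 8 half-life features, 181 binary TF-target
#' features and 1 or 57 expression labels — plus a known generative model:
#' Poisson-planted motif copies, linear effects and Gaussian noise, so the
#' achievable R-squared has a closed form (see [plantedR2Ceiling()]).
#'
#' Per gene, the label is
#' `sum_m alpha_m * count_m + beta . halflife + gamma . tf + eps`, with
#' `count_m ~ Poisson(meanCopies_m)` planted motif copies,
#' `halflife ~ N(0,1)^8`, `tf ~ Bernoulli(0.1)^181`, `eps ~ N(0, noiseSd^2)`.
#'
#' The default `noiseSd` is chosen so that the full planted signal explains
#' 80% of label variance (a theoretical R-squared ceiling of 0.8).
#'
#' @param nGenes number of genes.
#' @param upBp,downBp window extents around each anchor (defaults: a 3-kb
#'   window, 2,000 bp upstream + 1,000 bp downstream, keeping the 2:1
#'   upstream bias of the reference 10.5-kb design at miniature scale).
#' @param chromLength chromosome length; computed from the layout when NULL.
#' @param motifs list of planted elements, each
#'   `list(motif = <string>, effect = <alpha>, meanCopies = <lambda>)`. The
#'   default plants the 30-bp composite element at one copy per 100 bp of
#'   window (30 copies at the 3-kb reference window), keeping the planted
#'   density constant across window sizes.
#' @param halflifeEffect numeric(8) effect vector beta.
#' @param tfEffect numeric(181) effect vector gamma.
#' @param noiseSd label noise standard deviation; default gives ceiling 0.8.
#' @param nLabels 1 (median expression) or more (per-tissue mode, each label
#'   a rescaled noisy copy of the latent signal).
#' @param seed master seed; all draws derive from it.
#' @return list of class `synthSpec`.
#' @export
synthSpec <- function(nGenes = 2000L, upBp = 2000L, downBp = 1000L,
                      chromLength = NULL,
                      motifs = list(list(
                        motif = DEFAULT_MOTIF, effect = 0.2,
                        meanCopies = max(1, round((upBp + downBp) / 100)))),
                      halflifeEffect = defaultHalflifeEffect(),
                      tfEffect = defaultTfEffect(),
                      noiseSd = NULL, nLabels = 1L, seed = 1L) {
  stopifnot(length(halflifeEffect) == 8L, length(tfEffect) == 181L,
            length(motifs) >= 1L)
  for (m in motifs) {
    stopifnot(is.character(m$motif), nchar(m$motif) >= 1L,
              is.numeric(m$effect), is.numeric(m$meanCopies))
  }
  spec <- list(nGenes = as.integer(nGenes), upBp = as.integer(upBp),
               downBp = as.integer(downBp), chromLength = chromLength,
               motifs = motifs, halflifeEffect = halflifeEffect,
               tfEffect = tfEffect, noiseSd = noiseSd,
               nLabels = as.integer(nLabels), seed = as.integer(seed))
  if (is.null(spec$noiseSd)) {
    v <- signalVariances(spec)
    spec$noiseSd <- sqrt(sum(unlist(v)) / 4)   # ceiling 0.8
  }
  if (spec$noiseSd < 0) stop("noiseSd must be >= 0")
  structure(spec, class = "synthSpec")
}

signalVariances <- function(spec) {
  list(
    dna = sum(vapply(spec$motifs,
                     function(m) m$effect^2 * m$meanCopies, 0)),
    halflife = sum(spec$halflifeEffect^2),
    tf = sum(spec$tfEffect^2) * 0.1 * 0.9)
}

#' Closed-form R-squared ceiling of the planted model
#'
#' Variance explained by the listed feature groups divided by total label
#' variance: `sum(Var_g) / (Var_dna + Var_halflife + Var_tf + noiseSd^2)`.
#' The true generative predictor restricted to those features attains this
#' value in expectation; no model can beat it.
#'
#' @param spec a [synthSpec()].
#' @param features subset of `c("dna", "halflife", "tf")`.
#' @return numeric ceiling in (0, 1].
#' @export
plantedR2Ceiling <- function(spec, features = c("dna", "halflife", "tf")) {
  v <- signalVariances(spec)
  total <- sum(unlist(v)) + spec$noiseSd^2
  sum(unlist(v[intersect(names(v), features)])) / total
}

synthLayout <- function(spec) {
  span <- spec$upBp + spec$downBp
  gap <- 200L
  margin <- 500L
  needed <- 2L * margin + spec$nGenes * (span + gap)
  chromLength <- if (is.null(spec$chromLength)) needed else
    as.integer(spec$chromLength)
  if (chromLength < needed) {
    stop(sprintf(
      "infeasible placement: chromLength %d < %d required for %d windows",
      chromLength, needed, spec$nGenes))
  }
  list(span = span, gap = gap, margin = margin, chromLength = chromLength,
       segStarts = margin + (seq_len(spec$nGenes) - 1L) * (span + gap))
}

#' Generate the background genome and peak anchors
#'
#' An i.i.d. uniform-ACGT chromosome with one anchor per gene, placed so that
#' every window fits; strands alternate + and -. Deterministic under the spec
#' seed, to the byte.
#'
#' @param spec a [synthSpec()].
#' @return list of class `synthDataset` with `genome` (named `DNAStringSet`),
#'   `peaks` (data.frame), `layout` and `spec`; labels and features are added
#'   by [plantAndLabel()].
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "synthSpec"))
  layout <- synthLayout(spec)
  set.seed(spec$seed)
  bases <- sample(c("A", "C", "G", "T"), layout$chromLength, replace = TRUE)
  chrom <- paste(bases, collapse = "")
  ids <- sprintf("g%04d", seq_len(spec$nGenes))
  strands <- rep(c("+", "-"), length.out = spec$nGenes)
  pos <- ifelse(strands == "+",
                layout$segStarts + spec$upBp,
                layout$segStarts + spec$downBp)
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom, "chr1"))
  structure(list(genome = genome,
                 peaks = data.frame(chrom = "chr1", pos = as.integer(pos),
                                    gene_id = ids, strand = strands,
                                    stringsAsFactors = FALSE),
                 layout = layout, spec = spec),
            class = "synthDataset")
}

## Overlap-tolerant occurrence count (lookahead scan).
countOccurrences <- function(sequence, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

plantIntoSegment <- function(segChars, motifChars, nCopies, occupied) {
  span <- length(segChars)
  len <- length(motifChars)
  placed <- 0L
  tries <- 0L
  maxTries <- 200L * max(1L, nCopies)
  while (placed < nCopies) {
    tries <- tries + 1L
    if (tries > maxTries) {
      stop("infeasible placement: motif density too high for the window")
    }
    s <- sample.int(span - len + 1L, 1L)
    if (any(occupied[s:(s + len - 1L)])) next
    segChars[s:(s + len - 1L)] <- motifChars
    occupied[s:(s + len - 1L)] <- TRUE
    placed <- placed + 1L
  }
  list(segChars = segChars, occupied = occupied)
}

#' Plant motif copies and draw features, noise and labels
#'
#' For each gene, draws `Poisson(meanCopies)` copies of each motif and writes
#' them at uniform non-overlapping positions within the gene's window region
#' of the chromosome (reverse-complemented for minus-strand genes, so the
#' oriented window always carries the motif in its forward form). Half-life
#' features are standard normal, TF targets Bernoulli(0.1), and labels follow
#' the linear generative model of [synthSpec()]. The per-gene motif counts
#' entering the labels are the realized occurrence counts in the oriented
#' window, so an independent string scan reproduces them exactly.
#'
#' @param dataset output of [generateGenome()].
#' @param spec the [synthSpec()]; defaults to the one stored in `dataset`.
#' @return the dataset, completed with planted `genome`, `halflife`, `tf`,
#'   `labels`, `motifCounts` and `windows` (oriented window sequences).
#' @export
plantAndLabel <- function(dataset, spec = dataset$spec) {
  stopifnot(inherits(dataset, "synthDataset"))
  layout <- dataset$layout
  span <- layout$span
  for (m in spec$motifs) {
    if (nchar(m$motif) > span) {
      stop(sprintf("motif of %d bp is longer than the %d-bp window",
                   nchar(m$motif), span))
    }
  }
  set.seed(spec$seed + 1L)
  chrom <- as.character(dataset$genome[["chr1"]])
  n <- spec$nGenes
  ids <- dataset$peaks$gene_id
  segments <- substring(chrom, layout$segStarts + 1L, layout$segStarts + span)
  windows <- character(n)

  for (i in seq_len(n)) {
    segChars <- strsplit(segments[i], "", fixed = TRUE)[[1L]]
    occupied <- rep(FALSE, span)
    minus <- dataset$peaks$strand[i] == "-"
    for (m in spec$motifs) {
      k <- stats::rpois(1L, m$meanCopies)
      if (k == 0L) next
      motif <- if (minus) revComp(m$motif) else m$motif
      out <- plantIntoSegment(segChars, strsplit(motif, "", fixed = TRUE)[[1L]],
                              k, occupied)
      segChars <- out$segChars
      occupied <- out$occupied
    }
    segments[i] <- paste(segChars, collapse = "")
    windows[i] <- if (minus) revComp(segments[i]) else segments[i]
  }

  # realized (scan-verifiable) per-gene motif counts in oriented windows
  motifCounts <- vapply(spec$motifs, function(m) {
    vapply(windows, countOccurrences, 0L, motif = m$motif, USE.NAMES = FALSE)
  }, integer(n))
  if (is.null(dim(motifCounts))) {
    motifCounts <- matrix(motifCounts, nrow = n)
  }
  rownames(motifCounts) <- ids

  halflife <- matrix(stats::rnorm(n * 8L), n, 8L,
                     dimnames = list(ids, paste0("hl", 1:8)))
  tf <- matrix(stats::rbinom(n * 181L, 1L, 0.1), n, 181L,
               dimnames = list(ids, paste0("tf", 1:181)))
  alpha <- vapply(spec$motifs, `[[`, 0, "effect")
  latent <- as.numeric(motifCounts %*% alpha) +
    as.numeric(halflife %*% spec$halflifeEffect) +
    as.numeric(tf %*% spec$tfEffect)
  if (spec$nLabels == 1L) {
    labels <- matrix(latent + stats::rnorm(n, 0, spec$noiseSd), n, 1L,
                     dimnames = list(ids, "median"))
  } else {
    scales <- stats::runif(spec$nLabels, 0.7, 1.3)
    sds <- spec$noiseSd * stats::runif(spec$nLabels, 0.6, 1.6)
    labels <- vapply(seq_len(spec$nLabels), function(j) {
      scales[j] * latent + stats::rnorm(n, 0, sds[j])
    }, numeric(n))
    dimnames(labels) <- list(ids, sprintf("tissue%02d", seq_len(spec$nLabels)))
  }

  # write planted segments back into the chromosome in one pass
  pieces <- character(2L * n + 1L)
  prevEnd <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(chrom, prevEnd + 1L, layout$segStarts[i])
    pieces[2L * i] <- segments[i]
    prevEnd <- layout$segStarts[i] + span
  }
  pieces[2L * n + 1L] <- substr(chrom, prevEnd + 1L, nchar(chrom))
  chrom <- paste(pieces, collapse = "")

  dataset$genome <- Biostrings::DNAStringSet(stats::setNames(chrom, "chr1"))
  dataset$windows <- stats::setNames(windows, ids)
  dataset$halflife <- halflife
  dataset$tf <- tf
  dataset$labels <- labels
  dataset$motifCounts <- motifCounts
  dataset$spec <- spec
  dataset
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: [generateGenome()] followed by [plantAndLabel()].
#'
#' @param spec a [synthSpec()].
#' @return a completed `synthDataset`.
#' @export
simulateDataset <- function(spec) plantAndLabel(generateGenome(spec))

#' Write a synthetic dataset to disk
#'
#' Emits the exact file dialects the assembly step consumes: `genome.fa`,
#' headerless 4-column `peaks.tsv`, `halflife.tsv` (gene_id + 8 columns),
#' `tf.tsv` (gene_id + 181 columns) and `labels.tsv` (gene_id + 1 or more
#' columns). Output bytes are a pure function of the dataset, hence of the
#' spec seed.
#'
#' @param dataset a completed `synthDataset`.
#' @param outDir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
writeDataset <- function(dataset, outDir) {
  stopifnot(inherits(dataset, "synthDataset"), !is.null(dataset$labels))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- c(genome = file.path(outDir, "genome.fa"),
             peaks = file.path(outDir, "peaks.tsv"),
             halflife = file.path(outDir, "halflife.tsv"),
             tf = file.path(outDir, "tf.tsv"),
             labels = file.path(outDir, "labels.tsv"))
  Biostrings::writeXStringSet(dataset$genome, paths[["genome"]])
  utils::write.table(dataset$peaks, paths[["peaks"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeFeature <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeFeature(dataset$halflife, paths[["halflife"]])
  writeFeature(dataset$tf, paths[["tf"]])
  writeFeature(dataset$labels, paths[["labels"]])
  invisible(paths)
}

#' Build a GeneTable directly from a synthetic dataset in memory
#'
#' Equivalent to writing the dataset and re-assembling it from files, without
#' the I/O; used by the experiment harness.
#'
#' @param dataset a completed `synthDataset`.
#' @param windowName name for the window set.
#' @return a [GeneTable-class].
#' @export
synthGeneTable <- function(dataset, windowName = "main") {
  stopifnot(inherits(dataset, "synthDataset"), !is.null(dataset$labels))
  spec <- dataset$spec
  windows <- stats::setNames(list(unname(dataset$windows)), windowName)
  specs <- stats::setNames(
    list(c(up = spec$upBp, down = spec$downBp)), windowName)
  new("GeneTable", geneId = dataset$peaks$gene_id, windows = windows,
      windowSpecs = specs, halflife = dataset$halflife, tf = dataset$tf,
      labels = dataset$labels)
}

#' Reference synthetic study conditions
#'
#' `learnabilitySpec()` is the DNA-only condition: 2,000 genes, 3-kb windows,
#' a single planted element and noise set for a theoretical R-squared ceiling
#' of 0.8 (no auxiliary effects). `ablationSpec()` additionally plants
#' half-life and TF effects, with noise set so the full feature set has
#' ceiling 0.8; dropping feature groups lowers the ceiling, giving the
#' expected ablation ordering.
#'
#' @param seed master seed.
#' @return a [synthSpec()].
#' @export
learnabilitySpec <- function(seed = 1L) {
  spec <- synthSpec(halflifeEffect = numeric(8), tfEffect = numeric(181),
                    seed = seed)
  spec
}

#' @rdname learnabilitySpec
#' @export
ablationSpec <- function(seed = 1L) synthSpec(seed = seed)
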