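#' Parse a peak / TSS anchor file
#'
#' Reads a tab-separated, BED-like anchor file with at least four columns:
#' chromosome, anchor position (0-based, forward strand), gene id, strand.
#' Lines starting with `#` and blank lines are skipped. Records are returned
#' in file order.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos` (integer), `gene_id`,
#'   `strand`.
#' @export
parsePeaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("peak file has no records: ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  recs <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- fields[[i]]
    if (length(f) < 4L) {
      stop(sprintf("peak file line %d: expected >= 4 tab-separated columns, got %d",
                   ln, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 0L || f[2L] != as.character(pos)) {
      stop(sprintf("peak file line %d: position '%s' is not a non-negative integer",
                   ln, f[2L]))
    }
    if (!f[4L] %in% c("+", "-")) {
      stop(sprintf("peak file line %d: strand must be '+' or '-', got '%s'",
                   ln, f[4L]))
    }
    if (!nzchar(f[3L])) stop(sprintf("peak file line %d: empty gene id", ln))
    recs[[i]] <- data.frame(chrom = f[1L], pos = pos, gene_id = f[3L],
                            strand = f[4L], stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, recs)
  dup <- peaks$gene_id[duplicated(peaks$gene_id)]
  if (length(dup)) {
    stop("duplicate gene id(s) in peak file: ", paste(unique(dup), collapse = ", "))
  }
  rownames(peaks) <- NULL
  peaks
}

## Accepts a named DNAStringSet, a named character vector, or a FASTA path;
## returns a named character vector of uppercase chromosome sequences.
loadGenome <- function(genome) {
  if (inherits(genome, "seq2expr_genome")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", genome, ignore.case = TRUE)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is(genome, "DNAStringSet")) {
    seqs <- toupper(as.character(genome))
    names(seqs) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    seqs <- toupper(genome)
  } else {
    stop("genome must be a FASTA path, a named DNAStringSet, or a named character vector")
  }
  structure(seqs, class = "seq2expr_genome")
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Slice [start, end) (0-based half-open) from one chromosome string,
## N-padding any overhang beyond the chromosome boundaries.
sliceWithPadding <- function(chromSeq, start, end) {
  L <- nchar(chromSeq)
  leftPad <- max(0L, -start)
  rightPad <- max(0L, end - L)
  a <- max(0L, start)
  b <- min(L, end)
  core <- if (b > a) substr(chromSeq, a + 1L, b) else ""
  paste0(strrep("N", leftPad), core, strrep("N", rightPad))
}

#' Extract a strand-aware window around a gene anchor
#'
#' For a plus-strand gene the window is `genome[pos - upstreamBp, pos +
#' downstreamBp)`; for a minus-strand gene it is the reverse complement of
#' `genome[pos - downstreamBp, pos + upstreamBp)`. Either way "upstream" is 5'
#' of the anchor in gene orientation and the anchor base is the first
#' downstream base. Coordinates are 0-based half-open; overhangs beyond the
#' chromosome are filled with N so every gene yields a full-length window.
#'
#' @param genome FASTA path, named `DNAStringSet`, or named character vector
#'   of chromosome sequences.
#' @param peak one-row data.frame (or list) with `chrom`, `pos`, `gene_id`,
#'   `strand`, as produced by [parsePeaks()].
#' @param upstreamBp,downstreamBp window extents in bp; their sum must be
#'   positive.
#' @return a [GenomicWindow-class].
#' @export
extractWindow <- function(genome, peak, upstreamBp, downstreamBp) {
  upstreamBp <- as.integer(upstreamBp)
  downstreamBp <- as.integer(downstreamBp)
  if (upstreamBp < 0L || downstreamBp < 0L || upstreamBp + downstreamBp <= 0L) {
    stop("upstreamBp + downstreamBp must be positive")
  }
  genome <- loadGenome(genome)
  chrom <- as.character(peak$chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  pos <- as.integer(peak$pos)
  strand <- as.character(peak$strand)
  seqStr <- if (strand == "+") {
    sliceWithPadding(genome[[chrom]], pos - upstreamBp, pos + downstreamBp)
  } else if (strand == "-") {
    revComp(sliceWithPadding(genome[[chrom]], pos - downstreamBp, pos + upstreamBp))
  } else {
    stop("strand must be '+' or '-', got '", strand, "'")
  }
  new("GenomicWindow", geneId = as.character(peak$gene_id), sequence = seqStr,
      upstreamBp = upstreamBp, downstreamBp = downstreamBp)
}

readFeatureTable <- function(path, what, expectedCols = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop(what, " table must have gene_id plus value columns")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (!is.null(expectedCols) && ncol(vals) != expectedCols) {
    stop(sprintf("%s table must have %d value columns, got %d",
                 what, expectedCols, ncol(vals)))
  }
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", what, " table")
  rownames(vals) <- ids
  vals
}

#' Assemble a gene table from peaks, genome, features and labels
#'
#' Extracts one window per gene and window specification, reads auxiliary
#' feature tables and labels, and inner-joins everything on gene id. Genes
#' missing a peak or any requested feature are dropped with a message stating
#' the count. Row order follows the label file.
#'
#' @param peaks data.frame from [parsePeaks()] (or a peak file path).
#' @param genome see [extractWindow()].
#' @param windowSpecs named list of `c(up, down)` pairs, e.g.
#'   `list(main = c(7000, 3500))`.
#' @param labelPath TSV with header, gene ids in the first column and 1 or
#'   more expression columns.
#' @param halflifePath optional TSV of 8 half-life values per gene.
#' @param tfPath optional TSV of 181 binary TF-target values per gene.
#' @param logTransform apply `log10(x + 0.1)` to labels (the Xpresso-style
#'   convention); labels are consumed as-is by default.
#' @return a [GeneTable-class].
#' @export
assembleGeneTable <- function(peaks, genome,
                              windowSpecs = list(main = c(7000L, 3500L)),
                              labelPath, halflifePath = NULL, tfPath = NULL,
                              logTransform = FALSE) {
  if (is.character(peaks)) peaks <- parsePeaks(peaks)
  genome <- loadGenome(genome)
  labels <- readFeatureTable(labelPath, "label")
  halflife <- if (!is.null(halflifePath)) {
    readFeatureTable(halflifePath, "half-life", expectedCols = 8L)
  }
  tf <- if (!is.null(tfPath)) {
    readFeatureTable(tfPath, "TF-target", expectedCols = 181L)
  }

  ids <- rownames(labels)
  keep <- ids %in% peaks$gene_id
  if (!is.null(halflife)) keep <- keep & ids %in% rownames(halflife)
  if (!is.null(tf)) keep <- keep & ids %in% rownames(tf)
  nDropped <- sum(!keep)
  if (nDropped > 0L) {
    message(nDropped, " gene(s) dropped: missing peak or requested feature")
  }
  ids <- ids[keep]
  if (length(ids) == 0L) stop("empty join: no gene has all requested inputs")

  pk <- peaks[match(ids, peaks$gene_id), , drop = FALSE]
  windows <- lapply(windowSpecs, function(spec) {
    up <- as.integer(spec[[1L]]); down <- as.integer(spec[[2L]])
    vapply(seq_along(ids), function(i) {
      extractWindow(genome, pk[i, , drop = FALSE], up, down)@sequence
    }, character(1))
  })

  lab <- labels[ids, , drop = FALSE]
  if (logTransform) lab <- log10(lab + 0.1)
  new("GeneTable",
      geneId = ids,
      windows = windows,
      windowSpecs = lapply(windowSpecs, function(s)
        c(up = as.integer(s[[1L]]), down = as.integer(s[[2L]]))),
      halflife = if (!is.null(halflife)) halflife[ids, , drop = FALSE],
      tf = if (!is.null(tf)) tf[ids, , drop = FALSE],
      labels = lab)
}

#' @describeIn GeneTable-class gene id accessor.
#' @param x a GeneTable.
setMethod("geneIds", "GeneTable", function(x) x@geneId)

#' @describeIn GeneTable-class label matrix accessor.
setMethod("expressionLabels", "GeneTable", function(x) x@labels)

#' @describeIn GeneTable-class half-life matrix accessor (NULL when absent).
setMethod("halfLife", "GeneTable", function(x) x@halflife)

#' @describeIn GeneTable-class TF-target matrix accessor (NULL when absent).
setMethod("tfTargets", "GeneTable", function(x) x@tf)

#' @describeIn GeneTable-class window sequences for one window set.
#' @param which window set name; defaults to the first.
setMethod("windowSequences", "GeneTable", function(x, which = NULL) {
  if (is.null(which)) which <- names(x@windows)[1L]
  if (!which %in% names(x@windows)) {
    stop("unknown window set '", which, "'; available: ",
         paste(names(x@windows), collapse = ", "))
  }
  x@windows[[which]]
})

setMethod("show", "GeneTable", function(object) {
  cat(sprintf("GeneTable: %d genes, %d label column(s)\n",
              length(object@geneId), ncol(object@labels)))
  for (nm in names(object@windowSpecs)) {
    sp <- object@windowSpecs[[nm]]
    cat(sprintf("  window '%s': %d bp upstream + %d bp downstream\n",
                nm, sp[["up"]], sp[["down"]]))
  }
  cat(sprintf("  half-life: %s; TF targets: %s\n",
              if (is.null(object@halflife)) "absent" else "8 features",
              if (is.null(object@tf)) "absent" else "181 features"))
})

setMethod("show", "GenomicWindow", function(object) {
  cat(sprintf("GenomicWindow %s: %d bp (%d up + %d down): %s...\n",
              object@geneId, nchar(object@sequence),
              object@upstreamBp, object@downstreamBp,
              substr(object@sequence, 1L, 24L)))
})

#' Sequence of a GenomicWindow
#' @param x a [GenomicWindow-class].
#' @return character string.
#' @export
windowSequence <- function(x) {
  stopifnot(is(x, "GenomicWindow"))
  x@sequence
}
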