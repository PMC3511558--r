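# Accessors and show methods for the core classes.

#' @describeIn CellFeatureSet cells-by-features matrix (rownames are
#'   protein.image.cell keys).
#' @param x a CellFeatureSet.
#' @export
setMethod("featureMatrix", "CellFeatureSet", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' @describeIn CellFeatureSet unique protein IDs, in first-appearance order.
#' @export
setMethod("proteinIds", "CellFeatureSet", function(x) {
  unique(SummarizedExperiment::colData(x)$protein_id)
})

#' Cell-level metadata of a CellFeatureSet
#'
#' @param x a [CellFeatureSet-class].
#' @return data.frame with protein_id, image_id, cell_id per cell.
#' @export
cellKeys <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x)[, c("protein_id",
                                                     "image_id", "cell_id")])
}

#' Subset a CellFeatureSet to a set of proteins
#'
#' @param x a [CellFeatureSet-class].
#' @param proteins character vector of protein IDs to keep.
#' @return a [CellFeatureSet-class] restricted to those proteins' cells.
#' @export
subsetProteins <- function(x, proteins) {
  keep <- SummarizedExperiment::colData(x)$protein_id %in% proteins
  x[, keep]
}

setMethod("show", "CellFeatureSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CellFeatureSet:", ncol(object), "cells,", nrow(object), "features,",
      length(unique(cd$protein_id)), "proteins\n")
})

#' @describeIn LocationAnnotation the per-protein label sets.
#' @param x a LocationAnnotation.
#' @export
setMethod("labelSets", "LocationAnnotation", function(x) x@labels)

#' @describeIn LocationAnnotation protein IDs.
#' @export
setMethod("proteinIds", "LocationAnnotation", function(x) names(x@labels))

#' @describeIn LocationAnnotation declared vocabulary, or sorted union of
#'   observed labels when none was declared.
#' @export
setMethod("vocabulary", "LocationAnnotation", function(x) {
  if (length(x@vocabulary)) x@vocabulary else sort(unique(unlist(x@labels)))
})

#' @describeIn LocationAnnotation logical: exactly one label?
#' @export
setMethod("isSinglePattern", "LocationAnnotation", function(x) {
  vapply(x@labels, function(l) length(l) == 1L, TRUE)
})

#' Single-pattern labels as a named character vector
#'
#' @param x a [LocationAnnotation-class].
#' @return named character vector over the single-pattern proteins only.
#' @export
singleLabels <- function(x) {
  stopifnot(is(x, "LocationAnnotation"))
  s <- x@labels[isSinglePattern(x)]
  vapply(s, identity, "")
}

#' Restrict an annotation set to given proteins
#'
#' @param x a [LocationAnnotation-class].
#' @param proteins protein IDs to keep.
#' @return a [LocationAnnotation-class].
#' @export
subsetAnnotation <- function(x, proteins) {
  stopifnot(is(x, "LocationAnnotation"))
  new("LocationAnnotation", labels = x@labels[intersect(names(x@labels), proteins)],
      vocabulary = x@vocabulary)
}

#' Replace the label set of selected proteins
#'
#' Used by the distillation procedure to flip annotations to the
#' classifier's assignment.
#'
#' @param x a [LocationAnnotation-class].
#' @param proteins protein IDs to relabel.
#' @param labels character vector (recycled) of new single labels, or a
#'   list of label sets.
#' @return the modified [LocationAnnotation-class].
#' @export
relabel <- function(x, proteins, labels) {
  stopifnot(is(x, "LocationAnnotation"))
  if (!is.list(labels)) labels <- as.list(rep_len(labels, length(proteins)))
  lab <- x@labels
  lab[proteins] <- labels
  new("LocationAnnotation", labels = lab, vocabulary = x@vocabulary)
}

setMethod("show", "LocationAnnotation", function(object) {
  sp <- sum(isSinglePattern(object))
  cat("LocationAnnotation:", length(object@labels), "proteins (",
      sp, "single-pattern,", length(object@labels) - sp, "mixed ),",
      length(vocabulary(object)), "labels\n")
})

setMethod("length", "LocationAnnotation", function(x) length(x@labels))

setMethod("show", "SdaSelection", function(object) {
  cat("SdaSelection:", length(object@selected), "features in",
      nrow(object@log), "steps; final Wilks lambda",
      format(utils::tail(object@log$wilks, 1), digits = 4), "\n")
})

#' Selected feature names of an SdaSelection
#'
#' @param x an [SdaSelection-class].
#' @return character vector in entry order.
#' @export
selectedFeatures <- function(x) {
  stopifnot(is(x, "SdaSelection"))
  x@selected
}

#' Step log of an SdaSelection
#'
#' @param x an [SdaSelection-class].
#' @return data.frame of enter/remove steps with Wilks' lambda and partial F.
#' @export
selectionLog <- function(x) {
  stopifnot(is(x, "SdaSelection"))
  x@log
}

setMethod("show", "ConfusionTable", function(object) {
  cat("ConfusionTable:", nrow(object@table), "classes,",
      sum(object@sizes), if (object@normalized) "(row-normalized),"
      else "(counts),", "overall accuracy",
      overallAccuracy(object), "%\n")
})

#' @describeIn ConfusionTable size-weighted diagonal accuracy from either
#'   raw counts or printed row-normalized fractions plus class sizes.
#' @param x a ConfusionTable.
#' @param digits decimal places (NA = unrounded).
#' @export
setMethod("overallAccuracy", "ConfusionTable", function(x, digits = 1) {
  d <- diag(x@table)
  frac <- if (x@normalized) d else ifelse(x@sizes > 0, d / x@sizes, 0)
  acc <- 100 * sum(x@sizes * frac) / sum(x@sizes)
  if (is.na(digits)) acc else round(acc, digits)
})

#' @describeIn CrossValResult accuracy of the embedded protein-level
#'   confusion table.
#' @param x a CrossValResult.
#' @param digits decimal places (NA = unrounded).
#' @export
setMethod("overallAccuracy", "CrossValResult", function(x, digits = 1) {
  overallAccuracy(x@confusion, digits = digits)
})

#' @describeIn CrossValResult protein IDs, in result order.
#' @export
setMethod("proteinIds", "CrossValResult", function(x) x@proteins$protein_id)

#' Per-protein predictions of a CrossValResult
#'
#' @param x a [CrossValResult-class].
#' @return data.frame: protein_id, fold, true_label, predicted_label,
#'   prob_predicted.
#' @export
cvPredictions <- function(x) {
  stopifnot(is(x, "CrossValResult"))
  x@proteins
}

#' Per-protein class-probability matrix of a CrossValResult
#'
#' @param x a [CrossValResult-class].
#' @return numeric matrix, proteins x classes, rows summing to 1.
#' @export
cvProbabilities <- function(x) {
  stopifnot(is(x, "CrossValResult"))
  x@probs
}

#' Protein-level confusion table of a CrossValResult
#'
#' @param x a [CrossValResult-class].
#' @return a [ConfusionTable-class] of counts.
#' @export
cvConfusion <- function(x) {
  stopifnot(is(x, "CrossValResult"))
  x@confusion
}

setMethod("show", "CrossValResult", function(object) {
  cat("CrossValResult:", nrow(object@proteins), "proteins,",
      length(object@classes), "classes, protein-level accuracy",
      overallAccuracy(object), "%\n")
})

#' @describeIn ReannotationCandidates the entries data.frame.
#' @param x a ReannotationCandidates.
#' @export
setMethod("candidateEntries", "ReannotationCandidates", function(x) x@entries)

#' @describeIn ReannotationCandidates candidate protein IDs, in rank order.
#' @export
setMethod("proteinIds", "ReannotationCandidates", function(x) {
  x@entries$protein_id
})

setMethod("length", "ReannotationCandidates", function(x) nrow(x@entries))

setMethod("show", "ReannotationCandidates", function(object) {
  src <- sort(unique(unlist(strsplit(object@entries$sources, ";"))))
  cat("ReannotationCandidates:", nrow(object@entries), "proteins; sources:",
      paste(src, collapse = ", "), "\n")
})

setMethod("show", "DistillTrace", function(object) {
  cat("DistillTrace:", length(object@levels), "levels,",
      nrow(object@flipped), "label flips\n")
})

#' Per-level ranked disagreement lists of a DistillTrace
#'
#' @param x a [DistillTrace-class].
#' @return list of data.frames, one per recursion level.
#' @export
traceLevels <- function(x) {
  stopifnot(is(x, "DistillTrace"))
  x@levels
}

#' Label flips applied during distillation
#'
#' @param x a [DistillTrace-class].
#' @return data.frame: level, protein_id, from, to.
#' @export
traceFlips <- function(x) {
  stopifnot(is(x, "DistillTrace"))
  x@flipped
}

#' @describeIn ClusterModel the representative-cell matrix (proteins x
#'   features).
#' @param x a ClusterModel.
#' @export
setMethod("featureMatrix", "ClusterModel", function(x) x@vectors)

#' @describeIn ClusterModel protein IDs (rownames of the vectors).
#' @export
setMethod("proteinIds", "ClusterModel", function(x) rownames(x@vectors))

#' Flat cluster assignment of a ClusterModel
#'
#' @param x a [ClusterModel-class].
#' @return named integer vector protein -> cluster index.
#' @export
clusterAssignment <- function(x) {
  stopifnot(is(x, "ClusterModel"))
  x@assignment
}

#' Dominant (plurality) annotation per cluster
#'
#' @param x a [ClusterModel-class].
#' @return character vector of length k.
#' @export
dominantAnnotation <- function(x) {
  stopifnot(is(x, "ClusterModel"))
  x@dominant
}

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", nrow(object@vectors), "proteins in", object@k,
      "clusters\n")
})

#' Score table of a ProteinScores object
#'
#' @param x a [ProteinScores-class].
#' @return data.frame: protein_id, cluster, label, score1, score2.
#' @export
scoreTable <- function(x) {
  stopifnot(is(x, "ProteinScores"))
  x@scores
}

setMethod("show", "ProteinScores", function(object) {
  cat("ProteinScores:", nrow(object@scores), "proteins;",
      sum(object@scores$score1 < 1), "with score1 < 1\n")
})

#' @describeIn ReannotationTally the named outcome counts.
#' @param x a ReannotationTally.
#' @export
setMethod("outcomeCounts", "ReannotationTally", function(x) x@counts)

setMethod("show", "ReannotationTally", function(object) {
  cat("ReannotationTally (", object@total, "candidates ):\n")
  print(object@counts)
  cat("reannotation rate:", reannotationRate(object), "%\n")
})
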