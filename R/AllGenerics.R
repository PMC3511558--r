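#' Extract the cells-by-features matrix
#'
#' @param x a [CellFeatureSet-class] or [ClusterModel-class].
#' @return numeric matrix with observations in rows.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Protein identifiers carried by an object
#'
#' @param x an annoqc object keyed by protein.
#' @return character vector of protein IDs (unique, in object order).
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Per-protein label sets
#'
#' @param x a [LocationAnnotation-class].
#' @return named list of character vectors.
#' @export
setGeneric("labelSets", function(x) standardGeneric("labelSets"))

#' Label vocabulary (class order)
#'
#' @param x a [LocationAnnotation-class].
#' @return character vector: the declared vocabulary, or the sorted union
#'   of observed labels when no vocabulary was declared.
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))

#' Which proteins carry a single location label?
#'
#' @param x a [LocationAnnotation-class].
#' @return named logical vector.
#' @export
setGeneric("isSinglePattern", function(x) standardGeneric("isSinglePattern"))

#' Overall weighted classification accuracy
#'
#' The size-weighted diagonal of a confusion table,
#' \eqn{100 \sum_c n_c d_c / \sum_c n_c}, reported as a percentage.
#'
#' @param x a [ConfusionTable-class] or [CrossValResult-class].
#' @param digits decimal places for reporting (default 1); use
#'   \code{digits = NA} for the unrounded value.
#' @return numeric percentage.
#' @export
setGeneric("overallAccuracy",
           function(x, digits = 1) standardGeneric("overallAccuracy"))

#' Candidate entries as a data.frame
#'
#' @param x a [ReannotationCandidates-class].
#' @return data.frame with columns rank, protein_id, sources, score.
#' @export
setGeneric("candidateEntries", function(x) standardGeneric("candidateEntries"))

#' Outcome counts of a reannotation tally
#'
#' @param x a [ReannotationTally-class].
#' @return named integer vector over the six outcome categories.
#' @export
setGeneric("outcomeCounts", function(x) standardGeneric("outcomeCounts"))
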