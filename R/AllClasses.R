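#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats aggregate as.dist cutree dist hclust median p.adjust
#'   predict quantile rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head
NULL

#' CellFeatureSet: per-cell subcellular location features
#'
#' Container for a numeric feature matrix computed on segmented cells,
#' extending \linkS4class{SummarizedExperiment}. Columns are cells, rows are
#' features; the column data carries the grouping keys \code{protein_id},
#' \code{image_id} and \code{cell_id}. All feature values must be finite and
#' the (protein, image, cell) key triples unique.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; the single assay is
#'   named \code{"features"}.
#' @seealso [CellFeatureSet()] for construction from a cells-by-features
#'   matrix, [readFeatureTable()] for the delimited-text contract.
#' @exportClass CellFeatureSet
setClass("CellFeatureSet", contains = "SummarizedExperiment")

.validCellFeatureSet <- function(object) {
  msg <- NULL
  cd <- SummarizedExperiment::colData(object)
  need <- c("protein_id", "image_id", "cell_id")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing grouping columns:", paste(miss, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  else {
    a <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(a))
      msg <- c(msg, "feature values must be numeric")
    else if (any(!is.finite(a))) {
      bad <- which(!apply(is.finite(a), 2, all))[1L]
      msg <- c(msg, sprintf("non-finite feature value in cell '%s'",
                            colnames(object)[bad]))
    }
  }
  if (is.null(msg) ) {
    key <- paste(cd$protein_id, cd$image_id, cd$cell_id, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, sprintf("duplicate (protein,image,cell) triple: %s",
                            gsub("\r", "/", key[duplicated(key)][1L])))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("CellFeatureSet", .validCellFeatureSet)

#' Construct a CellFeatureSet
#'
#' @param features numeric matrix, cells in rows and features in columns
#'   (transposed internally to the assay orientation).
#' @param proteinId,imageId,cellId character vectors, one entry per cell.
#' @param featureNames optional feature names; defaults to the column names
#'   of \code{features}.
#' @return A [CellFeatureSet-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("f", 1:4)))
#' cfs <- CellFeatureSet(m, proteinId = c("P1", "P1", "P2"),
#'                       imageId = c("i1", "i1", "i1"),
#'                       cellId = c("c1", "c2", "c1"))
#' dim(featureMatrix(cfs))
#' @export
CellFeatureSet <- function(features, proteinId, imageId, cellId,
                           featureNames = colnames(features)) {
  features <- as.matrix(features)
  if (is.null(featureNames))
    featureNames <- paste0("f", seq_len(ncol(features)))
  stopifnot(length(proteinId) == nrow(features),
            length(imageId) == nrow(features),
            length(cellId) == nrow(features),
            length(featureNames) == ncol(features))
  a <- t(features)
  rownames(a) <- featureNames
  colnames(a) <- paste(proteinId, imageId, cellId, sep = ".")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a),
    colData = S4Vectors::DataFrame(protein_id = as.character(proteinId),
                                   image_id = as.character(imageId),
                                   cell_id = as.character(cellId),
                                   row.names = colnames(a)))
  new("CellFeatureSet", se)
}

#' LocationAnnotation: protein-level location labels
#'
#' Maps each protein to a non-empty set of subcellular location labels.
#' Proteins with exactly one label are "single-pattern"; those with more
#' are "mixed-pattern". An optional vocabulary restricts the admissible
#' labels (and fixes the class order used for deterministic tie-breaking
#' downstream).
#'
#' @slot labels named list; each element a character vector of labels.
#' @slot vocabulary character vector of admissible labels (may be empty,
#'   meaning unrestricted; then the sorted union of observed labels is used
#'   as the class order).
#' @exportClass LocationAnnotation
setClass("LocationAnnotation",
         representation(labels = "list", vocabulary = "character"))

.validLocationAnnotation <- function(object) {
  msg <- NULL
  lab <- object@labels
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    msg <- c(msg, "labels must be a uniquely named list keyed by protein_id")
  n <- vapply(lab, length, 0L)
  if (any(n == 0L))
    msg <- c(msg, sprintf("empty label set for protein '%s'",
                          names(lab)[n == 0L][1L]))
  if (any(vapply(lab, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "duplicated label within a label set")
  if (length(object@vocabulary)) {
    unknown <- setdiff(unique(unlist(lab)), object@vocabulary)
    if (length(unknown))
      msg <- c(msg, paste("labels outside vocabulary:",
                          paste(unknown, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("LocationAnnotation", .validLocationAnnotation)

#' Construct a LocationAnnotation
#'
#' @param labels named list of character vectors (one element per protein),
#'   or a named character vector for purely single-pattern sets.
#' @param vocabulary optional character vector of admissible labels.
#' @return A [LocationAnnotation-class] object.
#' @examples
#' ann <- LocationAnnotation(list(P1 = "nucleus", P2 = c("cytoplasm", "golgi")))
#' isSinglePattern(ann)
#' @export
LocationAnnotation <- function(labels, vocabulary = character()) {
  if (is.character(labels)) labels <- as.list(labels)
  labels <- lapply(labels, function(x) unique(as.character(x)))
  new("LocationAnnotation", labels = labels,
      vocabulary = as.character(vocabulary))
}

#' SdaSelection: result of stepwise discriminant feature selection
#'
#' @slot selected character vector of chosen features, in entry order
#'   (minus any later removals).
#' @slot log data.frame with one row per step: \code{step}, \code{action}
#'   ("enter"/"remove"), \code{feature}, \code{wilks} (Wilks' lambda after
#'   the step) and \code{partial_F}.
#' @exportClass SdaSelection
setClass("SdaSelection",
         representation(selected = "character", log = "data.frame"))

#' ConfusionTable: per-class confusion matrix with class sizes
#'
#' Either raw counts (rows = true class, columns = assigned class) or
#' row-normalized fractions accompanied by per-class sizes, as printed in
#' published classification tables.
#'
#' @slot table numeric matrix, square, classes in both dimensions.
#' @slot sizes numeric per-class totals (row sums for a count table).
#' @slot normalized logical; \code{TRUE} when \code{table} holds
#'   row-normalized fractions.
#' @exportClass ConfusionTable
setClass("ConfusionTable",
         representation(table = "matrix", sizes = "numeric",
                        normalized = "logical"))

.validConfusionTable <- function(object) {
  msg <- NULL
  tab <- object@table
  if (nrow(tab) != ncol(tab)) msg <- c(msg, "confusion table must be square")
  if (length(object@sizes) != nrow(tab))
    msg <- c(msg, "sizes length must match number of classes")
  if (any(object@sizes < 0)) msg <- c(msg, "negative class size")
  if (isTRUE(object@normalized)) {
    rs <- rowSums(tab)[object@sizes > 0]
    if (length(rs) && any(abs(rs - 1) > 0.06))  # printed tables round to 2 dp
      msg <- c(msg, "normalized rows must sum to ~1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ConfusionTable", .validConfusionTable)

#' Construct a ConfusionTable
#'
#' @param table square numeric matrix (counts or row fractions), with
#'   matching dimnames.
#' @param sizes per-class totals; defaults to row sums when \code{table}
#'   holds counts.
#' @param normalized whether \code{table} holds row-normalized fractions.
#' @return A [ConfusionTable-class] object.
#' @export
ConfusionTable <- function(table, sizes = NULL, normalized = FALSE) {
  table <- as.matrix(table)
  if (is.null(sizes)) {
    if (normalized) stop("sizes are required for a normalized table")
    sizes <- rowSums(table)
  }
  new("ConfusionTable", table = table, sizes = as.numeric(sizes),
      normalized = isTRUE(normalized))
}

#' CrossValResult: nested cross-validation output
#'
#' Per-protein truth, prediction and calibrated class-probability vectors
#' from nested cross-validated SVM classification, together with the
#' protein-level confusion matrix and the hyperparameters chosen in each
#' outer fold.
#'
#' @slot proteins data.frame: \code{protein_id}, \code{fold},
#'   \code{true_label}, \code{predicted_label}, \code{prob_predicted}.
#' @slot probs numeric matrix, proteins x classes; rows sum to 1.
#' @slot confusion a [ConfusionTable-class] (protein level).
#' @slot hyper data.frame: \code{fold}, \code{cost}, \code{gamma}.
#' @slot classes character class order used throughout.
#' @exportClass CrossValResult
setClass("CrossValResult",
         representation(proteins = "data.frame", probs = "matrix",
                        confusion = "ConfusionTable", hyper = "data.frame",
                        classes = "character"))

.validCrossValResult <- function(object) {
  msg <- NULL
  p <- object@probs
  if (nrow(p) != nrow(object@proteins))
    msg <- c(msg, "probs rows must match proteins rows")
  if (nrow(p) && (any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-9)))
    msg <- c(msg, "probability vectors must be non-negative and sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("CrossValResult", .validCrossValResult)

#' ReannotationCandidates: ranked proteins flagged for re-examination
#'
#' @slot entries data.frame: \code{rank} (1..n, no gaps),
#'   \code{protein_id} (unique), \code{sources} (";"-joined subset of
#'   svm/cluster/random), \code{score} (numeric, \code{NA} allowed).
#' @exportClass ReannotationCandidates
setClass("ReannotationCandidates", representation(entries = "data.frame"))

.validReannotationCandidates <- function(object) {
  e <- object@entries
  msg <- NULL
  need <- c("rank", "protein_id", "sources", "score")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, "entries need columns rank, protein_id, sources, score")
  else {
    if (anyDuplicated(e$protein_id))
      msg <- c(msg, "protein_ids must be unique within a candidate list")
    if (nrow(e) && !identical(as.integer(e$rank), seq_len(nrow(e))))
      msg <- c(msg, "ranks must be 1..n without gaps, in order")
    src <- setdiff(unlist(strsplit(e$sources, ";", fixed = TRUE)),
                   c("svm", "cluster", "random"))
    if (length(src))
      msg <- c(msg, paste("unknown source:", src[1L]))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ReannotationCandidates", .validReannotationCandidates)

#' Construct a ReannotationCandidates list
#'
#' @param proteinId character vector (unique), already in rank order.
#' @param sources single source name or vector of ";"-joined sources.
#' @param score optional numeric scores aligned with \code{proteinId}.
#' @return A [ReannotationCandidates-class] object.
#' @export
ReannotationCandidates <- function(proteinId, sources = "svm", score = NA_real_) {
  n <- length(proteinId)
  new("ReannotationCandidates",
      entries = data.frame(rank = seq_len(n),
                           protein_id = as.character(proteinId),
                           sources = rep_len(as.character(sources), n),
                           score = rep_len(as.numeric(score), n),
                           stringsAsFactors = FALSE))
}

#' DistillTrace: per-level record of the distillation procedure
#'
#' @slot levels list of data.frames (one per recursion level):
#'   \code{protein_id}, \code{assigned_label}, \code{probability},
#'   \code{rank}; sorted ascending by probability.
#' @slot flipped data.frame of label flips: \code{level},
#'   \code{protein_id}, \code{from}, \code{to}.
#' @exportClass DistillTrace
setClass("DistillTrace",
         representation(levels = "list", flipped = "data.frame"))

#' ClusterModel: representative-cell hierarchical clustering
#'
#' One representative cell vector per protein (selected features,
#' z-scored), the agglomerative tree, the AIC-chosen number of clusters,
#' the flat assignment, the dominant (plurality) annotation per cluster and
#' an optimal leaf order for reporting.
#'
#' @slot vectors numeric matrix, proteins x features (z-scored).
#' @slot tree the \code{hclust} object.
#' @slot k integer number of clusters.
#' @slot assignment named integer vector protein -> cluster (1..k).
#' @slot dominant character vector, dominant annotation per cluster.
#' @slot leafOrder integer permutation of proteins for display.
#' @exportClass ClusterModel
setClass("ClusterModel",
         representation(vectors = "matrix", tree = "ANY", k = "integer",
                        assignment = "integer", dominant = "character",
                        leafOrder = "integer"))

.validClusterModel <- function(object) {
  msg <- NULL
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(object@assignment) != nrow(object@vectors))
    msg <- c(msg, "assignment must cover every protein")
  if (length(object@assignment) &&
      !all(object@assignment %in% seq_len(object@k)))
    msg <- c(msg, "cluster indices must lie in 1..k")
  if (length(object@dominant) != object@k)
    msg <- c(msg, "one dominant annotation per cluster is required")
  if (is.null(msg)) TRUE else msg
}
setValidity("ClusterModel", .validClusterModel)

#' ProteinScores: the two cluster-based mis-annotation scores
#'
#' Score 1 is the ratio of the number of proteins of the protein's own
#' class in its cluster to the number in the dominant (plurality) class,
#' in (0, 1]. Score 2 is the distance (in normalized feature space) from
#' the protein's representative vector to the component-wise median vector
#' of the dominant-annotation proteins of its cluster, >= 0.
#'
#' @slot scores data.frame: \code{protein_id}, \code{cluster},
#'   \code{label}, \code{score1}, \code{score2}.
#' @exportClass ProteinScores
setClass("ProteinScores", representation(scores = "data.frame"))

.validProteinScores <- function(object) {
  s <- object@scores
  msg <- NULL
  if (!all(c("protein_id", "cluster", "label", "score1", "score2") %in%
           colnames(s)))
    msg <- c(msg, "scores need protein_id, cluster, label, score1, score2")
  else {
    if (any(s$score1 <= 0 | s$score1 > 1))
      msg <- c(msg, "score1 must lie in (0, 1]")
    if (any(s$score2 < 0)) msg <- c(msg, "score2 must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ProteinScores", .validProteinScores)

#' ReannotationTally: outcome counts from expert re-examination
#'
#' The six mutually exclusive outcome categories comparing the previous
#' human annotation, the automated assignment and the new human annotation
#' for each candidate protein: \code{am_right} (automated right, previous
#' wrong), \code{partially_right} (re-examination added the automated label
#' to the previous one), \code{both_right}, \code{am_wrong} (previous label
#' confirmed), \code{both_wrong} (a third assignment was made) and
#' \code{negative} (re-annotated as non-specific location).
#'
#' @slot counts named integer vector over the six categories.
#' @slot total integer, number of candidates tallied.
#' @exportClass ReannotationTally
setClass("ReannotationTally",
         representation(counts = "integer", total = "integer"))

.tallyCategories <- c("am_right", "partially_right", "both_right",
                      "am_wrong", "both_wrong", "negative")

.validReannotationTally <- function(object) {
  msg <- NULL
  if (!identical(names(object@counts), .tallyCategories))
    msg <- c(msg, paste("counts must be named:",
                        paste(.tallyCategories, collapse = ", ")))
  if (any(object@counts < 0L)) msg <- c(msg, "negative count")
  if (sum(object@counts) != object@total)
    msg <- c(msg, "counts must sum to total")
  if (is.null(msg)) TRUE else msg
}
setValidity("ReannotationTally", .validReannotationTally)

#' Construct a ReannotationTally from category counts
#'
#' @param counts numeric vector of six counts, named by category (any
#'   order) or unnamed in the canonical order \code{am_right},
#'   \code{partially_right}, \code{both_right}, \code{am_wrong},
#'   \code{both_wrong}, \code{negative}.
#' @return A [ReannotationTally-class] object.
#' @examples
#' ReannotationTally(c(21, 7, 0, 60, 9, 2))   # 99 candidates
#' @export
ReannotationTally <- function(counts) {
  if (is.null(names(counts))) names(counts) <- .tallyCategories
  counts <- as.integer(round(counts[.tallyCategories]))
  names(counts) <- .tallyCategories
  new("ReannotationTally", counts = counts, total = sum(counts))
}
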