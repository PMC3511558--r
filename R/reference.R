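# Published reference tables from the two HPA A-431 annotation QC rounds,
# shipped as plain-text TSVs: row-normalized confusion matrices with class
# sizes, and the six-category reannotation outcome tallies per candidate
# list. They are inputs to the rate/enrichment arithmetic.

#' Reference confusion matrices (HPA A-431 QC rounds)
#'
#' Row-normalized protein-level confusion fractions with per-class
#' protein counts, for the classifier before the first reannotation round
#' (11 classes, 878 proteins), before the second round (13 classes, 958
#' proteins) and after incorporating the second-round reannotations (950
#' proteins).
#'
#' @param round one of \code{"round1"}, \code{"round2"},
#'   \code{"round2_reannotated"}.
#' @return a [ConfusionTable-class] (normalized).
#' @examples
#' overallAccuracy(referenceConfusion("round1"))  # 82.4
#' @export
referenceConfusion <- function(round = c("round1", "round2",
                                         "round2_reannotated")) {
  round <- match.arg(round)
  path <- system.file("extdata", paste0("confusion_", round, ".tsv"),
                      package = "annoqc", mustWork = TRUE)
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$class
  ConfusionTable(m, sizes = df$size, normalized = TRUE)
}

#' Reference reannotation outcome tallies (HPA A-431 QC rounds)
#'
#' Six-category outcome counts from expert re-examination of the
#' candidate lists: the SVM distillation list (99 proteins round 1, 58
#' round 2), the clustering list (12, then 63), and the random baseline
#' draws evaluated alongside each (65, then 80).
#'
#' @param round \code{"round1"} or \code{"round2"}.
#' @param list one of \code{"svm"}, \code{"random_svm"}, \code{"cluster"},
#'   \code{"random_cluster"}.
#' @return a [ReannotationTally-class].
#' @examples
#' reannotationRate(referenceOutcomes("round1", "svm"))  # 39
#' @export
referenceOutcomes <- function(round = c("round1", "round2"),
                              list = c("svm", "random_svm", "cluster",
                                       "random_cluster")) {
  round <- match.arg(round)
  list <- match.arg(list)
  path <- system.file("extdata", paste0("outcomes_", round, ".tsv"),
                      package = "annoqc", mustWork = TRUE)
  df <- read.delim(path)
  ReannotationTally(setNames(df[[list]], df$category))
}
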