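# Recursive label-flip "distillation": proteins whose automated and human
# classes disagree with low classifier confidence sit near the decision
# boundary; flipping their labels to the automated assignment and
# retraining barely moves the boundary, so proteins that keep disagreeing
# with high confidence at every recursion level "distill out" as
# mis-annotation candidates.

#' Configuration of the distillation procedure
#'
#' @param N number of lowest-confidence disagreeing proteins whose labels
#'   are flipped per recursion level (default 5).
#' @param M number of recursion levels (default 20). The original study
#'   used N = 5, M = 20 on an 878-protein collection (a cumulative flip
#'   budget near 10\% of the cohort); scale N and M down accordingly for
#'   smaller cohorts.
#' @param seed integer seed for fold assignment.
#' @return list of class \code{"DistillConfig"}.
#' @export
distillConfig <- function(N = 5L, M = 20L, seed = 1L) {
  stopifnot(N >= 0L, M >= 1L)
  structure(list(N = as.integer(N), M = as.integer(M),
                 seed = as.integer(seed)),
            class = "DistillConfig")
}

#' Rank proteins whose automated and human classes disagree
#'
#' Disagreeing proteins are sorted in ascending order of the probability
#' the classifier assigned to its own (predicted) class; ties are broken
#' by protein ID.
#'
#' @param cv a [CrossValResult-class].
#' @param annotations a [LocationAnnotation-class] (the labels the
#'   classifier was trained against).
#' @return data.frame: protein_id, annotated_label, assigned_label,
#'   probability, rank; empty when all agree.
#' @export
rankDisagreements <- function(cv, annotations) {
  stopifnot(is(cv, "CrossValResult"))
  p <- cvPredictions(cv)
  ann <- .classOf(annotations)[p$protein_id]
  dis <- p$predicted_label != ann
  out <- data.frame(protein_id = p$protein_id[dis],
                    annotated_label = unname(ann[dis]),
                    assigned_label = p$predicted_label[dis],
                    probability = p$prob_predicted[dis])
  out <- out[order(out$probability, out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Distill mis-annotation candidates by recursive label flipping
#'
#' Runs nested cross-validated classification, ranks the disagreeing
#' proteins ascending by classifier-assigned probability, flips the labels
#' of the top \code{N} (lowest-probability) to the automated assignment,
#' retrains, and repeats for \code{M} levels. Flips are cumulative and
#' never reverted. The candidates are the proteins present in all
#' \code{M} ranked lists (stably misclassified with high confidence),
#' ordered by their mean within-list rank descending — most confident
#' disagreements first.
#'
#' To bound runtime, retraining reuses the fold structure, selected
#' features, normalization and tuned hyperparameters from level 0; only
#' the SVM fits are repeated at each level.
#'
#' @param table a [CellFeatureSet-class].
#' @param annotations a [LocationAnnotation-class] (single-pattern
#'   proteins are used).
#' @param cfg a [distillConfig()].
#' @param ... passed to [nestedCrossValidate()] (k, grid, selection
#'   controls).
#' @return list with \code{candidates} ([ReannotationCandidates-class],
#'   source \code{"svm"}, score = mean level-list probability) and
#'   \code{trace} ([DistillTrace-class]).
#' @export
distillCandidates <- function(table, annotations, cfg = distillConfig(), ...) {
  stopifnot(inherits(cfg, "DistillConfig"))
  single <- isSinglePattern(annotations)
  ann <- subsetAnnotation(annotations, names(single)[single])
  tab <- subsetProteins(table, proteinIds(ann))
  cv <- nestedCrossValidate(tab, ann, seed = cfg$seed, ...)
  plan <- attr(cv, "plan")
  levels <- list()
  flips <- list()
  current <- ann
  flipped <- character()
  for (m in seq_len(cfg$M)) {
    if (m > 1L) cv <- nestedCrossValidate(tab, current, plan = plan)
    lvl <- rankDisagreements(cv, current)
    levels[[m]] <- lvl
    if (m == 1L && nrow(lvl) == 0L) break
    if (m < cfg$M && cfg$N > 0L && nrow(lvl) > 0L) {
      top <- utils::head(lvl, cfg$N)
      flips[[m]] <- data.frame(level = m, protein_id = top$protein_id,
                               from = top$annotated_label,
                               to = top$assigned_label)
      current <- relabel(current, top$protein_id, top$assigned_label)
      flipped <- c(flipped, top$protein_id)
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(level = integer(), protein_id = character(),
               from = character(), to = character())
  trace <- new("DistillTrace", levels = levels, flipped = flips)
  ids <- Reduce(intersect, lapply(levels, function(l) l$protein_id))
  if (length(ids)) {
    meanRank <- vapply(ids, function(id)
      mean(vapply(levels, function(l) l$rank[l$protein_id == id], 0)), 0)
    meanProb <- vapply(ids, function(id)
      mean(vapply(levels, function(l) l$probability[l$protein_id == id], 0)), 0)
    ord <- order(-meanRank, ids)
    cand <- ReannotationCandidates(ids[ord], sources = "svm",
                                   score = meanProb[ord])
  } else {
    cand <- ReannotationCandidates(character(), sources = "svm")
  }
  list(candidates = cand, trace = trace)
}
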