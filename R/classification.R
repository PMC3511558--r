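# Nested cross-validated multi-class SVM over cells, protein-level
# probability aggregation, and precision-recall analyses.
#
# All cells of a protein stay in one fold (the conservative design for
# replicated cells). The inner level tunes (C, gamma) on 3-train /
# 1-validate splits of the four training folds by protein-level accuracy;
# the outer model is an RBF one-against-one SVM (LIBSVM via e1071) with
# class weights inversely proportional to class cell counts and
# pairwise-coupled per-cell probabilities, summed per protein.

#' Default RBF hyperparameter grid
#'
#' Log-spaced over the conventional LIBSVM search ranges
#' \eqn{C \in [2^{-5}, 2^{15}]}, \eqn{\gamma \in [2^{-15}, 2^{3}]}.
#'
#' @param cost numeric vector of candidate C values.
#' @param gamma numeric vector of candidate gamma values.
#' @return data.frame with columns \code{cost}, \code{gamma}.
#' @export
svmGrid <- function(cost = 2^seq(-5, 15, by = 5),
                    gamma = 2^seq(-15, 3, by = 6)) {
  expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
}

.classOf <- function(annotations) {
  vapply(labelSets(annotations), function(l) paste(sort(l), collapse = ";"), "")
}

#' Stratified protein-level fold assignment
#'
#' Assigns proteins (hence all their cells) to \code{k} folds, keeping the
#' per-fold class composition within one protein of proportional
#' allocation. Deterministic per seed. Classes with fewer proteins than
#' folds are spread over distinct folds with a warning.
#'
#' @param annotations a [LocationAnnotation-class]; the stratification
#'   class of a protein is its (sorted, ";"-joined) label set.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return named integer vector protein_id -> fold in 1..k.
#' @export
makeProteinFolds <- function(annotations, k = 5L, seed = 1L) {
  stopifnot(is(annotations, "LocationAnnotation"), k >= 2L)
  cls <- .classOf(annotations)
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(cls))
    names(fold) <- names(cls)
    for (cl in unique(cls)) {
      ids <- names(cls)[cls == cl]
      if (length(ids) < k)
        warning(sprintf("class '%s' has %d proteins (< %d folds)",
                        cl, length(ids), k), call. = FALSE)
      ids <- sample(ids)
      start <- sample.int(k, 1L)
      fold[ids] <- ((start - 1L + seq_along(ids) - 1L) %% k) + 1L
    }
    fold
  })
}

#' Aggregate per-cell class probabilities to a protein call
#'
#' Sums the per-cell probability vectors, renormalizes to 1 and predicts
#' the argmax class; argmax ties are broken by class order.
#'
#' @param cellProbs numeric matrix, cells x classes (each row summing
#'   to 1), or a single probability vector.
#' @return list with \code{label} (character) and \code{probs} (named
#'   numeric vector summing to 1).
#' @examples
#' aggregateProtein(rbind(c(0.6, 0.4), c(0.1, 0.9)))  # class 2, (0.35, 0.65)
#' @export
aggregateProtein <- function(cellProbs) {
  if (is.null(dim(cellProbs))) cellProbs <- matrix(cellProbs, nrow = 1,
                                                   dimnames = list(NULL, names(cellProbs)))
  stopifnot(nrow(cellProbs) >= 1L)
  s <- colSums(cellProbs)
  p <- s / sum(s)
  list(label = colnames(cellProbs)[which.max(p)], probs = p)
}

.classWeights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

.alignProbs <- function(p, classes) {
  out <- matrix(0, nrow(p), length(classes),
                dimnames = list(rownames(p), classes))
  out[, colnames(p)] <- p
  out
}

# majority vote per protein from per-cell hard predictions; ties by class order
.voteAccuracy <- function(pred, proteins, truth, classes) {
  correct <- 0L
  for (pid in unique(proteins)) {
    tab <- table(factor(pred[proteins == pid], levels = classes))
    if (classes[which.max(tab)] == truth[pid]) correct <- correct + 1L
  }
  correct / length(unique(proteins))
}

# Builds the per-outer-fold plan: selected features, normalization fit and
# tuned hyperparameters. Shared by nestedCrossValidate and the
# distillation procedure (which refits SVMs against a frozen plan).
.buildCvPlan <- function(table, annotations, k, grid, seed, select,
                         fEnter, fRemove, maxFeatures) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  folds <- makeProteinFolds(annotations, k = k, seed = seed)
  classes <- intersect(vocabulary(annotations),
                       unique(unlist(labelSets(annotations))))
  lab <- .classOf(annotations)
  x <- featureMatrix(table)
  cd <- cellKeys(table)
  keep <- cd$protein_id %in% names(folds)
  x <- x[keep, , drop = FALSE]
  prot <- cd$protein_id[keep]
  plan <- list(folds = folds, classes = classes, k = k,
               cellProtein = prot, outer = vector("list", k))
  for (f in seq_len(k)) {
    trainProt <- names(folds)[folds != f]
    trainCells <- prot %in% trainProt
    yTrain <- lab[prot[trainCells]]
    if (length(unique(yTrain)) < 2L)
      stop("degenerate training partition: fewer than 2 classes")
    feats <- colnames(x)
    if (select) {
      sub <- CellFeatureSet(x[trainCells, , drop = FALSE],
                            prot[trainCells],
                            cd$image_id[keep][trainCells],
                            cd$cell_id[keep][trainCells])
      sel <- sdaSelect(sub, subsetAnnotation(annotations, trainProt),
                       fEnter = fEnter, fRemove = fRemove,
                       maxFeatures = maxFeatures)
      if (length(selectedFeatures(sel))) feats <- selectedFeatures(sel)
    }
    zfit <- zscoreFit(x[trainCells, feats, drop = FALSE])
    zTrain <- zscoreApply(zfit, x[trainCells, feats, drop = FALSE])
    # inner tuning: each of the 4 training folds validates once
    innerFolds <- folds[trainProt]
    acc <- matrix(0, nrow(grid), 0)
    for (v in setdiff(seq_len(k), f)) {
      inTrain <- !(prot[trainCells] %in% trainProt[innerFolds == v])
      if (length(unique(yTrain[inTrain])) < 2L) next
      yv <- factor(yTrain[inTrain])
      w <- .classWeights(yv)
      a <- vapply(seq_len(nrow(grid)), function(i) {
        m <- e1071::svm(zTrain[inTrain, , drop = FALSE], yv,
                        kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i], class.weights = w)
        pr <- as.character(predict(m, zTrain[!inTrain, , drop = FALSE]))
        pv <- prot[trainCells][!inTrain]
        .voteAccuracy(pr, pv, lab, classes)
      }, 0)
      acc <- cbind(acc, a)
    }
    best <- if (ncol(acc)) which.max(rowMeans(acc)) else 1L
    plan$outer[[f]] <- list(fold = f, features = feats, zfit = zfit,
                            cost = grid$cost[best], gamma = grid$gamma[best])
  }
  plan
}

# Fit the outer models of a plan against (possibly re-labelled)
# annotations and predict held-out protein probabilities.
.cvWithPlan <- function(table, annotations, plan) {
  lab <- .classOf(annotations)
  classes <- plan$classes
  x <- featureMatrix(table)
  cd <- cellKeys(table)
  keep <- cd$protein_id %in% names(plan$folds)
  x <- x[keep, , drop = FALSE]
  prot <- cd$protein_id[keep]
  res <- list(); probs <- list(); hyper <- list()
  for (f in seq_len(plan$k)) {
    o <- plan$outer[[f]]
    testProt <- names(plan$folds)[plan$folds == f]
    trainCells <- !(prot %in% testProt)
    z <- zscoreApply(o$zfit, x[, o$features, drop = FALSE])
    yTrain <- factor(lab[prot[trainCells]])
    w <- .classWeights(yTrain)
    m <- e1071::svm(z[trainCells, , drop = FALSE], yTrain,
                    kernel = "radial", cost = o$cost, gamma = o$gamma,
                    class.weights = w, probability = TRUE)
    pr <- predict(m, z[!trainCells, , drop = FALSE], probability = TRUE)
    cellP <- .alignProbs(attr(pr, "probabilities"), classes)
    testCellsProt <- prot[!trainCells]
    for (pid in testProt) {
      agg <- aggregateProtein(cellP[testCellsProt == pid, , drop = FALSE])
      res[[pid]] <- data.frame(protein_id = pid, fold = f,
                               true_label = lab[[pid]],
                               predicted_label = agg$label,
                               prob_predicted = unname(agg$probs[agg$label]))
      probs[[pid]] <- agg$probs
    }
    hyper[[f]] <- data.frame(fold = f, cost = o$cost, gamma = o$gamma)
  }
  res <- do.call(rbind, res)
  ord <- order(match(res$protein_id, names(plan$folds)))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  probs <- do.call(rbind, probs)[res$protein_id, , drop = FALSE]
  conf <- table(factor(res$true_label, levels = classes),
                factor(res$predicted_label, levels = classes))
  new("CrossValResult", proteins = res, probs = probs,
      confusion = ConfusionTable(unclass(as.matrix(conf))),
      hyper = do.call(rbind, hyper), classes = classes)
}

#' Nested cross-validated SVM classification
#'
#' Runs two-level nested k-fold cross-validation over proteins: the inner
#' level (3 folds train / 1 fold validate, all four rotations averaged)
#' selects the RBF cost and gamma per outer fold; the outer model is then
#' trained on all four folds with class weights inversely proportional to
#' class cell counts and applied to the held-out fold. Per-cell class
#' probabilities are summed per protein and the argmax class assigned.
#' Stepwise discriminant feature selection and z-score normalization are
#' fitted on each outer training partition only (no selection leakage).
#'
#' @param table a [CellFeatureSet-class].
#' @param annotations a [LocationAnnotation-class]. Multi-label proteins
#'   are treated as their own (sorted, ";"-joined) combination class, so a
#'   purely single-pattern annotation yields the usual single-location
#'   classifier; see [comboClassAnnotation()].
#' @param k number of folds (default 5).
#' @param grid hyperparameter data.frame from [svmGrid()].
#' @param seed integer seed controlling fold assignment.
#' @param select run SDA per training partition (default TRUE).
#' @param fEnter,fRemove,maxFeatures passed to [sdaSelect()].
#' @param plan internal: a frozen plan from a previous run (used by the
#'   distillation procedure to refit only the SVMs).
#' @return A [CrossValResult-class]; the plan is attached as
#'   \code{metadata} attribute \code{"plan"} for reuse.
#' @export
nestedCrossValidate <- function(table, annotations, k = 5L, grid = svmGrid(),
                                seed = 1L, select = TRUE, fEnter = 3.84,
                                fRemove = 2.71, maxFeatures = 100L,
                                plan = NULL) {
  stopifnot(is(table, "CellFeatureSet"), is(annotations, "LocationAnnotation"))
  if (is.null(plan))
    plan <- .buildCvPlan(table, annotations, k = k, grid = grid, seed = seed,
                         select = select, fEnter = fEnter, fRemove = fRemove,
                         maxFeatures = maxFeatures)
  out <- .cvWithPlan(table, annotations, plan)
  attr(out, "plan") <- plan
  out
}

#' Collapse label sets into combination classes
#'
#' Turns each protein's label set into a single class named by the sorted,
#' ";"-joined labels (so mixed-pattern proteins become their own classes),
#' keeping only combinations observed for at least \code{minProteins}
#' proteins. Used for the classifier variant trained on all single+mixed
#' label combinations.
#'
#' @param annotations a [LocationAnnotation-class].
#' @param minProteins minimum proteins per combination class (default 5).
#' @return a [LocationAnnotation-class] whose label sets are singleton
#'   combination classes.
#' @export
comboClassAnnotation <- function(annotations, minProteins = 5L) {
  cls <- .classOf(annotations)
  keep <- names(cls)[cls %in% names(which(table(cls) >= minProteins))]
  LocationAnnotation(as.list(cls[keep]), vocabulary = sort(unique(cls[keep])))
}

#' Cross-validated prediction over single- and mixed-pattern proteins
#'
#' Splits single-pattern proteins into k folds and mixed-pattern proteins
#' into k folds; each outer model (trained on four single-pattern folds
#' with inner hyperparameter tuning) predicts its held-out single-pattern
#' fold plus one mixed-pattern fold, so every protein receives a
#' single-location call and an aggregated probability from a model that
#' never saw it.
#'
#' @inheritParams nestedCrossValidate
#' @return data.frame: protein_id, predicted_label, prob_predicted.
#' @export
crossValidateAllProteins <- function(table, annotations, k = 5L,
                                     grid = svmGrid(), seed = 1L,
                                     select = TRUE, fEnter = 3.84,
                                     fRemove = 2.71, maxFeatures = 100L) {
  single <- isSinglePattern(annotations)
  annSingle <- subsetAnnotation(annotations, names(single)[single])
  cv <- nestedCrossValidate(subsetProteins(table, proteinIds(annSingle)),
                            annSingle, k = k, grid = grid, seed = seed,
                            select = select, fEnter = fEnter,
                            fRemove = fRemove, maxFeatures = maxFeatures)
  plan <- attr(cv, "plan")
  preds <- cvPredictions(cv)[, c("protein_id", "predicted_label",
                                 "prob_predicted")]
  mixedIds <- names(single)[!single]
  if (length(mixedIds)) {
    mixedFold <- makeProteinFolds(subsetAnnotation(annotations, mixedIds),
                                  k = k, seed = seed + 1L)
    x <- featureMatrix(table)
    cd <- cellKeys(table)
    lab <- singleLabels(annSingle)
    trainProtAll <- names(plan$folds)
    mix <- list()
    for (f in seq_len(k)) {
      o <- plan$outer[[f]]
      trainProt <- trainProtAll[plan$folds != f]
      trainCells <- cd$protein_id %in% trainProt
      z <- zscoreApply(o$zfit, x[, o$features, drop = FALSE])
      yTrain <- factor(lab[cd$protein_id[trainCells]])
      m <- e1071::svm(z[trainCells, , drop = FALSE], yTrain,
                      kernel = "radial", cost = o$cost, gamma = o$gamma,
                      class.weights = .classWeights(yTrain),
                      probability = TRUE)
      foldMixed <- names(mixedFold)[mixedFold == f]
      cells <- cd$protein_id %in% foldMixed
      if (!any(cells)) next
      pr <- predict(m, z[cells, , drop = FALSE], probability = TRUE)
      cellP <- .alignProbs(attr(pr, "probabilities"), plan$classes)
      cp <- cd$protein_id[cells]
      for (pid in foldMixed) {
        agg <- aggregateProtein(cellP[cp == pid, , drop = FALSE])
        mix[[pid]] <- data.frame(protein_id = pid,
                                 predicted_label = agg$label,
                                 prob_predicted = unname(agg$probs[agg$label]))
      }
    }
    preds <- rbind(preds, do.call(rbind, mix))
  }
  rownames(preds) <- NULL
  preds
}

#' Precision-recall analysis of protein-level predictions
#'
#' Sweeps a threshold over the per-protein aggregated probabilities and
#' computes precision and recall under one of three definitions:
#' \describe{
#'   \item{any_label}{a protein counts as correct if the predicted
#'     location is among its true labels; precision = correct above
#'     threshold / all above threshold, recall = correct above threshold /
#'     all proteins.}
#'   \item{single_only}{only correctly predicted single-pattern proteins
#'     count as correct; the precision denominator is all proteins above
#'     threshold and the recall denominator all single-pattern proteins.}
#'   \item{single_vs_all_classifier}{for predictions from a combination-
#'     class model ([comboClassAnnotation()]): correct means a
#'     single-pattern protein predicted as its own single class; precision
#'     is over proteins \emph{predicted} single-pattern above threshold,
#'     recall over all single-pattern proteins.}
#' }
#'
#' @param predictions a [CrossValResult-class] or a data.frame with
#'   columns protein_id, predicted_label, prob_predicted.
#' @param truth a [LocationAnnotation-class] with the true label sets.
#' @param mode one of \code{"any_label"}, \code{"single_only"},
#'   \code{"single_vs_all_classifier"}.
#' @return data.frame: threshold, n_above, precision, recall. Thresholds
#'   are 0 plus every observed probability; "above" means probability >=
#'   threshold. Recall is non-increasing in threshold.
#' @export
precisionRecall <- function(predictions, truth,
                            mode = c("any_label", "single_only",
                                     "single_vs_all_classifier")) {
  mode <- match.arg(mode)
  if (is(predictions, "CrossValResult")) predictions <- cvPredictions(predictions)
  stopifnot(all(c("protein_id", "predicted_label", "prob_predicted") %in%
                colnames(predictions)))
  sets <- labelSets(truth)[predictions$protein_id]
  single <- vapply(sets, length, 0L) == 1L
  pred <- predictions$predicted_label
  predSingle <- !grepl(";", pred, fixed = TRUE)
  correct <- switch(mode,
    any_label = mapply(function(p, s) p %in% s, pred, sets),
    single_only = single & mapply(function(p, s) identical(p, s[1]),
                                  pred, sets),
    single_vs_all_classifier = predSingle & single &
      mapply(function(p, s) identical(p, s[1]), pred, sets))
  prob <- predictions$prob_predicted
  recallDenom <- switch(mode, any_label = length(pred), sum(single))
  thresholds <- sort(unique(c(0, prob)))
  rows <- lapply(thresholds, function(t) {
    above <- prob >= t
    denom <- switch(mode,
                    single_vs_all_classifier = sum(above & predSingle),
                    sum(above))
    nCorrect <- sum(correct & above)
    data.frame(threshold = t, n_above = sum(above),
               precision = if (denom > 0) nCorrect / denom else NA_real_,
               recall = nCorrect / recallDenom)
  })
  do.call(rbind, rows)
}
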