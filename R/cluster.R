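# Unsupervised mis-annotation candidates: one representative cell per
# protein, agglomerative clustering on normalized Euclidean distances, an
# AIC-selected cut, the dominant annotation per cluster, two
# mis-annotation scores, both rounds' selection rules, and Bar-Joseph
# optimal leaf ordering for reporting.

.repVectors <- function(table, features = NULL, normalize = TRUE) {
  x <- featureMatrix(table)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (normalize) x <- zscoreFitApply(x)
  prot <- cellKeys(table)$protein_id
  ids <- unique(prot)
  out <- matrix(NA_real_, length(ids), ncol(x),
                dimnames = list(ids, colnames(x)))
  for (pid in ids) {
    xi <- x[prot == pid, , drop = FALSE]
    med <- apply(xi, 2, median)
    d2 <- rowSums(sweep(xi, 2, med)^2)
    out[pid, ] <- xi[which.min(d2), ]   # tie: first cell in table order
  }
  out
}

#' Representative cell of one protein
#'
#' Returns the actual cell vector of the protein closest (Euclidean) to
#' the component-wise median of the protein's normalized cells; distance
#' ties are broken by cell order.
#'
#' @param table a [CellFeatureSet-class].
#' @param proteinId one protein ID present in \code{table}.
#' @param features optional feature subset.
#' @param normalize z-score features over all cells of \code{table} first
#'   (default TRUE).
#' @return named numeric feature vector.
#' @export
representativeCell <- function(table, proteinId, features = NULL,
                               normalize = TRUE) {
  stopifnot(proteinId %in% proteinIds(table))
  .repVectors(table, features, normalize)[proteinId, ]
}

#' Representative cells for every protein
#'
#' @inheritParams representativeCell
#' @return numeric matrix, proteins x features, rownames = protein IDs.
#' @export
representativeCells <- function(table, features = NULL, normalize = TRUE) {
  .repVectors(table, features, normalize)
}

#' Agglomerative dendrogram on normalized Euclidean distances
#'
#' @param vectors numeric matrix, proteins x features (already
#'   normalized, e.g. from [representativeCells()]).
#' @param linkage linkage method for \code{\link[stats]{hclust}}
#'   (default "average").
#' @return an \code{hclust} object.
#' @export
buildDendrogram <- function(vectors, linkage = "average") {
  stopifnot(nrow(vectors) >= 2L)
  hclust(dist(vectors), method = linkage)
}

#' AIC of a flat clustering under a spherical Gaussian model
#'
#' Each cluster is modelled as a spherical Gaussian around its mean with a
#' single pooled variance; the parameter count is \eqn{p = k d + 1}
#' (k cluster means in d dimensions plus the variance) and
#' \eqn{AIC = -2 \log L + 2 p}.
#'
#' @param vectors numeric matrix, observations x features.
#' @param assignment integer cluster index per observation.
#' @return numeric AIC value.
#' @export
clusterAIC <- function(vectors, assignment) {
  n <- nrow(vectors); d <- ncol(vectors)
  rss <- 0
  for (c in unique(assignment)) {
    xi <- vectors[assignment == c, , drop = FALSE]
    rss <- rss + sum(sweep(xi, 2, colMeans(xi))^2)
  }
  sigma2 <- max(rss / (n * d), 1e-12)
  logL <- -n * d / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(unique(assignment))
  -2 * logL + 2 * (k * d + 1)
}

#' Choose the number of clusters by AIC
#'
#' Cuts the tree at each k in \code{kRange}, evaluates [clusterAIC()] and
#' returns the argmin (smallest k on ties).
#'
#' @param tree an \code{hclust} object.
#' @param vectors the matrix the tree was built from.
#' @param kRange integer candidate cluster counts
#'   (default \code{1:min(n, 30)}).
#' @return integer k*, with the AIC curve attached as attribute
#'   \code{"aic"} (data.frame k, aic).
#' @export
chooseKAIC <- function(tree, vectors, kRange = NULL) {
  n <- nrow(vectors)
  if (is.null(kRange)) kRange <- seq_len(min(n, 30L))
  stopifnot(all(kRange >= 1L), all(kRange <= n))
  aic <- vapply(kRange, function(k)
    clusterAIC(vectors, cutree(tree, k = k)), 0)
  k <- kRange[which.min(aic)]
  attr(k, "aic") <- data.frame(k = kRange, aic = aic)
  k
}

.dominantLabel <- function(labels, classOrder) {
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  top[order(match(top, classOrder))][1L]   # tie: first in class order
}

#' Build a representative-cell cluster model
#'
#' Convenience pipeline: representative cells of the single-pattern
#' proteins, agglomerative tree, AIC-selected cut, dominant annotation per
#' cluster and (optionally) optimal leaf ordering.
#'
#' @param table a [CellFeatureSet-class].
#' @param annotations a [LocationAnnotation-class]; single-pattern
#'   proteins are clustered.
#' @param features optional feature subset (e.g. from [sdaSelect()]).
#' @param linkage linkage method (default "average").
#' @param kRange candidate cluster counts for [chooseKAIC()].
#' @param orderLeaves compute [leafOrder()] (O(n^3); default TRUE).
#' @return a [ClusterModel-class].
#' @export
buildClusterModel <- function(table, annotations, features = NULL,
                              linkage = "average", kRange = NULL,
                              orderLeaves = TRUE) {
  single <- isSinglePattern(annotations)
  ids <- intersect(proteinIds(table), names(single)[single])
  vec <- representativeCells(subsetProteins(table, ids), features)
  tree <- buildDendrogram(vec, linkage)
  k <- as.integer(chooseKAIC(tree, vec, kRange))
  assign <- cutree(tree, k = k)
  lab <- singleLabels(annotations)[rownames(vec)]
  classOrder <- vocabulary(annotations)
  dominant <- vapply(seq_len(k), function(c)
    .dominantLabel(lab[assign == c], classOrder), "")
  lo <- if (orderLeaves) leafOrder(tree, dist(vec)) else
    as.integer(tree$order)
  new("ClusterModel", vectors = vec, tree = tree, k = k,
      assignment = stats::setNames(as.integer(assign), rownames(vec)),
      dominant = dominant, leafOrder = lo)
}

#' Dominant-annotation accuracy of a clustering
#'
#' Fraction of proteins whose own annotation equals the dominant
#' (plurality) annotation of their cluster, as a percentage.
#'
#' @param model a [ClusterModel-class].
#' @param annotations a [LocationAnnotation-class].
#' @param digits decimal places (default 0, matching published rounding).
#' @return numeric percentage.
#' @export
clusterAccuracy <- function(model, annotations, digits = 0) {
  stopifnot(is(model, "ClusterModel"))
  lab <- singleLabels(annotations)[proteinIds(model)]
  acc <- 100 * mean(lab == model@dominant[model@assignment])
  if (is.na(digits)) acc else round(acc, digits)
}

#' Compute the two cluster-based mis-annotation scores
#'
#' Score 1: (number of proteins of the protein's own class in its
#' cluster) / (number of proteins of the dominant class); 1 iff the
#' protein's class is the (tie-broken) dominant one. Score 2: Euclidean
#' distance from the protein's representative vector to the
#' component-wise median vector of the dominant-annotation proteins in
#' its cluster (0 iff the protein sits exactly at that median). In a
#' singleton cluster the protein is its own dominant class, so score 2 is
#' computed against the protein's own vector (degenerate, reported via a
#' message).
#'
#' @param model a [ClusterModel-class].
#' @param annotations a [LocationAnnotation-class].
#' @return a [ProteinScores-class].
#' @export
scoreProteins <- function(model, annotations) {
  stopifnot(is(model, "ClusterModel"))
  ids <- proteinIds(model)
  lab <- singleLabels(annotations)[ids]
  assign <- model@assignment
  vec <- model@vectors
  singletons <- 0L
  rows <- lapply(seq_along(ids), function(i) {
    c0 <- assign[i]
    members <- ids[assign == c0]
    dom <- model@dominant[c0]
    s1 <- sum(lab[members] == lab[ids[i]]) / sum(lab[members] == dom)
    domMembers <- members[lab[members] == dom]
    if (identical(domMembers, ids[i])) singletons <<- singletons + 1L
    med <- apply(vec[domMembers, , drop = FALSE], 2, median)
    s2 <- sqrt(sum((vec[ids[i], ] - med)^2))
    data.frame(protein_id = ids[i], cluster = unname(c0),
               label = unname(lab[ids[i]]), score1 = s1, score2 = s2)
  })
  if (singletons > 0L)
    message("scoreProteins: ", singletons,
            " protein(s) alone in their dominant class; score2 degenerate")
  s <- do.call(rbind, rows)
  rownames(s) <- NULL
  new("ProteinScores", scores = s)
}

#' Round-1 candidate selection (tight criteria)
#'
#' Intersects the proteins with score 1 below one (annotation not
#' dominant in their cluster) with the \code{nLowS2} lowest values of
#' score 2 (close to the dominant-class median, i.e. well clustered).
#' With \code{onePerCluster}, only the lowest-score-1 protein per cluster
#' is kept (ties by lower score 2, then protein ID). The list is ranked
#' by score 1 ascending.
#'
#' @param scores a [ProteinScores-class].
#' @param nLowS2 size of the low-score-2 subset (default 300, the
#'   original histogram-peak cutoff; scale with cohort size).
#' @param onePerCluster restrict to one candidate per cluster
#'   (default TRUE).
#' @return a [ReannotationCandidates-class] with source \code{"cluster"}
#'   and score = score 1.
#' @export
selectCandidatesRound1 <- function(scores, nLowS2 = 300L,
                                   onePerCluster = TRUE) {
  s <- scoreTable(scores)
  lowS2 <- s$protein_id[order(s$score2, s$protein_id)][
    seq_len(min(nLowS2, nrow(s)))]
  cand <- s[s$score1 < 1 & s$protein_id %in% lowS2, , drop = FALSE]
  if (onePerCluster && nrow(cand)) {
    cand <- cand[order(cand$score1, cand$score2, cand$protein_id), ,
                 drop = FALSE]
    cand <- cand[!duplicated(cand$cluster), , drop = FALSE]
  }
  cand <- cand[order(cand$score1, cand$score2, cand$protein_id), ,
               drop = FALSE]
  ReannotationCandidates(cand$protein_id, sources = "cluster",
                         score = cand$score1)
}

#' Round-2 candidate selection (rank-sum ordering)
#'
#' Ranks proteins by score 1 ascending and by score 2 ascending, orders
#' by the sum of the two ranks ascending (ties by the score-1 rank, then
#' protein ID) and returns the top \code{budget}.
#'
#' @param scores a [ProteinScores-class].
#' @param budget number of candidates to return.
#' @return a [ReannotationCandidates-class] with source \code{"cluster"}
#'   and score = rank sum.
#' @export
selectCandidatesRound2 <- function(scores, budget) {
  s <- scoreTable(scores)
  if (budget > nrow(s)) {
    warning("budget exceeds number of proteins; returning all")
    budget <- nrow(s)
  }
  r1 <- match(s$protein_id, s$protein_id[order(s$score1, s$protein_id)])
  r2 <- match(s$protein_id, s$protein_id[order(s$score2, s$protein_id)])
  ord <- order(r1 + r2, r1, s$protein_id)[seq_len(budget)]
  ReannotationCandidates(s$protein_id[ord], sources = "cluster",
                         score = (r1 + r2)[ord])
}

#' Optimal leaf ordering of a dendrogram
#'
#' Bar-Joseph dynamic program: among the \eqn{2^{n-1}} leaf orders
#' consistent with the tree, finds one minimizing the sum of distances
#' between adjacent leaves. Used for reporting cluster layouts.
#'
#' @param tree an \code{hclust} object.
#' @param distances a \code{dist} object (or matrix) over the leaves.
#' @return integer permutation of leaf indices.
#' @export
leafOrder <- function(tree, distances) {
  d <- as.matrix(distances)
  n <- length(tree$order)
  stopifnot(nrow(d) == n)
  # solve(node) returns leaves (in left-to-right block order), cost matrix
  # M[u, w] over leaf pairs (Inf where invalid) and backpointers.
  solve <- function(node) {
    if (node < 0) {
      leaf <- -node
      M <- matrix(0, 1, 1, dimnames = list(leaf, leaf))
      return(list(leaves = leaf, M = M, back = NULL,
                  left = NULL, right = NULL))
    }
    L <- solve(tree$merge[node, 1])
    R <- solve(tree$merge[node, 2])
    lv <- L$leaves; rv <- R$leaves
    nm <- c(lv, rv)
    M <- matrix(Inf, length(nm), length(nm), dimnames = list(nm, nm))
    back <- array(NA_integer_, dim = c(length(nm), length(nm), 2),
                  dimnames = list(nm, nm, NULL))
    dLR <- d[lv, rv, drop = FALSE]
    for (u in as.character(lv)) for (w in as.character(rv)) {
      # cost(u..m | k..w) over interior endpoints m in L, k in R
      cm <- outer(L$M[u, as.character(lv)], R$M[as.character(rv), w], "+") +
        dLR
      best <- arrayInd(which.min(cm), dim(cm))
      M[u, w] <- M[w, u] <- cm[best]
      back[u, w, ] <- c(lv[best[1]], rv[best[2]])
    }
    list(leaves = nm, M = M, back = back, left = L, right = R)
  }
  root <- solve(nrow(tree$merge))
  lv <- as.character(root$left$leaves)
  rv <- as.character(root$right$leaves)
  sub <- root$M[lv, rv, drop = FALSE]
  best <- arrayInd(which.min(sub), dim(sub))
  build <- function(node, u, w) {
    if (is.null(node$back)) return(node$leaves)
    inLeft <- u %in% node$left$leaves
    if (!inLeft) { tmp <- u; u <- w; w <- tmp }
    mk <- node$back[as.character(u), as.character(w), ]
    ordL <- build(node$left, u, mk[1])
    ordR <- build(node$right, mk[2], w)
    out <- c(ordL, ordR)
    if (!inLeft) rev(out) else out
  }
  as.integer(build(root, root$left$leaves[best[1]],
                   root$right$leaves[best[2]]))
}
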