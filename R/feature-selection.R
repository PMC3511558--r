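# Stepwise Discriminant Analysis (SDA) on cell-level features, plus
# train-fold-anchored z-score normalization.
#
# SDA is classic forward stepping with backward elimination on Wilks'
# lambda: Lambda(S) = det(W_S) / det(T_S) with W the pooled within-class
# scatter and T the total scatter over the selected feature subset S.
# Entry/removal use Rao's partial-F approximation:
#   F_enter(j)  = (n - g - p)     / (g - 1) * (Lambda_S / Lambda_{S+j} - 1)
#   F_remove(k) = (n - g - p + 1) / (g - 1) * (Lambda_{S-k} / Lambda_S - 1)
# with n cells, g classes, p = |S|. Determinant ratios are computed via
# Schur complements so each step costs O(p^2) per candidate.

.cellClassLabels <- function(table, annotations) {
  lab <- singleLabels(annotations)
  cd <- cellKeys(table)
  keep <- cd$protein_id %in% names(lab)
  list(keep = keep, y = factor(lab[cd$protein_id[keep]]))
}

.scatterMatrices <- function(x, y) {
  n <- nrow(x)
  tot <- crossprod(sweep(x, 2, colMeans(x)))
  within <- matrix(0, ncol(x), ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    if (nrow(xi) > 1)
      within <- within + crossprod(sweep(xi, 2, colMeans(xi)))
  }
  dimnames(tot) <- dimnames(within) <- list(colnames(x), colnames(x))
  list(W = within, T = tot, n = n, g = nlevels(y))
}

.safeChol <- function(m, label, ridgeState) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    eps <- 1e-8 * mean(diag(m))
    if (eps <= 0) eps <- 1e-8
    ridgeState$used <- TRUE
    ch <- chol(m + diag(eps, nrow(m)))
  }
  ch
}

#' Stepwise discriminant feature selection
#'
#' Forward-stepwise selection with backward elimination on cell-level
#' features. At each step the unselected feature with the largest partial
#' F (from the ratio of Wilks' lambda with/without the feature) is entered
#' if its F exceeds \code{fEnter}; after each entry, selected features
#' whose F-to-remove falls below \code{fRemove} are removed. Stops when no
#' entry qualifies or \code{maxFeatures} is reached. Deterministic; ties
#' are broken by feature column order. A singular within-class scatter is
#' handled by a small ridge on the scatter diagonal (reported via a
#' message), never by failure.
#'
#' @param table a [CellFeatureSet-class] (cell-level features).
#' @param annotations a [LocationAnnotation-class]; only single-pattern
#'   proteins are used, each cell inheriting its protein's label.
#' @param fEnter F-to-enter threshold (default 3.84, the 5\% chi-square_1
#'   critical value).
#' @param fRemove F-to-remove threshold (default 2.71, the 10\% critical
#'   value); must be below \code{fEnter}.
#' @param maxFeatures cap on the number of selected features (default 100).
#' @return An [SdaSelection-class].
#' @examples
#' coh <- generateCohort(syntheticConfig(nClasses = 3,
#'   proteinsPerClass = c(8, 8, 8), nFeatures = 15, nInformative = 5,
#'   cellsPerProtein = c(4, 6), mislabelRate = 0, seed = 2))
#' sel <- sdaSelect(coh$table, coh$observed)
#' selectedFeatures(sel)
#' @export
sdaSelect <- function(table, annotations, fEnter = 3.84, fRemove = 2.71,
                      maxFeatures = 100L) {
  stopifnot(is(table, "CellFeatureSet"), is(annotations, "LocationAnnotation"),
            fEnter > fRemove)
  cl <- .cellClassLabels(table, annotations)
  x <- featureMatrix(table)[cl$keep, , drop = FALSE]
  y <- cl$y
  if (nlevels(y) < 2L) stop("need >= 2 classes with single-pattern proteins")
  if (min(table(y)) < 2L) stop("each class needs >= 2 cells")
  sc <- .scatterMatrices(x, y)
  W <- sc$W; TT <- sc$T; n <- sc$n; g <- sc$g
  feats <- colnames(x)
  ridgeState <- new.env(); ridgeState$used <- FALSE

  selected <- integer()
  lambda <- 1
  log <- list()
  step <- 0L
  repeat {
    cand <- setdiff(seq_along(feats), selected)
    if (!length(cand) || length(selected) >= maxFeatures) break
    p <- length(selected)
    const <- (n - g - p) / (g - 1)
    if (const <= 0) break
    if (p == 0L) {
      schurW <- diag(W)[cand]
      schurT <- diag(TT)[cand]
    } else {
      chW <- .safeChol(W[selected, selected, drop = FALSE], "W", ridgeState)
      chT <- .safeChol(TT[selected, selected, drop = FALSE], "T", ridgeState)
      bW <- backsolve(chW, W[selected, cand, drop = FALSE], transpose = TRUE)
      bT <- backsolve(chT, TT[selected, cand, drop = FALSE], transpose = TRUE)
      schurW <- diag(W)[cand] - colSums(bW^2)
      schurT <- diag(TT)[cand] - colSums(bT^2)
    }
    ratio <- schurW / schurT           # Lambda_{S+j} / Lambda_S
    ratio[schurT <= 0 | schurW < 0] <- 1
    ratio <- pmin(pmax(ratio, 1e-12), 1)
    fEnterAll <- const * (1 / ratio - 1)
    best <- which.max(fEnterAll)       # first max: tie-break by column order
    if (fEnterAll[best] <= fEnter) break
    selected <- c(selected, cand[best])
    lambda <- lambda * ratio[best]
    step <- step + 1L
    log[[length(log) + 1L]] <- data.frame(
      step = step, action = "enter", feature = feats[cand[best]],
      wilks = lambda, partial_F = fEnterAll[best])
    # backward elimination after each entry
    repeat {
      p <- length(selected)
      if (p < 2L) break
      chW <- .safeChol(W[selected, selected, drop = FALSE], "W", ridgeState)
      chT <- .safeChol(TT[selected, selected, drop = FALSE], "T", ridgeState)
      invW <- diag(chol2inv(chW))
      invT <- diag(chol2inv(chT))
      constR <- (n - g - p + 1) / (g - 1)
      # Lambda_{S-k} / Lambda_S = (W^-1)_kk / (T^-1)_kk
      remRatio <- invW / invT
      fRem <- constR * (remRatio - 1)
      fRem[length(fRem)] <- Inf        # never remove the feature just entered
      worst <- which.min(fRem)
      if (fRem[worst] >= fRemove) break
      lambda <- lambda * remRatio[worst]
      step <- step + 1L
      log[[length(log) + 1L]] <- data.frame(
        step = step, action = "remove", feature = feats[selected[worst]],
        wilks = lambda, partial_F = fRem[worst])
      selected <- selected[-worst]
    }
  }
  if (ridgeState$used)
    message("sdaSelect: singular scatter encountered; ",
            "ridge added to scatter diagonal")
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), action = character(), feature = character(),
               wilks = numeric(), partial_F = numeric())
  new("SdaSelection", selected = feats[selected], log = log)
}

#' Wilks' lambda for a feature subset (direct computation)
#'
#' Direct determinant-ratio evaluation of Wilks' lambda,
#' \eqn{\det(W_S)/\det(T_S)}, for a given feature subset. Mainly useful for
#' checking the stepwise path.
#'
#' @param table a [CellFeatureSet-class].
#' @param annotations a [LocationAnnotation-class] (single-pattern labels).
#' @param features character vector of feature names.
#' @return numeric Wilks' lambda in (0, 1].
#' @export
wilksLambda <- function(table, annotations, features) {
  cl <- .cellClassLabels(table, annotations)
  x <- featureMatrix(table)[cl$keep, features, drop = FALSE]
  sc <- .scatterMatrices(x, cl$y)
  det(sc$W) / det(sc$T)
}

#' Fit a z-score normalization on training cells
#'
#' @param train a [CellFeatureSet-class] or numeric matrix (observations x
#'   features).
#' @return list with per-feature \code{mean} and \code{sd}.
#' @export
zscoreFit <- function(train) {
  x <- if (is(train, "CellFeatureSet")) featureMatrix(train) else as.matrix(train)
  stopifnot(nrow(x) >= 1L)
  list(mean = colMeans(x), sd = apply(x, 2, sd))
}

#' Apply a fitted z-score normalization
#'
#' Features with zero training SD map to 0 (never NaN).
#'
#' @param fit a [zscoreFit()] result.
#' @param x a [CellFeatureSet-class] or numeric matrix to normalize.
#' @return object of the same kind as \code{x}, normalized.
#' @export
zscoreApply <- function(fit, x) {
  isCfs <- is(x, "CellFeatureSet")
  m <- if (isCfs) featureMatrix(x) else as.matrix(x)
  s <- fit$sd
  s[!is.finite(s) | s == 0] <- Inf   # constant features -> 0 after scaling
  z <- sweep(sweep(m, 2, fit$mean), 2, s, "/")
  if (!isCfs) return(z)
  cd <- cellKeys(x)
  CellFeatureSet(z, cd$protein_id, cd$image_id, cd$cell_id)
}

#' Fit on train, apply to another table
#'
#' Per-feature mean/SD are estimated on \code{train} only and applied to
#' \code{applyTo} (which may be \code{train} itself).
#'
#' @param train training [CellFeatureSet-class] or matrix.
#' @param applyTo object to normalize (defaults to \code{train}).
#' @return normalized object of the same kind as \code{applyTo}.
#' @export
zscoreFitApply <- function(train, applyTo = train) {
  zscoreApply(zscoreFit(train), applyTo)
}
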