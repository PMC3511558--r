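# Seeded synthetic cohorts with the statistical structure the framework
# assumes: strongly imbalanced classes, per-protein cell replicates,
# injected mislabels, and mixed-pattern proteins interpolating between
# class prototypes.

#' Configuration for a synthetic cohort
#'
#' The defaults emulate the structure of the first-round HPA A-431
#' single-pattern study set: 11 location classes with protein counts
#' ranging from 7 to 326, an average of about 9 segmented cells per image
#' with up to two images per protein (hence 9-18 cells per protein), and a
#' feature vector in which only a minority of dimensions carry location
#' signal.
#'
#' @param nClasses number of location classes (>= 2).
#' @param proteinsPerClass integer vector of per-class protein counts
#'   (length \code{nClasses}); defaults to the imbalanced counts of the
#'   emulated collection.
#' @param cellsPerProtein length-2 integer range; each protein receives a
#'   uniform draw from it (default 9-18).
#' @param nFeatures total number of features (default 120).
#' @param nInformative number of features carrying class signal
#'   (default 30; must satisfy \code{nClasses <= nInformative <= nFeatures}).
#' @param classSeparation pairwise prototype distance in units of the
#'   within-class cell SD \eqn{\sqrt{proteinEffectSd^2 + cellNoiseSd^2}}
#'   (default 3).
#' @param proteinEffectSd SD of the per-protein offset shared by all of a
#'   protein's cells (default 0.5).
#' @param cellNoiseSd SD of independent per-cell noise (default 1).
#' @param mislabelRate fraction of single-pattern proteins whose observed
#'   label is replaced by a uniformly random different class (default 0.1).
#' @param mixedFraction fraction of proteins rendered as mixed-pattern
#'   convex combinations of two class prototypes (default 0).
#' @param mixingAlpha length-2 range in (0,1) for the mixing coefficient.
#' @param classNames optional class names; default "class01", ...
#' @param seed integer RNG seed (default 1).
#' @return A list of class \code{"SyntheticConfig"}.
#' @seealso [generateCohort()]
#' @export
syntheticConfig <- function(nClasses = 11L,
                            proteinsPerClass = NULL,
                            cellsPerProtein = c(9L, 18L),
                            nFeatures = 120L,
                            nInformative = 30L,
                            classSeparation = 3,
                            proteinEffectSd = 0.5,
                            cellNoiseSd = 1,
                            mislabelRate = 0.1,
                            mixedFraction = 0,
                            mixingAlpha = c(0.3, 0.7),
                            classNames = NULL,
                            seed = 1L) {
  if (is.null(proteinsPerClass)) {
    # protein counts of the emulated 11-class collection (878 proteins)
    default <- c(12L, 326L, 37L, 34L, 41L, 26L, 104L, 37L, 87L, 167L, 7L)
    proteinsPerClass <- if (nClasses == 11L) default else
      pmax(2L, round(exp(seq(log(5), log(326), length.out = nClasses))))
  }
  if (length(proteinsPerClass) != nClasses)
    stop("config error: proteinsPerClass must have length nClasses")
  if (nClasses < 2L) stop("config error: nClasses must be >= 2")
  if (nInformative > nFeatures)
    stop("config error: nInformative must be <= nFeatures")
  if (nInformative < nClasses)
    stop("config error: nInformative must be >= nClasses ",
         "(prototypes are orthogonal directions in the informative subspace)")
  stopifnot(length(cellsPerProtein) == 2L,
            cellsPerProtein[1] >= 1L,
            cellsPerProtein[2] >= cellsPerProtein[1],
            classSeparation > 0, proteinEffectSd > 0, cellNoiseSd > 0,
            mislabelRate >= 0, mislabelRate < 1,
            mixedFraction >= 0, mixedFraction < 1,
            mislabelRate + mixedFraction < 1,
            length(mixingAlpha) == 2L, all(mixingAlpha > 0),
            all(mixingAlpha < 1))
  if (is.null(classNames))
    classNames <- sprintf("class%02d", seq_len(nClasses))
  structure(list(nClasses = as.integer(nClasses),
                 proteinsPerClass = as.integer(proteinsPerClass),
                 cellsPerProtein = as.integer(cellsPerProtein),
                 nFeatures = as.integer(nFeatures),
                 nInformative = as.integer(nInformative),
                 classSeparation = classSeparation,
                 proteinEffectSd = proteinEffectSd,
                 cellNoiseSd = cellNoiseSd,
                 mislabelRate = mislabelRate,
                 mixedFraction = mixedFraction,
                 mixingAlpha = mixingAlpha,
                 classNames = as.character(classNames),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic cohort
#'
#' Class prototypes are placed at mutually equidistant points in the
#' informative feature subspace (random orthonormal directions, pairwise
#' distance \code{classSeparation} in within-class-SD units). Each
#' protein's cells are prototype + a protein-level Gaussian offset
#' (\code{proteinEffectSd}) + independent per-cell noise
#' (\code{cellNoiseSd}); uninformative features are pure noise. A fraction
#' \code{mixedFraction} of proteins get features
#' \eqn{\alpha p_A + (1-\alpha) p_B} and truth label \{A, B\}; a fraction
#' \code{mislabelRate} of the remaining single-pattern proteins have their
#' observed label replaced by a uniformly random different class. Fully
#' reproducible from \code{config$seed}.
#'
#' @param config a [syntheticConfig()] list.
#' @return A list of class \code{"SyntheticCohort"} with elements
#'   \code{table} ([CellFeatureSet-class]), \code{truth} and
#'   \code{observed} ([LocationAnnotation-class]), \code{mislabeledIds}
#'   (character) and \code{config}.
#' @examples
#' coh <- generateCohort(syntheticConfig(nClasses = 3,
#'   proteinsPerClass = c(5, 5, 5), nFeatures = 20, nInformative = 10,
#'   cellsPerProtein = c(3, 4), seed = 7))
#' coh$table
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  withr::with_seed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  d <- cfg$nFeatures
  di <- cfg$nInformative
  g <- cfg$nClasses
  sigmaW <- sqrt(cfg$proteinEffectSd^2 + cfg$cellNoiseSd^2)
  # random orthonormal directions; scaling a/sqrt(2) per direction makes all
  # pairwise prototype distances equal to classSeparation * sigmaW
  q <- qr.Q(qr(matrix(rnorm(di * g), di, g)))
  proto <- t(q) * (cfg$classSeparation * sigmaW / sqrt(2))  # g x di

  ids <- sprintf("prot%04d", seq_len(sum(cfg$proteinsPerClass)))
  classOf <- rep(cfg$classNames, cfg$proteinsPerClass)
  nProt <- length(ids)

  nMixed <- round(cfg$mixedFraction * nProt)
  mixedIdx <- if (nMixed > 0) sort(sample.int(nProt, nMixed)) else integer()
  singleIdx <- setdiff(seq_len(nProt), mixedIdx)
  nMis <- round(cfg$mislabelRate * length(singleIdx))
  misIdx <- if (nMis > 0) sort(sample(singleIdx, nMis)) else integer()

  truth <- as.list(classOf)
  observed <- as.list(classOf)
  names(truth) <- names(observed) <- ids

  protoOf <- proto[match(classOf, cfg$classNames), , drop = FALSE]
  for (i in mixedIdx) {
    other <- sample(setdiff(cfg$classNames, classOf[i]), 1L)
    alpha <- runif(1, cfg$mixingAlpha[1], cfg$mixingAlpha[2])
    protoOf[i, ] <- alpha * proto[match(classOf[i], cfg$classNames), ] +
      (1 - alpha) * proto[match(other, cfg$classNames), ]
    truth[[i]] <- sort(c(classOf[i], other))
    observed[[i]] <- truth[[i]]
  }
  for (i in misIdx)
    observed[[i]] <- sample(setdiff(cfg$classNames, classOf[i]), 1L)

  nCells <- sample(seq(cfg$cellsPerProtein[1], cfg$cellsPerProtein[2]),
                   nProt, replace = TRUE)
  total <- sum(nCells)
  feat <- matrix(rnorm(total * d, sd = cfg$cellNoiseSd), total, d)
  colnames(feat) <- sprintf("f%03d", seq_len(d))
  protRow <- rep(seq_len(nProt), nCells)
  # protein-level offsets live in the informative subspace only, so the
  # uninformative features are pure i.i.d. noise with no class- or
  # protein-level structure
  offsets <- matrix(rnorm(nProt * di, sd = cfg$proteinEffectSd), nProt, di)
  feat[, seq_len(di)] <- feat[, seq_len(di)] + protoOf[protRow, ] +
    offsets[protRow, ]

  # split each protein's cells over up to two images of ~9 cells
  imageNo <- unlist(lapply(nCells, function(n)
    rep(seq_len(ceiling(n / 9)), each = 9L)[seq_len(n)]))
  cellNo <- unlist(lapply(nCells, seq_len))
  tab <- CellFeatureSet(feat,
                        proteinId = ids[protRow],
                        imageId = sprintf("img%d", imageNo),
                        cellId = sprintf("cell%02d", cellNo))
  structure(list(table = tab,
                 truth = LocationAnnotation(truth, cfg$classNames),
                 observed = LocationAnnotation(observed, cfg$classNames),
                 mislabeledIds = ids[misIdx],
                 config = cfg),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", length(x$truth), "proteins,",
      ncol(x$table), "cells,", x$config$nClasses, "classes;",
      length(x$mislabeledIds), "injected mislabels\n")
  invisible(x)
}
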