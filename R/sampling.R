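# Random-sampling baseline, reannotation outcome tallies, reannotation
# rate and enrichment folds.

#' Random per-class candidate sample (baseline)
#'
#' For each class, draws \code{r} proteins uniformly at random with
#' replacement (so small classes are represented without being exhausted)
#' and returns the deduplicated union. Deterministic per seed.
#'
#' @param annotations a [LocationAnnotation-class]; single-pattern
#'   proteins are sampled within their class.
#' @param r draws per class (default 7).
#' @param seed integer seed.
#' @return a [ReannotationCandidates-class] with source \code{"random"}.
#' @export
randomSamplePerClass <- function(annotations, r = 7L, seed = 1L) {
  stopifnot(is(annotations, "LocationAnnotation"), r >= 1L)
  lab <- singleLabels(annotations)
  withr::with_seed(as.integer(seed), {
    picked <- unlist(lapply(unique(lab), function(cl) {
      ids <- names(lab)[lab == cl]
      sample(ids, r, replace = TRUE)
    }))
    ReannotationCandidates(unique(picked), sources = "random")
  })
}

#' Tally reannotation outcomes
#'
#' Classifies each candidate into one of six mutually exclusive outcome
#' categories by comparing its previous human label set, its automated
#' (classifier or cluster) assignment, and its new label set after expert
#' re-examination:
#' \itemize{
#'   \item \code{negative}: re-annotated as the reserved non-specific
#'     label (antibody likely bad);
#'   \item \code{both_right}: new = previous = automated;
#'   \item \code{am_right}: new = automated, differing from previous;
#'   \item \code{partially_right}: re-examination added the automated
#'     label to the previous set;
#'   \item \code{am_wrong}: new = previous, differing from automated;
#'   \item \code{both_wrong}: a different assignment altogether.
#' }
#'
#' @param previous a [LocationAnnotation-class] (labels before
#'   re-examination).
#' @param automated named character vector protein -> automated label.
#' @param reannotated a [LocationAnnotation-class] (labels after
#'   re-examination); must cover every candidate.
#' @param candidates a [ReannotationCandidates-class] (or character
#'   vector of protein IDs).
#' @param nonspecificLabel reserved label marking non-specific location
#'   (default \code{"non-specific location"}).
#' @return a [ReannotationTally-class].
#' @export
tallyOutcomes <- function(previous, automated, reannotated, candidates,
                          nonspecificLabel = "non-specific location") {
  ids <- if (is.character(candidates)) candidates else proteinIds(candidates)
  missing <- setdiff(ids, proteinIds(reannotated))
  if (length(missing))
    stop("candidate not covered by reannotation: ", missing[1L])
  counts <- setNames(integer(length(.tallyCategories)), .tallyCategories)
  setsPrev <- labelSets(previous)
  setsNew <- labelSets(reannotated)
  for (id in ids) {
    prev <- sort(setsPrev[[id]])
    new <- sort(setsNew[[id]])
    am <- sort(automated[[id]])
    cat <- if (identical(new, nonspecificLabel)) "negative"
      else if (identical(new, prev) && identical(new, am)) "both_right"
      else if (identical(new, am)) "am_right"
      else if (identical(new, sort(union(prev, am))) && !all(am %in% prev))
        "partially_right"
      else if (identical(new, prev)) "am_wrong"
      else "both_wrong"
    counts[cat] <- counts[cat] + 1L
  }
  new("ReannotationTally", counts = counts, total = length(ids))
}

#' Reannotation rate of a tally
#'
#' Percentage of candidates whose annotations changed upon
#' re-examination: (am_right + partially_right + both_wrong + negative) /
#' total. Rounded to the nearest integer percent for reporting by
#' default; pass \code{digits = NA} for the exact value.
#'
#' @param tally a [ReannotationTally-class].
#' @param digits decimal places (default 0; NA = unrounded).
#' @return numeric percentage in [0, 100].
#' @examples
#' reannotationRate(ReannotationTally(c(4, 5, 17, 34, 4, 1)))  # 14/65 -> 22
#' @export
reannotationRate <- function(tally, digits = 0) {
  stopifnot(is(tally, "ReannotationTally"))
  if (tally@total == 0L) stop("empty tally")
  changed <- sum(tally@counts[c("am_right", "partially_right",
                                "both_wrong", "negative")])
  rate <- 100 * changed / tally@total
  if (is.na(digits)) rate else round(rate, digits)
}

#' Enrichment of a candidate method over the random baseline
#'
#' Ratio of a method's reannotation rate to the random-sampling rate,
#' reported to one decimal. Rates are taken as given (conventionally the
#' integer-rounded reported rates).
#'
#' @param rateMethod method reannotation rate (percent).
#' @param rateRandom random-baseline rate (percent); must be > 0.
#' @param digits decimal places (default 1; NA = unrounded).
#' @return numeric fold enrichment.
#' @examples
#' enrichment(39, 22)  # 1.8
#' @export
enrichment <- function(rateMethod, rateRandom, digits = 1) {
  if (rateRandom <= 0) stop("undefined enrichment: random rate is 0")
  fold <- rateMethod / rateRandom
  if (is.na(digits)) fold else round(fold, digits)
}
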