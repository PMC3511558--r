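# Delimited-text contracts shared by all stages.
#
# Feature table : header protein_id, image_id, cell_id, <feature columns>
# Annotations   : header protein_id, labels (multi-labels ";"-joined)
# Candidate list: header rank, protein_id, sources, score

.readDelim <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character")
}

#' Read a per-cell feature table
#'
#' Parses the delimited-text feature contract: one row per segmented cell,
#' grouping-key columns \code{protein_id}, \code{image_id}, \code{cell_id},
#' and any number of numeric feature columns. Non-numeric or non-finite
#' feature cells are an error (never silently dropped), as are duplicate
#' key triples.
#'
#' @param path path to a TSV (or CSV) file.
#' @param sep field delimiter; tab by default, \code{","} accepted.
#' @return A [CellFeatureSet-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  need <- c("protein_id", "image_id", "cell_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("feature table schema error: missing column(s) ",
         paste(miss, collapse = ", "))
  featCols <- setdiff(colnames(df), need)
  if (!length(featCols)) stop("feature table has no feature columns")
  m <- matrix(NA_real_, nrow(df), length(featCols),
              dimnames = list(NULL, featCols))
  for (j in featCols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in feature '%s', row %d",
                   j, bad[1L]))
    m[, j] <- v
  }
  CellFeatureSet(m, df$protein_id, df$image_id, df$cell_id)
}

#' Write a per-cell feature table
#'
#' @param x a [CellFeatureSet-class].
#' @param path output file path.
#' @param sep field delimiter (tab by default).
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(x, path, sep = "\t") {
  stopifnot(is(x, "CellFeatureSet"))
  df <- cbind(cellKeys(x), as.data.frame(featureMatrix(x)))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein annotation file
#'
#' Two columns: \code{protein_id} and \code{labels}, with multiple labels
#' joined by \code{labelSep}. Labels are whitespace-trimmed; an empty label
#' set is an error; with a strict vocabulary, unknown labels are an error.
#'
#' @param path path to a TSV (or CSV) file.
#' @param sep field delimiter.
#' @param labelSep separator between labels within the labels field.
#' @param vocabulary optional character vector of admissible labels.
#' @return A [LocationAnnotation-class].
#' @export
readAnnotations <- function(path, sep = "\t", labelSep = ";",
                            vocabulary = character()) {
  df <- .readDelim(path, sep)
  if (!all(c("protein_id", "labels") %in% colnames(df)))
    stop("annotation schema error: need columns protein_id, labels")
  sets <- lapply(strsplit(df$labels, labelSep, fixed = TRUE),
                 function(x) {
                   x <- trimws(x)
                   x[nzchar(x)]
                 })
  names(sets) <- df$protein_id
  empty <- vapply(sets, length, 0L) == 0L
  if (any(empty))
    stop("empty label set for protein '", df$protein_id[empty][1L], "'")
  LocationAnnotation(sets, vocabulary = vocabulary)
}

#' Write a protein annotation file
#'
#' @param x a [LocationAnnotation-class].
#' @param path output file path.
#' @param sep field delimiter.
#' @param labelSep separator used to join multi-label sets.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(x, path, sep = "\t", labelSep = ";") {
  stopifnot(is(x, "LocationAnnotation"))
  df <- data.frame(protein_id = proteinIds(x),
                   labels = vapply(labelSets(x), paste, "",
                                   collapse = labelSep))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a candidate list
#'
#' @param path path to a TSV with columns rank, protein_id, sources, score.
#' @param sep field delimiter.
#' @return A [ReannotationCandidates-class].
#' @export
readCandidates <- function(path, sep = "\t") {
  df <- .readDelim(path, sep)
  if (!all(c("rank", "protein_id", "sources", "score") %in% colnames(df)))
    stop("candidate schema error: need rank, protein_id, sources, score")
  df <- df[order(as.integer(df$rank)), , drop = FALSE]
  out <- ReannotationCandidates(df$protein_id, sources = df$sources,
                                score = suppressWarnings(as.numeric(df$score)))
  out
}

#' Write a candidate list
#'
#' @param x a [ReannotationCandidates-class].
#' @param path output file path.
#' @param sep field delimiter.
#' @return \code{path}, invisibly.
#' @export
writeCandidates <- function(x, path, sep = "\t") {
  stopifnot(is(x, "ReannotationCandidates"))
  write.table(candidateEntries(x), path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Merge candidate lists from several sources
#'
#' Forms the union of the input lists. A protein present in several lists
#' keeps the union of its sources and its best (lowest) rank; the merged
#' list is re-ranked 1..n by (best rank, then input order). The merged size
#' is always \eqn{\sum_i |L_i| -} duplicates.
#'
#' @param ... [ReannotationCandidates-class] objects, or a single list of
#'   them.
#' @return A [ReannotationCandidates-class].
#' @examples
#' a <- ReannotationCandidates(c("P1", "P2"), "svm")
#' b <- ReannotationCandidates(c("P2", "P3"), "cluster")
#' length(mergeCandidates(a, b))  # 3
#' @export
mergeCandidates <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) &&
      !is(lists[[1]], "ReannotationCandidates"))
    lists <- lists[[1]]
  stopifnot(length(lists) >= 1L,
            all(vapply(lists, is, TRUE, "ReannotationCandidates")))
  all <- do.call(rbind, lapply(lists, candidateEntries))
  keep <- list()
  for (i in seq_len(nrow(all))) {
    id <- all$protein_id[i]
    if (is.null(keep[[id]])) {
      keep[[id]] <- all[i, ]
    } else {
      prev <- keep[[id]]
      src <- union(strsplit(prev$sources, ";", fixed = TRUE)[[1]],
                   strsplit(all$sources[i], ";", fixed = TRUE)[[1]])
      prev$sources <- paste(src, collapse = ";")
      if (all$rank[i] < prev$rank) {
        prev$rank <- all$rank[i]
        prev$score <- all$score[i]
      }
      keep[[id]] <- prev
    }
  }
  merged <- do.call(rbind, keep)
  merged <- merged[order(merged$rank, seq_len(nrow(merged))), , drop = FALSE]
  ReannotationCandidates(merged$protein_id, sources = merged$sources,
                         score = merged$score)
}
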