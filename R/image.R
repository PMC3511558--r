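# Toy image -> feature path: renders idealized single-cell fluorescence
# patterns (four channels: nucleus, ER-like, microtubule-like references
# plus the protein channel) and computes a small, documented feature
# vector. This is a simplified stand-in for full subcellular-location
# feature extraction, sufficient to exercise the downstream pipeline.

.patterns <- c("nuclear", "nuclear_no_nucleoli", "nucleolar", "cytoplasmic",
               "vesicular", "perinuclear", "filamentous")

#' Supported synthetic cell patterns
#'
#' @return character vector of pattern names accepted by
#'   [renderCellImage()].
#' @export
cellPatterns <- function() .patterns

.ellipse <- function(nr, nc, cx, cy, rx, ry) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), nc), nr, nc)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Render an idealized single-cell image
#'
#' Draws a 64x64 four-channel raster: a nucleus reference, an ER-like
#' reference (perinuclear haze), a microtubule-like reference (radial
#' filaments) and a protein channel with the requested pattern geometry.
#' Pixel values lie in [0, 1] and are quantized to 8-bit levels.
#' Deterministic for a given (pattern, seed).
#'
#' @param pattern one of [cellPatterns()].
#' @param seed integer seed controlling cell geometry and noise.
#' @param size image side length in pixels (default 64).
#' @return list with \code{channels} (named list of matrices:
#'   \code{nucleus}, \code{er}, \code{mt}, \code{protein}), \code{mask}
#'   (logical cell mask) and \code{nucleusMask} (logical).
#' @export
renderCellImage <- function(pattern, seed = 1L, size = 64L) {
  pattern <- match.arg(pattern, .patterns)
  withr::with_seed(as.integer(seed), .renderImpl(pattern, as.integer(size)))
}

.renderImpl <- function(pattern, size) {
  cx <- size / 2 + runif(1, -3, 3)
  cy <- size / 2 + runif(1, -3, 3)
  crx <- size * runif(1, 0.38, 0.45)
  cry <- size * runif(1, 0.30, 0.40)
  cell <- .ellipse(size, size, cx, cy, crx, cry)
  nrx <- crx * runif(1, 0.35, 0.45)
  nry <- cry * runif(1, 0.35, 0.45)
  ncx <- cx + runif(1, -2, 2)
  ncy <- cy + runif(1, -2, 2)
  nuc <- .ellipse(size, size, ncx, ncy, nrx, nry) & cell
  periNuc <- .ellipse(size, size, ncx, ncy, nrx * 1.45, nry * 1.45) &
    cell & !nuc
  # 2-3 nucleoli: small discs inside the nucleus
  nNucleoli <- sample(2:3, 1)
  nucleoli <- matrix(FALSE, size, size)
  for (i in seq_len(nNucleoli)) {
    a <- runif(1, 0, 2 * pi); r <- runif(1, 0.2, 0.6)
    nucleoli <- nucleoli | .ellipse(size, size,
                                    ncx + cos(a) * r * nrx,
                                    ncy + sin(a) * r * nry,
                                    max(2, nrx * 0.22), max(2, nry * 0.22))
  }
  nucleoli <- nucleoli & nuc
  cyto <- cell & !nuc

  radial <- function(nLines, inner, width = 1.2) {
    m <- matrix(0, size, size)
    x <- matrix(rep(seq_len(size), each = size), size, size)
    y <- matrix(rep(seq_len(size), size), size, size)
    ang <- atan2(y - ncy, x - ncx)
    rad <- sqrt((x - ncx)^2 + (y - ncy)^2)
    th <- runif(nLines, -pi, pi)
    for (t in th) {
      d <- abs(((ang - t + pi) %% (2 * pi)) - pi) * rad
      m <- pmax(m, exp(-(d / width)^2) * (rad > inner))
    }
    m * cell
  }

  noise <- function() matrix(runif(size * size, 0, 0.02), size, size)
  prot <- switch(pattern,
    nuclear = nuc * 0.9,
    nuclear_no_nucleoli = (nuc & !nucleoli) * 0.9,
    nucleolar = nucleoli * 0.9,
    cytoplasmic = cyto * 0.7,
    perinuclear = periNuc * 0.9,
    vesicular = {
      m <- matrix(0, size, size)
      idx <- which(cyto)
      pick <- sample(idx, min(25L, length(idx)))
      for (p in pick) {
        i <- (p - 1) %% size + 1; j <- (p - 1) %/% size + 1
        m <- m | .ellipse(size, size, j, i, 1.6, 1.6)
      }
      (m & cell) * 0.9
    },
    filamentous = radial(9L, inner = 2))
  channels <- list(
    nucleus = pmin(1, nuc * 0.9 + noise() * cell),
    er = pmin(1, periNuc * 0.7 + cyto * 0.25 + noise() * cell),
    mt = pmin(1, radial(14L, inner = nrx * 0.8) * 0.8 + noise() * cell),
    protein = pmin(1, prot + noise() * cell))
  channels <- lapply(channels, function(m) round(m * 255) / 255)
  list(channels = channels, mask = cell, nucleusMask = nuc)
}

#' Names of the basic image features, in output order
#'
#' @return character vector naming the entries of
#'   [extractBasicFeatures()].
#' @export
basicFeatureNames <- function() {
  c("int_mean", "int_sd", "int_max", "int_q75",
    "frac_in_nucleus", "overlap_er", "overlap_mt",
    "object_count", "object_mean_size",
    "radial_mean", "radial_sd",
    "grad_mean", "grad_sd")
}

#' Extract basic features from a rendered cell image
#'
#' Computes a fixed-length, documented feature vector from a four-channel
#' raster and its cell mask: protein-channel intensity statistics, the
#' fraction of protein mass inside the nucleus, overlap of the thresholded
#' protein signal with the thresholded ER-like and microtubule-like
#' references, object count and mean object size after thresholding at
#' half the channel maximum, radial distribution moments (intensity-
#' weighted distance from the cell centroid, normalized by the cell
#' radius) and gradient-magnitude texture summaries. Deterministic.
#' Requires the EBImage package for connected-component labeling.
#'
#' @param image a list as returned by [renderCellImage()] (or a list with
#'   \code{channels} and \code{nucleusMask}).
#' @param mask logical cell mask; defaults to \code{image$mask}.
#' @return named numeric vector of length
#'   \code{length(basicFeatureNames())}.
#' @export
extractBasicFeatures <- function(image, mask = image$mask) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("extractBasicFeatures requires the EBImage package")
  if (!any(mask)) stop("empty cell mask")
  ch <- image$channels
  p <- ch$protein * mask
  inMask <- p[mask]
  total <- sum(p)
  thr <- if (max(p) > 0) 0.5 * max(p) else Inf
  pBin <- p >= thr & mask
  lab <- EBImage::bwlabel(pBin)
  nObj <- max(lab)
  objSize <- if (nObj > 0) sum(pBin) / nObj else 0
  nucMask <- image$nucleusMask
  fracNuc <- if (total > 0) sum(p[nucMask]) / total else 0
  ovl <- function(ref) {
    refBin <- ref >= 0.5 * max(ref) & mask
    if (sum(pBin) == 0) 0 else sum(pBin & refBin) / sum(pBin)
  }
  idx <- which(mask, arr.ind = TRUE)
  cyx <- colMeans(idx)
  rmax <- max(sqrt((idx[, 1] - cyx[1])^2 + (idx[, 2] - cyx[2])^2))
  if (total > 0) {
    pi2 <- which(p > 0, arr.ind = TRUE)
    w <- p[p > 0]
    r <- sqrt((pi2[, 1] - cyx[1])^2 + (pi2[, 2] - cyx[2])^2) / rmax
    rMean <- sum(w * r) / sum(w)
    rSd <- sqrt(sum(w * (r - rMean)^2) / sum(w))
  } else rMean <- rSd <- 0
  gx <- abs(p[, -1] - p[, -ncol(p)])
  gy <- abs(p[-1, ] - p[-nrow(p), ])
  grad <- c(gx, gy)
  out <- c(mean(inMask), stats::sd(inMask), max(p),
           unname(quantile(inMask, 0.75)),
           fracNuc, ovl(ch$er), ovl(ch$mt),
           nObj, objSize, rMean, rSd,
           mean(grad), stats::sd(grad))
  out[!is.finite(out)] <- 0
  names(out) <- basicFeatureNames()
  out
}
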