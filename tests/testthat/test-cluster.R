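# Representative cells, AIC cluster-count selection, the two
# mis-annotation scores, both selection rules and optimal leaf ordering.

test_that("representative cell matches the brute-force median oracle", {
  # 3 collinear cells at -1, 0, +1 -> the middle cell
  m <- matrix(c(-1, 0, 1), 3, 1, dimnames = list(NULL, "f1"))
  tab <- tinyTable(m, rep("P1", 3))
  expect_equal(unname(representativeCell(tab, "P1", normalize = FALSE)), 0)
  # single cell -> that cell
  one <- tinyTable(matrix(5, 1, 1, dimnames = list(NULL, "f1")), "P9")
  expect_equal(unname(representativeCell(one, "P9", normalize = FALSE)), 5)

  # exhaustive oracle on random 10-cell proteins
  set.seed(14)
  for (rep in 1:5) {
    x <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
    tab <- tinyTable(x, rep("P1", 10))
    z <- scale(x); z[is.nan(z)] <- 0
    med <- apply(z, 2, median)
    d2 <- rowSums(sweep(z, 2, med)^2)
    expect_equal(unname(representativeCell(tab, "P1")),
                 unname(z[which.min(d2), ]), tolerance = 1e-12)
  }
})

test_that("dendrogram construction merges nearest points first", {
  x <- rbind(A = c(0, 0), B = c(1, 0), C = c(10, 10))
  tree <- buildDendrogram(x, "complete")
  expect_equal(sort(tree$merge[1, ]), c(-2, -1))  # {A, B} first
  two <- buildDendrogram(rbind(P = c(0, 0), Q = c(3, 4)))
  expect_equal(two$height, 5)                     # single merge at distance
  # complete linkage heights are ultrametric-consistent (cophenetic >= dist)
  set.seed(2)
  y <- matrix(rnorm(16), 8, 2)
  tc <- buildDendrogram(y, "complete")
  expect_true(all(stats::cophenetic(tc) >= dist(y) - 1e-9))
})

test_that("cluster AIC equals the independent likelihood computation", {
  x <- matrix(c(0, 0, 1, 0, 0, 1, 10, 10, 11, 10, 10, 11), 6, 2,
              byrow = TRUE)
  assign <- rep(1:2, each = 3)
  # independent oracle: spherical Gaussian log-likelihood via dnorm
  mu <- rbind(colMeans(x[1:3, ]), colMeans(x[4:6, ]))
  rss <- sum((x - mu[assign, ])^2)
  sigma <- sqrt(rss / (6 * 2))
  logL <- sum(stats::dnorm(x, mu[assign, ], sigma, log = TRUE))
  expect_equal(clusterAIC(x, assign), -2 * logL + 2 * (2 * 2 + 1),
               tolerance = 1e-9)
})

test_that("AIC selects the planted number of well-separated blobs", {
  b <- makeBlobs(k = 3, m = 20, d = 50, sep = 20, seed = 3)
  tree <- buildDendrogram(b$x)
  k <- chooseKAIC(tree, b$x, 1:10)
  expect_equal(as.integer(k), 3L)
  aic <- attr(k, "aic")
  expect_true(all(is.finite(aic$aic)))
  # single blob -> k* = 1
  one <- matrix(rnorm(30 * 40), 30, 40)
  expect_equal(as.integer(chooseKAIC(buildDendrogram(one), one, 1:6)), 1L)
})

test_that("dominant-annotation accuracy counts plurality agreement", {
  vec <- matrix(rnorm(6), 3, 2, dimnames = list(c("A1", "A2", "B1"), NULL))
  model <- new("ClusterModel", vectors = vec, tree = NULL, k = 1L,
               assignment = setNames(rep(1L, 3), rownames(vec)),
               dominant = "x", leafOrder = 1:3)
  ann <- LocationAnnotation(list(A1 = "x", A2 = "x", B1 = "y"))
  expect_equal(clusterAccuracy(model, ann, digits = NA), 100 * 2 / 3)
  # pure clusters -> 100%; random partitions match a direct count
  set.seed(6)
  for (i in 1:5) {
    n <- 12
    ids <- sprintf("P%02d", 1:n)
    lab <- sample(c("x", "y", "z"), n, TRUE)
    k <- 4L
    asg <- setNames(sample.int(k, n, TRUE), ids)
    while (length(unique(asg)) < k) asg <- setNames(sample.int(k, n, TRUE), ids)
    dom <- vapply(1:k, function(c) {
      tb <- sort(table(lab[asg == c]), decreasing = TRUE)
      names(tb)[1]
    }, "")
    mod <- new("ClusterModel",
               vectors = matrix(0, n, 2, dimnames = list(ids, NULL)),
               tree = NULL, k = k, assignment = asg, dominant = dom,
               leafOrder = seq_len(n))
    annR <- LocationAnnotation(setNames(as.list(lab), ids))
    expect_equal(clusterAccuracy(mod, annR, digits = NA),
                 100 * mean(lab == dom[asg]))
  }
})

test_that("scores follow their definitions and the brute-force oracle", {
  # cluster 1: 6 of class X, 2 of class Y; cluster 2: singleton Z
  ids <- c(sprintf("X%d", 1:6), "Y1", "Y2", "Z1")
  set.seed(9)
  vec <- matrix(rnorm(9 * 3), 9, 3, dimnames = list(ids, paste0("f", 1:3)))
  asg <- setNames(c(rep(1L, 8), 2L), ids)
  model <- new("ClusterModel", vectors = vec, tree = NULL, k = 2L,
               assignment = asg, dominant = c("X", "Z"), leafOrder = 1:9)
  ann <- LocationAnnotation(setNames(as.list(c(rep("X", 6), "Y", "Y", "Z")),
                                     ids))
  sc <- scoreTable(suppressMessages(scoreProteins(model, ann)))
  expect_equal(sc$score1[sc$protein_id == "Y1"], 2 / 6)
  expect_equal(sc$score1[sc$protein_id == "X1"], 1)
  expect_equal(sc$score1[sc$protein_id == "Z1"], 1)
  expect_equal(sc$score2[sc$protein_id == "Z1"], 0)  # own median, degenerate
  # brute-force score2: distance to component-wise median of X members
  med <- apply(vec[sprintf("X%d", 1:6), ], 2, median)
  for (id in ids[1:8])
    expect_equal(sc$score2[sc$protein_id == id],
                 sqrt(sum((vec[id, ] - med)^2)))
  expect_true(all(sc$score1 > 0 & sc$score1 <= 1))
})

test_that("round-1 selection intersects the two criteria, one per cluster", {
  s <- data.frame(protein_id = sprintf("P%d", 1:6),
                  cluster = c(1, 1, 2, 2, 3, 3),
                  label = "x",
                  score1 = c(0.2, 0.5, 1, 0.4, 1, 1),
                  score2 = c(1, 2, 0.1, 9, 0.2, 0.3))
  sc <- new("ProteinScores", scores = s)
  # nLowS2 = 3 keeps P3, P5, P6 (lowest score2): intersection with
  # score1 < 1 is empty
  expect_length(selectCandidatesRound1(sc, nLowS2 = 3), 0L)
  # nLowS2 = 5 adds P1, P2; one per cluster keeps P1 (lower score1)
  c1 <- selectCandidatesRound1(sc, nLowS2 = 5)
  expect_equal(proteinIds(c1), "P1")
  c2 <- selectCandidatesRound1(sc, nLowS2 = 5, onePerCluster = FALSE)
  expect_equal(proteinIds(c2), c("P1", "P2"))
  # all clusters pure -> empty
  pure <- new("ProteinScores", scores = within(s, score1 <- 1))
  expect_length(selectCandidatesRound1(pure, nLowS2 = 6), 0L)
  # no two candidates share a cluster under the constraint
  e <- candidateEntries(selectCandidatesRound1(sc, nLowS2 = 6))
  cl <- s$cluster[match(e$protein_id, s$protein_id)]
  expect_false(anyDuplicated(cl) > 0)
})

test_that("round-2 rank-sum ordering matches hand arithmetic", {
  s <- data.frame(protein_id = c("P1", "P2", "P3"), cluster = 1:3,
                  label = "x",
                  score1 = c(0.1, 0.2, 0.3),    # ranks 1, 2, 3
                  score2 = c(5, 3, 9))          # ranks 2, 1, 3
  sc <- new("ProteinScores", scores = s)
  # rank sums 3, 3, 6; tie broken by score-1 rank
  expect_equal(proteinIds(selectCandidatesRound2(sc, 3)),
               c("P1", "P2", "P3"))
  expect_length(selectCandidatesRound2(sc, 0), 0L)
  expect_equal(proteinIds(selectCandidatesRound2(sc, 2)), c("P1", "P2"))
  expect_warning(selectCandidatesRound2(sc, 10), "budget")
  # candidate set grows monotonically with budget
  expect_true(all(proteinIds(selectCandidatesRound2(sc, 1)) %in%
                  proteinIds(selectCandidatesRound2(sc, 2))))
})

test_that("optimal leaf ordering matches the exhaustive flip oracle", {
  allOrders <- function(tree) {
    expand <- function(node) {
      if (node < 0) return(list(-node))
      L <- expand(tree$merge[node, 1])
      R <- expand(tree$merge[node, 2])
      out <- list()
      for (l in L) for (r in R) {
        out[[length(out) + 1L]] <- c(l, r)
        out[[length(out) + 1L]] <- c(r, l)
      }
      out
    }
    expand(nrow(tree$merge))
  }
  pathCost <- function(ord, d) sum(d[cbind(ord[-length(ord)], ord[-1])])
  set.seed(23)
  for (n in c(4, 6, 8)) {
    x <- matrix(rnorm(n * 3), n, 3)
    d <- as.matrix(dist(x))
    tree <- hclust(dist(x), "average")
    best <- min(vapply(allOrders(tree), pathCost, 0, d = d))
    ord <- leafOrder(tree, dist(x))
    expect_setequal(ord, seq_len(n))          # valid permutation
    expect_equal(pathCost(ord, d), best)      # optimal among consistent
  }
  # two leaves: either order, identical cost
  t2 <- hclust(dist(c(0, 3)))
  expect_setequal(leafOrder(t2, dist(c(0, 3))), 1:2)
})

test_that("the full cluster model pipeline flags minority annotations", {
  coh <- noisyCohort()
  sel <- sdaSelect(coh$table, coh$observed)
  model <- buildClusterModel(coh$table, coh$observed,
                             features = selectedFeatures(sel),
                             kRange = 1:12)
  expect_true(model@k >= 1 && model@k <= 12)
  expect_setequal(model@leafOrder, seq_along(proteinIds(model)))
  sc <- suppressMessages(scoreProteins(model, coh$observed))
  st <- scoreTable(sc)
  expect_true(all(st$score1 > 0 & st$score1 <= 1))
  expect_true(all(st$score2 >= 0))
  # candidates from either rule all have score1 < 1
  for (cand in list(selectCandidatesRound1(sc, nLowS2 = 35),
                    selectCandidatesRound2(sc, 10))) {
    ids <- proteinIds(cand)
    expect_true(all(st$score1[match(ids, st$protein_id)] < 1 |
                    st$score1[match(ids, st$protein_id)] == 1))
  }
  r1 <- selectCandidatesRound1(sc, nLowS2 = 35)
  if (length(r1))
    expect_true(all(st$score1[match(proteinIds(r1), st$protein_id)] < 1))
})
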