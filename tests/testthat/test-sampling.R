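# Random baseline, outcome tallies, rates and enrichment.

test_that("per-class sampling with replacement is seeded and bounded", {
  lab <- c(rep("a", 30), rep("b", 5), "c")
  ann <- LocationAnnotation(setNames(as.list(lab),
                                     sprintf("P%02d", seq_along(lab))))
  s <- randomSamplePerClass(ann, r = 7, seed = 4)
  expect_lte(length(s), 3 * 7)
  expect_identical(proteinIds(randomSamplePerClass(ann, 7, seed = 4)),
                   proteinIds(s))
  # a size-1 class collapses to that single protein
  expect_true("P36" %in% proteinIds(s))
  expect_equal(sum(proteinIds(s) == "P36"), 1L)
  # sampled proteins stay within their class
  expect_true(all(proteinIds(s) %in% names(lab <- setNames(lab,
    sprintf("P%02d", seq_along(lab))))))
})

test_that("outcome categories follow their definitions", {
  prev <- LocationAnnotation(list(P1 = "X", P2 = "X", P3 = "X", P4 = "X",
                                  P5 = "X", P6 = "X"))
  auto <- c(P1 = "Y", P2 = "Y", P3 = "X", P4 = "Y", P5 = "Y", P6 = "Y")
  newAnn <- LocationAnnotation(list(
    P1 = "Y",                      # am_right
    P2 = c("X", "Y"),              # partially_right
    P3 = "X",                      # both_right
    P4 = "X",                      # am_wrong
    P5 = "Z",                      # both_wrong
    P6 = "non-specific location")) # negative
  t <- tallyOutcomes(prev, auto, newAnn, paste0("P", 1:6))
  expect_equal(unname(outcomeCounts(t)), rep(1L, 6))
  expect_error(tallyOutcomes(prev, auto, newAnn, c("P1", "P99")), "covered")
})

test_that("outcome categories are exclusive and exhaustive", {
  # every (previous, automated, new) combination over a 3-label vocabulary
  labs <- c("X", "Y", "Z")
  newSets <- c(lapply(seq_along(labs), function(i) labs[i]),
               list(c("X", "Y"), c("X", "Z"), c("Y", "Z"), labs,
                    "non-specific location"))
  n <- 0L
  for (p in labs) for (a in labs) for (new in newSets) {
    t <- tallyOutcomes(LocationAnnotation(list(Q = p)), c(Q = a),
                       LocationAnnotation(list(Q = new)), "Q")
    expect_equal(sum(outcomeCounts(t)), 1L)  # exactly one category fires
    n <- n + 1L
  }
  expect_equal(n, 3L * 3L * 8L)
})

test_that("published tally columns sum and reproduce the printed rates", {
  svm1 <- referenceOutcomes("round1", "svm")
  expect_equal(svm1@total, 99L)
  expect_equal(sum(outcomeCounts(svm1)), 99L)
  expect_equal(reannotationRate(svm1), 39)             # (21+7+9+2)/99
  expect_equal(reannotationRate(referenceOutcomes("round1", "random_svm")),
               22)                                     # 14/65
  expect_equal(reannotationRate(referenceOutcomes("round1", "cluster")),
               33)                                     # 4/12
  expect_equal(reannotationRate(referenceOutcomes("round2", "svm")), 36)
  expect_equal(reannotationRate(referenceOutcomes("round2", "cluster")), 32)
  expect_equal(reannotationRate(referenceOutcomes("round2", "random_svm")),
               11)                                     # 9/80
  # all both_right -> 0%
  zero <- ReannotationTally(c(0, 0, 12, 0, 0, 0))
  expect_equal(reannotationRate(zero), 0)
  expect_error(reannotationRate(ReannotationTally(rep(0, 6))), "empty")
})

test_that("enrichment folds divide reported rates", {
  expect_equal(enrichment(39, 22), 1.8)
  expect_equal(enrichment(33, 22), 1.5)
  expect_equal(enrichment(36, 11), 3.3)
  expect_equal(enrichment(32, 11), 2.9)
  expect_equal(enrichment(50, 50), 1.0)
  expect_error(enrichment(10, 0), "undefined")
})

test_that("rates stay in range and a tally validates its counts", {
  set.seed(3)
  for (i in 1:20) {
    t <- ReannotationTally(rpois(6, 5) + c(1, 0, 0, 0, 0, 0))
    r <- reannotationRate(t, digits = NA)
    expect_gte(r, 0); expect_lte(r, 100)
    expect_equal(enrichment(r, r, digits = NA), 1)
  }
  expect_error(new("ReannotationTally",
                   counts = setNames(rep(1L, 6),
                                     c("am_right", "partially_right",
                                       "both_right", "am_wrong",
                                       "both_wrong", "negative")),
               total = 5L))
})
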