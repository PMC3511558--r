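# Delimited-text contracts: parsing, validation, round-trips, and
# candidate-list merging.

test_that("feature table round-trips and validates", {
  m <- matrix(c(1.5, 2, 3, -0.5, 0, 10), 3, 2,
              dimnames = list(NULL, c("f_a", "f_b")))
  cfs <- tinyTable(m, c("P1", "P1", "P2"))
  expect_equal(ncol(cfs), 3L)        # 3 cells
  expect_equal(nrow(cfs), 2L)        # 2 features
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(cfs, path)
  back <- readFeatureTable(path)
  expect_equal(featureMatrix(back), featureMatrix(cfs),
               ignore_attr = "dimnames")
  expect_equal(cellKeys(back), cellKeys(cfs))

  # non-numeric and non-finite cells are errors, not silent drops
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\timage_id\tcell_id\tf1",
               "P1\ti1\tc1\tNaN"), bad)
  expect_error(readFeatureTable(bad), "non-numeric|non-finite")
  writeLines(c("protein_id\timage_id\tcell_id\tf1",
               "P1\ti1\tc1\tabc"), bad)
  expect_error(readFeatureTable(bad), "non-numeric")
  writeLines(c("protein_id\tcell_id\tf1", "P1\tc1\t1"), bad)
  expect_error(readFeatureTable(bad), "schema")
  # duplicate key triple violates the container invariant
  expect_error(CellFeatureSet(matrix(1:2, 2, 1), c("P1", "P1"),
                              c("i1", "i1"), c("c1", "c1")),
               "duplicate")
})

test_that("annotations parse label sets and reject empties", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tlabels", "P1\tnucleus",
               "P2\tcytoplasm; golgi"), path)
  ann <- readAnnotations(path)
  expect_equal(labelSets(ann)$P1, "nucleus")
  expect_setequal(labelSets(ann)$P2, c("cytoplasm", "golgi"))
  expect_equal(unname(isSinglePattern(ann)), c(TRUE, FALSE))

  writeLines(c("protein_id\tlabels", "P3\t"), path)
  expect_error(readAnnotations(path), "empty label set")
  writeLines(c("protein_id\tlabels", "P1\tmoon"), path)
  expect_error(readAnnotations(path, vocabulary = c("nucleus", "golgi")),
               "vocabulary")

  # write/read round-trip
  writeAnnotations(ann, path)
  expect_equal(labelSets(readAnnotations(path)), labelSets(ann))
})

test_that("candidate lists round-trip and validate rank structure", {
  cand <- ReannotationCandidates(c("P3", "P1", "P9"), sources = "svm",
                                 score = c(0.9, 0.5, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(cand, path)
  back <- readCandidates(path)
  expect_equal(proteinIds(back), proteinIds(cand))
  expect_error(ReannotationCandidates(c("P1", "P1")), "unique")
})

test_that("merging unions sources, keeps best rank, re-ranks densely", {
  a <- ReannotationCandidates(c("P1", "P2", "P3"), "svm")
  b <- ReannotationCandidates(c("P4", "P2"), "cluster")
  m <- mergeCandidates(a, b)
  expect_equal(length(m), 4L)
  e <- candidateEntries(m)
  expect_equal(e$rank, 1:4)
  expect_setequal(strsplit(e$sources[e$protein_id == "P2"], ";")[[1]],
                  c("svm", "cluster"))
  # best (lowest) original rank is the sort key: P1 and P4 held rank 1,
  # P2 rank 2, P3 rank 3
  expect_equal(e$protein_id, c("P1", "P4", "P2", "P3"))

  # disjoint singletons
  expect_equal(length(mergeCandidates(ReannotationCandidates("A"),
                                      ReannotationCandidates("B"))), 2L)
})

test_that("merged size equals sum minus duplicates (published list sizes)", {
  ids <- sprintf("HPA%04d", 1:400)
  # 99 + 12 with 5 shared -> 106 candidates round 1
  svm1 <- ReannotationCandidates(ids[1:99], "svm")
  clt1 <- ReannotationCandidates(c(ids[1:5], ids[100:106]), "cluster")
  expect_equal(length(mergeCandidates(svm1, clt1)), 106L)
  # 103 + 80 with 21 shared -> 162 round 2
  auto2 <- ReannotationCandidates(ids[1:103], "svm")
  rand2 <- ReannotationCandidates(c(ids[1:21], ids[200:258]), "random")
  expect_equal(length(mergeCandidates(auto2, rand2)), 162L)

  # property: |merge(A,B)| = |A| + |B| - |A n B| on random lists
  set.seed(11)
  for (i in 1:25) {
    A <- sample(ids, sample(1:40, 1))
    B <- sample(ids, sample(1:40, 1))
    m <- mergeCandidates(ReannotationCandidates(A, "svm"),
                         ReannotationCandidates(B, "random"))
    expect_equal(length(m), length(A) + length(B) - length(intersect(A, B)))
    expect_equal(candidateEntries(m)$rank, seq_len(length(m)))
  }
})
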