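test_that("p-distances count mismatches over compared columns", {
  expect_true(all(pDistance(c(a = "ACDE", b = "ACDE")) == 0))
  expect_equal(pDistance(c(a = "ACDE", b = "ACDF"))["a", "b"], 0.25)
  # complete deletion drops the gapped column for every pair
  d <- pDistance(c(a = "A-DE", b = "ACDF"), gapMode = "complete")
  expect_equal(d["a", "b"], 1 / 3)
  # pairwise deletion only drops per-pair gapped columns
  d2 <- pDistance(c(a = "A-DE", b = "ACDF", c = "ACDE"),
                  gapMode = "pairwise")
  expect_equal(d2["a", "b"], 1 / 3)
  expect_equal(d2["b", "c"], 0.25)
  expect_true(isSymmetric(d2) && all(diag(d2) == 0))

  expect_error(pDistance(c(a = "--", b = "AC"), gapMode = "complete"),
               "no gap-free")
  expect_error(pDistance(c(a = "-C", b = "A-"), gapMode = "pairwise"),
               "no comparable")
  expect_error(pDistance(c(a = "AC", b = "ACD")), "equal length")
})

test_that("the Kimura protein correction behaves on its valid range", {
  expect_equal(kimuraCorrect(0), 0)
  expect_equal(kimuraCorrect(0.25), -log(0.7375))
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(kimuraCorrect(p)) > 0))
  expect_error(kimuraCorrect(0.9), "saturated")
  expect_warning(capped <- kimuraCorrect(c(0.1, 0.9), onSaturate = "cap"),
                 "capped")
  expect_equal(attr(capped, "saturated"), c(FALSE, TRUE))
})

test_that("three-taxon NJ reproduces the closed-form limb lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  pm <- pathMetric(tr)
  expect_equal(pm, D[rownames(pm), colnames(pm)])
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(unname(lens["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(lens["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(lens["C"]), (4 + 5 - 3) / 2)
})

test_that("NJ recovers the generating additive tree exactly", {
  # ((A:1,B:2):1,(C:3,D:4)): the printed pairwise distances
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighborJoining(D)
  pm <- pathMetric(tr)
  expect_equal(pm, D[rownames(pm), colnames(pm)], tolerance = 1e-12)
  expect_equal(treeBipartitions(tr), "C,D")  # the AB|CD split

  expect_error(neighborJoining(D[1:2, 1:2]), "at least 3")
  Dneg <- D; Dneg[1, 2] <- Dneg[2, 1] <- -1
  expect_error(neighborJoining(Dneg), "non-negative")
  Dasym <- D; Dasym[1, 2] <- 99
  expect_error(neighborJoining(Dasym), "symmetric")
})

test_that("NJ agrees with ape::nj and is additive on random trees", {
  for (seed in 1:30) {
    n <- 4 + seed %% 5
    ra <- randomAdditive(n, seed)
    tr <- neighborJoining(ra$D)
    pm <- pathMetric(tr)
    expect_lt(max(abs(pm - ra$D[rownames(pm), colnames(pm)])), 1e-9)
    expect_setequal(treeBipartitions(tr),
                    treeBipartitions(ape::unroot(ra$tree)))
    # independent implementation cross-check on the same matrix
    expect_setequal(treeBipartitions(tr), treeBipartitions(ape::nj(ra$D)))
  }
})

test_that("bootstrap supports are seeded, bounded and concentrated on real splits", {
  # two tight 3-taxon clusters separated by a long branch
  set.seed(99)
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  base <- sample(alphabet, 100, replace = TRUE)
  far <- sample(alphabet, 100, replace = TRUE)
  mut <- function(s, k) { i <- sample(100, k); s[i] <- "W"; s }
  aln <- c(x1 = paste(base, collapse = ""),
           x2 = paste(mut(base, 1), collapse = ""),
           x3 = paste(mut(base, 2), collapse = ""),
           y1 = paste(far, collapse = ""),
           y2 = paste(mut(far, 1), collapse = ""),
           y3 = paste(mut(far, 2), collapse = ""))
  b1 <- bootstrapNJ(aln, nReps = 100, seed = 7)
  b2 <- bootstrapNJ(aln, nReps = 100, seed = 7)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  central <- paste(sort(c("y1", "y2", "y3")), collapse = ",")
  expect_true(central %in% names(b1$supports))
  expect_gte(b1$supports[[central]], 95)

  one <- bootstrapNJ(aln, nReps = 1, seed = 3)
  expect_true(all(one$supports %in% c(0, 1)))

  flat <- bootstrapNJ(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
                      nReps = 5, seed = 1)
  expect_true(flat$degenerate)
})

test_that("low-support clades can be collapsed to multifurcations", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- neighborJoining(D)
  boot <- list(tree = tr, nReps = 100,
               supports = setNames(2, treeBipartitions(tr)))
  ntip <- length(tr$tip.label)
  boot$tree$node.label <- rep("", tr$Nnode)
  sigs <- stressPrio:::.nodeSignatures(tr)
  boot$tree$node.label[!is.na(sigs)] <- "2"
  collapsed <- collapseLowSupport(boot, floor = 0.05)
  expect_equal(collapsed$Nnode, tr$Nnode - 1L)  # split contracted
})

test_that("Newick output round-trips and quotes awkward labels", {
  D <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- writeNewickTree(neighborJoining(D))
  expect_match(txt, "^\\(.*\\);$")
  expect_equal(sort(readNewickTree(txt)$tip.label), c("A", "B", "C"))

  q <- writeNewickTree(neighborJoining(
    `dimnames<-`(D, list(c("a b", "B", "C"), c("a b", "B", "C")))))
  expect_match(q, "'a b'", fixed = TRUE)
  expect_true("a b" %in% readNewickTree(q)$tip.label)

  for (seed in 1:20) {
    ra <- randomAdditive(4 + seed %% 4, seed + 100)
    tr <- neighborJoining(ra$D)
    back <- readNewickTree(writeNewickTree(tr))
    expect_setequal(treeBipartitions(back), treeBipartitions(tr))
    expect_equal(pathMetric(back), pathMetric(tr), tolerance = 1e-5)
  }
})
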