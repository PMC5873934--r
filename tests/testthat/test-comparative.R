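test_that("Venn partition assigns each gene to its membership region", {
  p <- vennPartition(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(p$regions[["A"]], "g1")
  expect_equal(p$regions[["B"]], "g3")
  expect_equal(p$regions[["A+B"]], "g2")

  same <- vennPartition(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(names(same$regions), "A+B")
  expect_equal(same$regions[["A+B"]], c("x", "y"))

  expect_error(vennPartition(list(c("a"), c("b"))), "labels")
  expect_error(vennPartition(list(A = "a")), "2 and 8")
  expect_error(vennPartition(setNames(list("a", "b"), c("A", "A"))),
               "unique")
})

test_that("partition regions are disjoint, exhaustive, and match a per-gene oracle", {
  for (seed in 1:6) {
    set.seed(seed)
    nSets <- sample(2:6, 1)
    labels <- LETTERS[seq_len(nSets)]
    sets <- lapply(setNames(labels, labels), function(l)
      sample(sprintf("g%02d", 1:50), sample(0:40, 1)))
    p <- vennPartition(sets)
    allGenes <- unlist(p$regions, use.names = FALSE)
    expect_equal(sort(allGenes), p$universe)       # exhaustive + disjoint
    expect_equal(anyDuplicated(allGenes), 0L)
    # per-gene bit-vector oracle
    for (g in p$universe) {
      member <- labels[vapply(sets, function(s) g %in% s, logical(1))]
      key <- paste(sort(member), collapse = "+")
      expect_true(g %in% p$regions[[key]])
    }
    counts <- vennCounts(p)
    expect_equal(nrow(counts), 2^nSets - 1)
    expect_equal(sum(counts$count), length(p$universe))
  }
})

test_that("multistress classes follow region breadth and conserve the focal set", {
  sets <- list(
    drought = c("Sb03g026070", "Sb09g030600", "Sb01g003880", "d_only"),
    salt = c("Sb03g026070", "Sb09g030600", "s1"),
    cold = c("Sb03g026070", "Sb09g030600", "s1"),
    heat = c("Sb03g026070", "Sb09g030600", "Sb01g003880"))
  p <- vennPartition(sets)
  cls <- multistressClassify(p, "drought")
  expect_equal(unname(cls["d_only"]), "specific")
  expect_equal(unname(cls["Sb01g003880"]), "dual")
  expect_equal(unname(cls["Sb03g026070"]), "universal")
  expect_equal(unname(cls["Sb09g030600"]), "universal")
  expect_equal(length(cls), length(sets$drought))
  expect_error(multistressClassify(p, "frost"), "unknown focal")

  for (seed in 1:4) {
    set.seed(seed)
    rsets <- lapply(setNames(1:4, c("a", "b", "c", "d")), function(i)
      sample(sprintf("g%02d", 1:30), sample(1:25, 1)))
    rp <- vennPartition(rsets)
    rcls <- multistressClassify(rp, "a")
    expect_equal(length(rcls), length(unique(rsets$a)))
  }
})

test_that("percentage reporting rounds half away from zero", {
  expect_equal(percentageReport(48, 169, 1), 28.4)
  expect_equal(percentageReport(84, 169, 1), 49.7)
  expect_equal(percentageReport(37, 169, 1), 21.9)
  expect_equal(percentageReport(169, 272, 0), 62)
  expect_equal(percentageReport(352, 1116, 0), 32)
  expect_equal(percentageReport(0, 10), 0)
  # exact .5 ties go away from zero, not to even
  expect_equal(percentageReport(25, 1000, 0), 3)
  expect_equal(percentageReport(125, 1000, 1), 12.5)
  expect_equal(percentageReport(1125, 10000, 1), 11.3)
  expect_error(percentageReport(1, 0), "positive")
  expect_error(percentageReport(-1, 10), "non-negative")
})

test_that("orthology classes are a bijection over the non-empty presence vectors", {
  expect_equal(orthologyClass(c(sorghum = FALSE, maize = TRUE, rice = TRUE,
                                arabidopsis = FALSE)), "SOMR")
  expect_equal(orthologyClass(c(sorghum = TRUE, maize = FALSE, rice = FALSE,
                                arabidopsis = FALSE)), "Sorghum")
  expect_equal(orthologyClass(c(sorghum = TRUE, maize = TRUE, rice = TRUE,
                                arabidopsis = TRUE)), "Sorghum_SOMRA")
  expect_error(orthologyClass(c(sorghum = FALSE, maize = FALSE,
                                rice = FALSE, arabidopsis = FALSE)),
               "at least one")

  tab <- orthologyClassTable()
  expect_equal(nrow(tab), 15L)
  expect_equal(anyDuplicated(tab$class), 0L)
  legend <- c("SOA", "SOM", "SOMA", "SOMR", "SOMRA", "SOR", "SORA",
              "Sorghum", "Sorghum_SOA", "Sorghum_SOMA", "Sorghum_SOMR",
              "Sorghum_SOMRA", "Sorghum_SOR", "Sorghum_SORA")
  expect_true(all(legend %in% tab$class))
})

test_that("Venn partitions serialize with stable region keys", {
  p <- vennPartition(list(B = c("g1", "g2"), A = c("g2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVennPartition(p, path)
  back <- utils::read.delim(path)
  expect_equal(back$count[back$region == "A+B"], 1L)
  expect_equal(sum(back$count), 2L)
})
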