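grFromDf <- function(df, idCol = "gene_id") {
  stressPrio:::.makeLocusGRanges(df$chrom, df$start, df$end,
                                 df[, idCol, drop = FALSE])
}

test_that("containment assigns genes falling within QTL regions", {
  qtls <- readQTLRegions(writeTempTsv(data.frame(
    qtl_id = c("QYLD1.2", "QX"), trait = c("grain yield", "x"),
    chrom = c("Chr 1", "chr1"), start = c(11145830, 1),
    end = c(12704841, 1000), ref = "ref048")))
  genes <- grFromDf(data.frame(
    gene_id = c("Sb01g012195", "offchrom"),
    chrom = c("chr1", "chr2"), start = c(11188494, 11188494),
    end = c(11188718, 11188718)))
  res <- colocalize(genes, qtls)
  expect_equal(res$assignments$gene_id, "Sb01g012195")
  expect_equal(res$assignments$qtl_id, "QYLD1.2")
  expect_equal(res$perQTL$count[res$perQTL$qtl_id == "QX"], 0L)
  expect_equal(res$uniqueGenes, 1L)
})

test_that("chromosome labels normalize consistently", {
  expect_equal(normalizeChrom(c("Chr 1", "CHR2", "3", "chr10")),
               c("chr1", "chr2", "chr3", "chr10"))
})

test_that("colocalization matches a brute-force all-pairs oracle", {
  set.seed(10)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:200),
    chrom = sample(paste0("chr", 1:3), 200, replace = TRUE),
    start = sample.int(1e5, 200))
  genes$end <- genes$start + sample.int(2000, 200)
  qtls <- data.frame(
    qtl_id = sprintf("q%02d", 1:20), trait = "t",
    chrom = sample(paste0("chr", 1:3), 20, replace = TRUE),
    start = sample.int(8e4, 20))
  qtls$end <- qtls$start + sample.int(4e4, 20)
  gGr <- grFromDf(genes)
  qGr <- stressPrio:::.makeLocusGRanges(qtls$chrom, qtls$start, qtls$end,
                                        qtls[c("qtl_id", "trait")])
  for (mode in c("containment", "overlap")) {
    res <- colocalize(gGr, qGr, mode = mode)
    brute <- do.call(rbind, lapply(seq_len(nrow(qtls)), function(i)
      do.call(rbind, lapply(seq_len(nrow(genes)), function(j) {
        hit <- genes$chrom[j] == qtls$chrom[i] &&
          (if (mode == "containment")
             qtls$start[i] <= genes$start[j] && genes$end[j] <= qtls$end[i]
           else genes$start[j] <= qtls$end[i] &&
             qtls$start[i] <= genes$end[j])
        if (hit) data.frame(qtl_id = qtls$qtl_id[i],
                            gene_id = genes$gene_id[j])
      }))))
    brute <- brute[order(brute$qtl_id, brute$gene_id), ]
    rownames(brute) <- NULL
    expect_equal(res$assignments[c("qtl_id", "gene_id")], brute)
  }
  # containment is a subset of overlap
  cont <- colocalize(gGr, qGr, "containment")$assignments
  over <- colocalize(gGr, qGr, "overlap")$assignments
  expect_true(all(paste(cont$qtl_id, cont$gene_id) %in%
                    paste(over$qtl_id, over$gene_id)))
})

test_that("best-hit selection follows the tie-break key and ignores row order", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q1", "q1", "q2", "q3"),
    subject_id = c("sB", "sA", "sC", "sD", "sX", "sY"),
    pct_identity = c(90, 95, 95, 95, 80, 99),
    aln_length = c(100, 100, 120, 100, 50, 60),
    evalue = c(1e-30, 1e-30, 1e-20, 1e-30, 1e-5, 1e-40),
    bit_score = c(200, 200, 200, 200, 40, 90))
  best <- bestHits(hits, evalueMax = 1e-10)
  # q1: equal bit scores; 1e-30 beats 1e-20; then identity 95 beats 90;
  # then subject sA beats sD lexicographically
  expect_equal(best$subject_id[best$query_id == "q1"], "sA")
  # q2 fails the e-value ceiling entirely
  expect_false("q2" %in% best$query_id)
  expect_equal(best$subject_id[best$query_id == "q3"], "sY")

  set.seed(20)
  for (i in 1:20) {
    perm <- hits[sample(nrow(hits)), ]
    expect_equal(bestHits(perm, 1e-10), best)
  }

  # bit score dominates everything else
  two <- data.frame(query_id = "q", subject_id = c("a", "b"),
                    pct_identity = c(99, 80), aln_length = c(500, 50),
                    evalue = c(1e-20, 1e-50), bit_score = c(100, 101))
  expect_equal(bestHits(two, 1)$subject_id, "b")
})

test_that("trait-category rollups conserve counts and percentages", {
  fx <- loadTable3Fixture()
  roll <- summarizeByTrait(fx$perQTL, fx$traitCategories)
  expect_equal(attr(roll, "total"), sum(fx$perQTL$count))
  expect_equal(sum(roll$count), attr(roll, "total"))

  one <- summarizeByTrait(data.frame(qtl_id = "q", trait = "grain yield",
                                     count = 5L),
                          fx$traitCategories)
  expect_equal(one$pct, 100)

  expect_warning(
    oth <- summarizeByTrait(data.frame(qtl_id = "q", trait = "mystery",
                                       count = 2L), fx$traitCategories),
    "unmapped")
  expect_equal(oth$category, "other")
})

test_that("locus readers convert coordinate conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tgeneX", bed)
  gr <- readGeneLoci(bed, format = "bed")
  expect_equal(GenomicRanges::start(gr), 100L)  # 0-based half-open -> 1-based
  expect_equal(GenomicRanges::end(gr), 200L)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneY"), gff)
  gr2 <- readGeneLoci(gff, format = "gff3")
  expect_equal(S4Vectors::mcols(gr2)$gene_id, "geneY")
  expect_equal(GenomicRanges::start(gr2), 100L)

  expect_error(readGeneLoci(writeTempTsv(data.frame(
    gene_id = "g", chrom = "chr1", start = 10, end = 5))), "coordinates")
  expect_error(readQTLRegions(writeTempTsv(data.frame(
    qtl_id = c("a", "a"), trait = "t", chrom = "chr1",
    start = 1, end = 10))), "duplicate")
})
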