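test_that("association TSVs load with dedup and prefix validation", {
  df <- data.frame(gene_id = c("g1", "g1", "g2"), species = "sorghum",
                   term_id = "GO:0000001", ontology_key = "GO")
  path <- writeTempTsv(df)
  expect_message(tab <- readAssociations(path), "1 exact-duplicate")
  expect_equal(nRecords(tab), 2L)

  empty <- writeTempTsv(df[0, ])
  expect_equal(nRecords(readAssociations(empty)), 0L)

  # a GRO association loads and is queryable by its term
  gro <- writeTempTsv(data.frame(gene_id = "Sb03g003110",
                                 species = "sorghum",
                                 term_id = "GRO:0007150",
                                 ontology_key = "GRO"))
  tab <- readAssociations(gro)
  r <- records(tab)
  expect_equal(r$gene_id[r$term_id == "GRO:0007150"], "Sb03g003110")

  # prefix mismatch: single bad row rejected with warning
  mixed <- writeTempTsv(data.frame(gene_id = c("g1", "g2"),
                                   species = "sorghum",
                                   term_id = c("GO:0000001", "TO:0000001"),
                                   ontology_key = "GO"))
  expect_warning(tab2 <- readAssociations(mixed), "prefix")
  expect_equal(nRecords(tab2), 1L)

  # >50% bad rows is a file-level error
  bad <- writeTempTsv(data.frame(gene_id = c("g1", "g2", "g3"),
                                 species = "sorghum",
                                 term_id = c("GO:0000001", "TO:0000001",
                                             "TO:0000002"),
                                 ontology_key = "GO"))
  expect_error(readAssociations(bad), "50%")
})

test_that("true-path propagation closes annotation sets upward", {
  g <- chainGraph()   # a is_a b is_a c
  reg <- list(GO = g)
  tab <- smallAssoc(data.frame(gene_id = "g1", term_id = "GO:0000001"))
  prop <- propagateAnnotations(tab, reg)
  expect_setequal(records(prop)$term_id,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_true(all(records(prop)$provenance == "direct"))

  # annotation to the root is a fixed point
  rootTab <- smallAssoc(data.frame(gene_id = "g1", term_id = "GO:0000003"))
  expect_equal(records(propagateAnnotations(rootTab, reg)),
               records(rootTab))

  # siblings under one parent: parent collects both genes
  d <- diamondGraph()
  sib <- smallAssoc(data.frame(gene_id = c("g1", "g2"),
                               term_id = c("GO:0000002", "GO:0000003")))
  prop2 <- propagateAnnotations(sib, list(GO = d))
  r <- records(prop2)
  expect_setequal(r$gene_id[r$term_id == "GO:0000004"], c("g1", "g2"))

  # unknown terms are dropped with a warning
  expect_warning(
    out <- propagateAnnotations(
      smallAssoc(data.frame(gene_id = "g1", term_id = "GO:7777777")), reg),
    "unknown")
  expect_equal(nRecords(out), 0L)
})

test_that("propagation is idempotent on random tables", {
  for (seed in 1:4) {
    g <- randomDagGraph(15L, seed)
    set.seed(seed)
    n <- 60L
    tab <- smallAssoc(data.frame(
      gene_id = sample(sprintf("g%02d", 1:10), n, replace = TRUE),
      term_id = sample(termIds(g), n, replace = TRUE)))
    p1 <- propagateAnnotations(tab, list(GO = g))
    p2 <- propagateAnnotations(p1, list(GO = g))
    expect_equal(records(p2), records(p1))
    expect_gte(nRecords(p1), nRecords(tab))
  }
})

test_that("genesForTerms collects genes via closure with provenance", {
  g <- chainGraph()
  reg <- list(GO = g)
  ts <- buildTermSet(g, "GO:0000002", "mid")  # members: b and its child a
  tab <- propagateAnnotations(
    smallAssoc(data.frame(gene_id = "g1", term_id = "GO:0000001")), reg)
  hits <- genesForTerms(tab, ts, "sorghum")
  expect_equal(hits$gene_id, "g1")  # annotated only to a descendant
  expect_true(hits$direct)

  none <- genesForTerms(tab, buildTermSet(g, "GO:0000003",
                                          closure = FALSE), "maize")
  expect_equal(nrow(none), 0L)

  expect_error(genesForTerms(tab, new("TermSet", ontologyKey = "GO",
                                      seedIds = character(),
                                      memberIds = character(), label = ""),
                             "sorghum"),
               "empty term set")
})

test_that("ortholog transfer adds transitive records without touching direct ones", {
  g <- parseOBO(oboStanza("EO:0007404", "drought environment"))
  reg <- list(EO = g)
  ts <- buildTermSet(g, "EO:0007404", "drought")
  base <- smallAssoc(data.frame(gene_id = "r1", species = "rice",
                                term_id = "EO:0007404"))
  orth <- orthologMap(data.frame(species_a = "rice", gene_a = "r1",
                                 species_b = "sorghum", gene_b = "s1"))
  res <- transferTransitive(base, orth, "sorghum", ts)
  r <- records(res$table)
  new <- r[r$species == "sorghum", ]
  expect_equal(new$gene_id, "s1")
  expect_equal(new$term_id, "EO:0007404")
  expect_equal(new$provenance, "transitive")
  expect_equal(new$source_species, "rice")
  expect_equal(new$source_gene, "r1")
  expect_equal(unname(res$summary["n_transitive"]), 1L)

  # no orthologs: unchanged
  noOrth <- orthologMap(data.frame(species_a = character(),
                                   gene_a = character(),
                                   species_b = character(),
                                   gene_b = character()))
  expect_equal(nRecords(transferTransitive(base, noOrth, "sorghum",
                                           ts)$table),
               nRecords(base))
})

test_that("direct association takes precedence over transitive transfer", {
  g <- parseOBO(c(oboStanza("EO:0007404"), oboStanza("EO:0007048")))
  ts <- buildTermSet(g, c("EO:0007404", "EO:0007048"), "stress")
  orth <- orthologMap(data.frame(species_a = "rice", gene_a = "r1",
                                 species_b = "sorghum", gene_b = "s1"))
  # enumerate 2-gene scenarios: s1 direct to one, both, or neither member term
  for (directTerms in list(character(), "EO:0007404",
                           c("EO:0007404", "EO:0007048"))) {
    rows <- data.frame(gene_id = "r1", species = "rice",
                       term_id = c("EO:0007404", "EO:0007048"))
    if (length(directTerms))
      rows <- rbind(rows, data.frame(gene_id = "s1", species = "sorghum",
                                     term_id = directTerms))
    tab <- smallAssoc(rows)
    res <- transferTransitive(tab, orth, "sorghum", ts)
    r <- records(res$table)
    nDirectBefore <- sum(records(tab)$provenance == "direct")
    expect_equal(sum(r$provenance == "direct"), nDirectBefore)
    if (length(directTerms)) {
      # any direct support for the set blocks all transfer for the set
      expect_equal(sum(r$provenance == "transitive"), 0L)
      expect_equal(unname(res$summary["n_direct"]), 1L)
    } else {
      expect_equal(sum(r$provenance == "transitive"), 2L)
    }
    # transfer never removes records
    expect_gte(nrow(r), nrow(records(tab)))
  }
})
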