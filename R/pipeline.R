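#' Read a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent named list) declaring
#' input paths, term-set seeds and thresholds. Recognised fields:
#' \describe{
#'   \item{ontologies}{named map ontology key -> OBO path.}
#'   \item{associations, orthologs}{association / ortholog TSV paths.}
#'   \item{term_sets}{named map group key -> list(seeds, label).}
#'   \item{target_species}{species being screened (default "sorghum").}
#'   \item{expression}{list(values, meta, contrast = c(attr, levelA, levelB)).}
#'   \item{stress_sets}{named map stress label -> gene-list file (one gene
#'     per line), for the cross-stress partition.}
#'   \item{qtls, gene_loci}{QTL table and gene-locus TSV paths.}
#'   \item{alignment}{aligned FASTA for the phylogeny stage.}
#'   \item{thresholds}{screen_alpha (default 0.01), attribute_alpha (0.05),
#'     de_alpha (0.01), fold (2), evalue_max (1e-10).}
#'   \item{integration}{"intersection" (default) or "union" of screened and
#'     up-regulated genes.}
#'   \item{output_dir, seed}{output directory and RNG seed.}
#' }
#'
#' @param path YAML file path.
#' @return named list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.config_path <- path
  .fillConfigDefaults(cfg)
}

.fillConfigDefaults <- function(cfg) {
  th <- cfg$thresholds
  cfg$thresholds <- list(
    screen_alpha = if (!is.null(th$screen_alpha)) th$screen_alpha else 0.01,
    attribute_alpha = if (!is.null(th$attribute_alpha)) th$attribute_alpha
                      else 0.05,
    de_alpha = if (!is.null(th$de_alpha)) th$de_alpha else 0.01,
    fold = if (!is.null(th$fold)) th$fold else 2,
    evalue_max = if (!is.null(th$evalue_max)) th$evalue_max else 1e-10)
  for (a in c("screen_alpha", "attribute_alpha", "de_alpha"))
    if (cfg$thresholds[[a]] <= 0 || cfg$thresholds[[a]] > 1)
      stop("threshold ", a, " must lie in (0, 1]")
  if (cfg$thresholds$fold < 1) stop("fold threshold must be >= 1")
  if (is.null(cfg$target_species)) cfg$target_species <- "sorghum"
  if (is.null(cfg$integration)) cfg$integration <- "intersection"
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

.cfgPath <- function(cfg, p) {
  if (is.null(p) || file.exists(p)) return(p)
  base <- cfg$.config_path
  if (!is.null(base)) {
    cand <- file.path(dirname(base), p)
    if (file.exists(cand)) return(cand)
  }
  stop("input file not found: ", p)
}

.writeTsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the screening pipeline end to end
#'
#' Executes, for every stage whose inputs the configuration declares:
#' ontology screening (per-ontology collection, merge, all-ontology filter),
#' the enrichment gate, the cross-stress Venn partition, differential
#' expression and its integration with the screened candidates (intersection
#' by default), QTL co-localization, and optionally a bootstrapped NJ
#' phylogeny. Stage outputs are written as TSV/Newick files under the output
#' directory together with a JSON run manifest recording the seed, the
#' configuration checksum and per-stage record counts. Reruns with identical
#' inputs and seed reproduce identical outputs.
#'
#' @param config a configuration list or the path to a YAML file
#'   (see [readPipelineConfig()]).
#' @param outputDir overrides the configuration's output directory.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else .fillConfigDefaults(config)
  dir <- if (!is.null(outputDir)) outputDir else cfg$output_dir
  if (is.null(dir)) stop("no output directory configured")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "stressPrio",
                   version = as.character(utils::packageVersion("stressPrio")),
                   seed = cfg$seed, stages = list())
  if (!is.null(cfg$.config_path))
    manifest$config_md5 <- unname(tools::md5sum(cfg$.config_path))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  candidates <- NULL

  if (!is.null(cfg$ontologies) && !is.null(cfg$associations) &&
      !is.null(cfg$term_sets)) {
    stage("screen", {
      registry <- lapply(cfg$ontologies, function(p)
        parseOBO(.cfgPath(cfg, p)))
      assoc <- propagateAnnotations(
        readAssociations(.cfgPath(cfg, cfg$associations)), registry)
      orth <- if (!is.null(cfg$orthologs))
        readOrthologs(.cfgPath(cfg, cfg$orthologs))
      else orthologMap(data.frame(species_a = character(),
                                  gene_a = character(),
                                  species_b = character(),
                                  gene_b = character()))
      termSets <- lapply(names(cfg$term_sets), function(k)
        buildTermSet(registry[[k]], unlist(cfg$term_sets[[k]]$seeds),
                     label = cfg$term_sets[[k]]$label %||% k))
      names(termSets) <- names(cfg$term_sets)
      collected <- collectPerOntology(assoc, orth, termSets,
                                      cfg$target_species)
      merged <- mergeUnique(collected$sets)
      passed <- allOntologyFilter(collected$matrix, names(termSets))
      writeSupportMatrix(collected$matrix,
                         file.path(dir, "support_matrix.tsv"))
      .writeTsv(screenReport(collected), dir, "screen_report.tsv")
      .writeTsv(merged, dir, "merged_candidates.tsv")
      enr <- enrichTerms(if (length(passed)) passed else merged$gene_id,
                         assoc, cfg$target_species, registry = registry,
                         alpha = cfg$thresholds$screen_alpha, correct = TRUE)
      .writeTsv(enr, dir, "enrichment.tsv")
      sig <- significantTerms(enr)
      r <- records(assoc)
      gated <- sort(intersect(
        if (length(passed)) passed else merged$gene_id,
        r$gene_id[r$term_id %in% sig$term_id]))
      writeLines(gated, file.path(dir, "screened_genes.txt"))
      candidates <- gated
      manifest$stages$screen <- list(
        status = "ok", merged = nrow(merged),
        all_ontology_pass = length(passed),
        enriched_terms = nrow(sig), screened_genes = length(gated))
    })
  }

  if (!is.null(cfg$stress_sets)) {
    stage("venn", {
      sets <- lapply(cfg$stress_sets, function(p)
        readLines(.cfgPath(cfg, p)))
      part <- vennPartition(sets)
      writeVennPartition(part, file.path(dir, "stress_partition.tsv"))
      manifest$stages$venn <- list(status = "ok",
                                    universe = length(part$universe))
    })
  }

  if (!is.null(cfg$expression)) {
    stage("de", {
      se <- readExpression(.cfgPath(cfg, cfg$expression$values),
                           .cfgPath(cfg, cfg$expression$meta))
      de <- runDE(se, unlist(cfg$expression$contrast),
                  alpha = cfg$thresholds$de_alpha,
                  foldThreshold = cfg$thresholds$fold)
      .writeTsv(de, dir, "de_results.tsv")
      up <- de$gene_id[de$class == "up"]
      manifest$stages$de <- list(status = "ok", genes = nrow(de),
                                  up = length(up),
                                  down = sum(de$class == "down"))
      if (!is.null(candidates)) {
        integrated <- if (cfg$integration == "union")
          sort(union(candidates, up)) else sort(intersect(candidates, up))
        writeLines(integrated, file.path(dir, "integrated_candidates.txt"))
        manifest$stages$integration <- list(status = "ok",
                                             mode = cfg$integration,
                                             genes = length(integrated))
      }
    })
  }

  if (!is.null(cfg$qtls) && !is.null(cfg$gene_loci)) {
    stage("colocalize", {
      qtls <- readQTLRegions(.cfgPath(cfg, cfg$qtls))
      genes <- readGeneLoci(.cfgPath(cfg, cfg$gene_loci))
      res <- colocalize(genes, qtls)
      .writeTsv(res$assignments, dir, "qtl_assignments.tsv")
      .writeTsv(res$perQTL, dir, "qtl_counts.tsv")
      manifest$stages$colocalize <- list(status = "ok",
                                          assignments = res$total,
                                          unique_genes = res$uniqueGenes)
    })
  }

  if (!is.null(cfg$alignment)) {
    stage("phylo", {
      if (!requireNamespace("Biostrings", quietly = TRUE))
        stop("the phylo stage needs the Biostrings package to read FASTA")
      aln <- Biostrings::readAAStringSet(.cfgPath(cfg, cfg$alignment))
      boot <- bootstrapNJ(setNames(as.character(aln), names(aln)),
                          nReps = cfg$bootstrap_reps %||% 100L,
                          seed = cfg$seed)
      writeNewickTree(boot$tree, file.path(dir, "tree.nwk"))
      manifest$stages$phylo <- list(status = "ok",
                                     taxa = length(aln),
                                     reps = boot$nReps)
    })
  }

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a self-contained simulated input directory
#'
#' Emits a complete set of pipeline inputs generated by the synthetic-data
#' module — an OBO ontology, association and ortholog snapshots, an
#' expression matrix with metadata, QTL and gene-locus tables — together with
#' a ground-truth manifest (`truth.json`) and a ready-to-run `config.yaml`.
#'
#' @param dir output directory (created if needed).
#' @param seed global seed; each generator draws from a derived substream.
#' @param nGenes,studySize,nPlantedDE scale knobs passed to the generators.
#' @return the directory path, invisibly.
#' @export
writeSimulationDirectory <- function(dir, seed = 1L, nGenes = 400L,
                                     studySize = 40L, nPlantedDE = 30L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obo <- simulateOntology(60L, key = "GO",
                          seed = deriveSeed(seed, "ontology"))
  writeLines(obo, file.path(dir, "ontology.obo"))
  graph <- parseOBO(obo)
  sim <- simulateAssociations(graph, nGenes = nGenes, studySize = studySize,
                              planted = list(studyCover = round(0.8 * studySize),
                                             backgroundCover = round(0.1 * nGenes)),
                              seed = deriveSeed(seed, "associations"))
  .writeTsv(records(sim$assoc)[c("gene_id", "species", "term_id",
                                 "ontology_key")], dir, "associations.tsv")
  .writeTsv(data.frame(species_a = "sorghum", gene_a = sim$study,
                       species_b = "rice",
                       gene_b = paste0("os_", sim$study)),
            dir, "orthologs.tsv")
  expr <- simulateExpression(nGenes = nGenes, nPlanted = nPlantedDE,
                             seed = deriveSeed(seed, "expression"))
  vals <- SummarizedExperiment::assay(expr$se, "expr")
  # reuse the association gene ids so DE integrates with screening
  rownames(vals) <- sprintf("g%05d", seq_len(nGenes))
  .writeTsv(data.frame(gene_id = rownames(vals), vals, check.names = FALSE),
            dir, "expression.tsv")
  .writeTsv(as.data.frame(SummarizedExperiment::colData(expr$se)),
            dir, "samples.tsv")
  qtl <- simulateQTLScenario(seed = deriveSeed(seed, "qtl"))
  .writeTsv(data.frame(qtl_id = GenomicRanges::mcols(qtl$qtls)$qtl_id,
                       trait = GenomicRanges::mcols(qtl$qtls)$trait,
                       chrom = as.character(GenomicRanges::seqnames(qtl$qtls)),
                       start = GenomicRanges::start(qtl$qtls),
                       end = GenomicRanges::end(qtl$qtls),
                       ref = GenomicRanges::mcols(qtl$qtls)$ref),
            dir, "qtls.tsv")
  .writeTsv(data.frame(gene_id = GenomicRanges::mcols(qtl$genes)$gene_id,
                       chrom = as.character(GenomicRanges::seqnames(qtl$genes)),
                       start = GenomicRanges::start(qtl$genes),
                       end = GenomicRanges::end(qtl$genes)),
            dir, "gene_loci.tsv")
  truth <- list(
    planted_term = sim$planted$term,
    study_genes = sim$study,
    planted_de_genes = sprintf("g%05d", seq_len(nPlantedDE)),
    qtl_assignments = qtl$truth,
    n_qtl_assignments = nrow(qtl$truth))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- list(
    ontologies = list(GO = "ontology.obo"),
    associations = "associations.tsv",
    orthologs = "orthologs.tsv",
    term_sets = list(GO = list(seeds = list(sim$planted$term),
                               label = "planted stress")),
    target_species = "sorghum",
    expression = list(values = "expression.tsv", meta = "samples.tsv",
                      contrast = list("treatment", "stress", "control")),
    qtls = "qtls.tsv",
    gene_loci = "gene_loci.tsv",
    output_dir = "out",
    seed = seed)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
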