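# Seeded synthetic inputs with the statistical structure the pipeline
# assumes, plus the packaged drought-QTL fixture. Every generator is a pure
# function of its arguments and seed: the caller's RNG state is saved and
# restored, and one global seed fans out to per-generator substreams so
# adding a generator never perturbs existing fixtures.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a per-generator substream seed
#'
#' Maps a global seed and a stream label to a deterministic 31-bit seed, so
#' each generator draws from its own substream.
#'
#' @param seed global integer seed.
#' @param stream label of the substream, e.g. "expression".
#' @return a positive integer below 2^31.
#' @export
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483629 + 1)
}

#' Generate a random acyclic ontology as OBO text
#'
#' Terms are created in index order and each non-root term draws its parents
#' among earlier terms, so the output is acyclic by construction and parses
#' through [parseOBO()].
#'
#' @param nTerms number of terms.
#' @param key ontology key (GO/TO/PO/GRO/EO), used as the accession prefix.
#' @param maxParents maximum parents per term (default 2); `maxParents = 0`
#'   with `nRoots = 1` yields a star when combined with depth-1 chains.
#' @param nRoots number of parentless terms (default 1).
#' @param seed integer seed.
#' @return character vector of OBO lines.
#' @export
simulateOntology <- function(nTerms, key = "GO", maxParents = 2L,
                             nRoots = 1L, seed = 1L) {
  stopifnot(nTerms >= 1L, nRoots >= 1L, nRoots <= nTerms)
  ids <- sprintf("%s:%07d", key, seq_len(nTerms))
  .withSeed(seed, {
    lines <- character()
    for (i in seq_len(nTerms)) {
      stanza <- c("[Term]", paste0("id: ", ids[i]),
                  paste0("name: synthetic term ", i))
      if (i > nRoots && maxParents > 0L) {
        k <- sample.int(min(maxParents, i - 1L), 1L)
        par <- sample(ids[seq_len(i - 1L)], k)
        stanza <- c(stanza, paste0("is_a: ", par))
      }
      lines <- c(lines, stanza, "")
    }
    lines
  })
}

#' Generate gene-term associations with a planted enrichment
#'
#' Builds an association snapshot over `nGenes` genes of the target species:
#' every gene is annotated to the graph's first term (so the background
#' universe is exactly `nGenes`), each gene receives `density` further random
#' terms, and the planted term is assigned to exactly
#' `planted$backgroundCover` genes of which exactly `planted$studyCover`
#' belong to the study set (counts, not probabilities). A fraction
#' `transitiveFraction` of the target species' genes have their annotations
#' rerouted through a named ortholog in `sourceSpecies` — the gene itself
#' keeps no direct record and becomes reachable only transitively, with the
#' ortholog pair emitted in the ortholog map.
#'
#' @param graph an [OntologyGraph] supplying the term vocabulary.
#' @param nGenes background size.
#' @param studySize study-set size (the first `studySize` genes).
#' @param planted list with `term` (defaults to the graph's last term),
#'   `studyCover`, `backgroundCover`.
#' @param density mean random annotations per gene (default 2).
#' @param species target species (default "sorghum").
#' @param sourceSpecies ortholog source species (default "rice").
#' @param transitiveFraction fraction of genes reachable only transitively.
#' @param seed integer seed.
#' @return list with `assoc` (an [AssociationTable]), `orthologs` (an
#'   [OrthologMap]), `study` (study gene ids), `planted` (the realized spec).
#' @export
simulateAssociations <- function(graph, nGenes = 1000L, studySize = 50L,
                                 planted = list(studyCover = 40L,
                                                backgroundCover = 100L),
                                 density = 2, species = "sorghum",
                                 sourceSpecies = "rice",
                                 transitiveFraction = 0, seed = 1L) {
  ids <- termIds(graph)
  key <- ontologyKey(graph)
  if (is.null(planted$term)) planted$term <- ids[length(ids)]
  if (planted$studyCover > studySize ||
      planted$backgroundCover > nGenes ||
      planted$studyCover > planted$backgroundCover)
    stop("infeasible planted coverage counts")
  genes <- sprintf("g%05d", seq_len(nGenes))
  study <- genes[seq_len(studySize)]
  .withSeed(seed, {
    rec <- data.frame(gene_id = genes, term_id = ids[1],
                      stringsAsFactors = FALSE)
    nExtra <- stats::rpois(nGenes, density)
    pool <- setdiff(ids, planted$term)
    extra <- data.frame(
      gene_id = rep(genes, nExtra),
      term_id = sample(pool, sum(nExtra), replace = TRUE),
      stringsAsFactors = FALSE)  # duplicate draws collapse on load
    inStudy <- sample(study, planted$studyCover)
    outStudy <- sample(setdiff(genes, study),
                       planted$backgroundCover - planted$studyCover)
    rec <- rbind(rec, extra,
                 data.frame(gene_id = c(inStudy, outStudy),
                            term_id = planted$term,
                            stringsAsFactors = FALSE))
    rec$species <- species
    rec$ontology_key <- key
    orth <- data.frame(species_a = character(), gene_a = character(),
                       species_b = character(), gene_b = character(),
                       stringsAsFactors = FALSE)
    if (transitiveFraction > 0) {
      nT <- round(transitiveFraction * nGenes)
      tGenes <- sample(genes, nT)
      reroute <- rec$gene_id %in% tGenes
      srcGene <- paste0("src_", rec$gene_id)
      rec$gene_id[reroute] <- srcGene[reroute]
      rec$species[reroute] <- sourceSpecies
      orth <- data.frame(species_a = species, gene_a = tGenes,
                         species_b = sourceSpecies,
                         gene_b = paste0("src_", tGenes),
                         stringsAsFactors = FALSE)
    }
    list(assoc = associationTable(rec), orthologs = orthologMap(orth),
         study = study, planted = planted)
  })
}

#' Generate a two-group expression matrix with planted up-regulation
#'
#' Emulates an RPKM-like two-condition design: per-gene baselines on the
#' log2 scale, Gaussian noise (sd `noiseSd`) added per sample, a planted
#' log2 fold change added to the stress group of the first `nPlanted` genes,
#' and the result exponentiated to the linear scale.
#'
#' @param nGenes number of genes.
#' @param nPlanted number of planted up-regulated genes.
#' @param log2fc planted effect on the log2 scale.
#' @param noiseSd per-sample Gaussian noise sd on the log2 scale.
#' @param nPerGroup samples per condition (>= 2).
#' @param baselineLog2 range of per-gene baseline log2 expression.
#' @param seed integer seed.
#' @return list with `se` (a SummarizedExperiment, see
#'   [makeExpressionSet()]) and `truth` (planted gene ids).
#' @export
simulateExpression <- function(nGenes = 1000L, nPlanted = 50L, log2fc = 3,
                               noiseSd = 1, nPerGroup = 5L,
                               baselineLog2 = c(4, 8), seed = 1L) {
  if (nPerGroup < 2L) stop("need at least 2 samples per group")
  if (nPlanted > nGenes) stop("nPlanted exceeds nGenes")
  genes <- sprintf("gene%05d", seq_len(nGenes))
  samples <- c(paste0("ctl", seq_len(nPerGroup)),
               paste0("str", seq_len(nPerGroup)))
  treatment <- rep(c("control", "stress"), each = nPerGroup)
  .withSeed(seed, {
    base <- stats::runif(nGenes, baselineLog2[1], baselineLog2[2])
    lfc <- c(rep(log2fc, nPlanted), rep(0, nGenes - nPlanted))
    mu <- outer(base, rep(0, 2 * nPerGroup), "+") +
      outer(lfc, as.numeric(treatment == "stress"))
    vals <- 2^(mu + matrix(stats::rnorm(nGenes * 2 * nPerGroup, 0, noiseSd),
                           nGenes, 2 * nPerGroup))
    dimnames(vals) <- list(genes, samples)
    meta <- data.frame(sample_id = samples, tissue = "leaf",
                       treatment = treatment, genotype = "wt",
                       stringsAsFactors = FALSE)
    list(se = makeExpressionSet(vals, meta),
         truth = genes[seq_len(nPlanted)])
  })
}

#' Generate a QTL co-localization scenario with known ground truth
#'
#' Places non-overlapping QTLs on the given chromosomes, then genes strictly
#' inside each QTL, genes outside every QTL, and optionally genes straddling
#' a QTL boundary (contained under overlap mode only).
#'
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param nQTL number of QTL regions.
#' @param genesPerQTL genes planted strictly inside each QTL.
#' @param genesOutside genes planted outside every QTL.
#' @param genesStraddling genes straddling a QTL boundary.
#' @param seed integer seed.
#' @return list with `qtls` and `genes` (GRanges) and `truth` (data.frame of
#'   expected containment-mode assignments `qtl_id`, `gene_id`).
#' @export
simulateQTLScenario <- function(chromLengths = c(chr1 = 1e6, chr2 = 1e6),
                                nQTL = 4L, genesPerQTL = 3L,
                                genesOutside = 10L, genesStraddling = 0L,
                                seed = 1L) {
  .withSeed(seed, {
    maxSlots <- max(1, ceiling(nQTL / length(chromLengths)))
    qtlWidth <- floor(min(chromLengths) / (2 * maxSlots + 1))
    if (qtlWidth < 100L) stop("QTLs do not fit on the chromosomes")
    chrom <- rep(names(chromLengths), length.out = nQTL)
    slot <- stats::ave(seq_len(nQTL), chrom, FUN = seq_along)
    qstart <- (slot - 1) * 2 * qtlWidth + 1
    qend <- qstart + qtlWidth - 1
    if (any(qend > chromLengths[chrom]))
      stop("QTL longer than chromosome")
    qtl_id <- sprintf("QTL%02d", seq_len(nQTL))
    qtls <- .makeLocusGRanges(chrom, qstart, qend,
                              data.frame(qtl_id = qtl_id,
                                         trait = "synthetic trait",
                                         ref = "synthetic",
                                         stringsAsFactors = FALSE))
    geneW <- 50L
    gid <- 0L
    rows <- list(); truth <- list()
    for (q in seq_len(nQTL)) for (g in seq_len(genesPerQTL)) {
      gid <- gid + 1L
      s <- qstart[q] + sample.int(qtlWidth - 2L * geneW, 1L)
      rows[[gid]] <- data.frame(gene_id = sprintf("syn%04d", gid),
                                chrom = chrom[q], start = s,
                                end = s + geneW, stringsAsFactors = FALSE)
      truth[[gid]] <- data.frame(qtl_id = qtl_id[q],
                                 gene_id = sprintf("syn%04d", gid),
                                 stringsAsFactors = FALSE)
    }
    for (g in seq_len(genesOutside)) {
      gid <- gid + 1L
      ch <- sample(names(chromLengths), 1L)
      nOn <- sum(chrom == ch)
      s <- nOn * 2 * qtlWidth + sample.int(
        max(1, chromLengths[[ch]] - nOn * 2 * qtlWidth - 2 * geneW), 1L)
      rows[[gid]] <- data.frame(gene_id = sprintf("syn%04d", gid),
                                chrom = ch, start = s, end = s + geneW,
                                stringsAsFactors = FALSE)
    }
    if (genesStraddling > 0L) for (g in seq_len(genesStraddling)) {
      gid <- gid + 1L
      q <- sample.int(nQTL, 1L)
      rows[[gid]] <- data.frame(gene_id = sprintf("syn%04d", gid),
                                chrom = chrom[q],
                                start = qend[q] - geneW, end = qend[q] + geneW,
                                stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    genes <- .makeLocusGRanges(df$chrom, df$start, df$end,
                               data.frame(gene_id = df$gene_id,
                                          stringsAsFactors = FALSE))
    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(qtl_id = character(), gene_id = character())
    truthDf <- truthDf[order(truthDf$qtl_id, truthDf$gene_id), , drop = FALSE]
    rownames(truthDf) <- NULL
    list(qtls = qtls, genes = genes, truth = truthDf)
  })
}

#' Load the packaged sorghum drought-QTL fixture
#'
#' The 22 published sorghum drought-tolerance QTL regions with, for each, the
#' representative co-localized gene locus and the number of candidate genes
#' found in the region (`total`). Four representative end coordinates whose
#' leading digits were truncated in the printed source are editorially
#' restored and flagged (`corrected`). The trait-category map groups the QTL
#' traits into seed dormancy, yield-related (grain yield, stay-green,
#' flowering time) and drought adaptation (shoot/root dry weight, nodal root
#' angle, total leaf area).
#'
#' @return list with `qtls` (GRanges: qtl_id, trait, ref, total), `genes`
#'   (GRanges: gene_id, qtl_id, corrected), `perQTL` (data.frame qtl_id,
#'   trait, count) and `traitCategories` (named character vector).
#' @export
loadTable3Fixture <- function() {
  qf <- system.file("extdata", "table3_qtls.tsv", package = "stressPrio",
                    mustWork = TRUE)
  gf <- system.file("extdata", "table3_genes.tsv", package = "stressPrio",
                    mustWork = TRUE)
  qdf <- utils::read.delim(qf, comment.char = "#", stringsAsFactors = FALSE)
  gdf <- utils::read.delim(gf, comment.char = "#", stringsAsFactors = FALSE)
  qtls <- .makeLocusGRanges(qdf$chrom, qdf$start, qdf$end,
                            data.frame(qtl_id = qdf$qtl_id,
                                       trait = qdf$trait, ref = qdf$ref,
                                       total = qdf$total,
                                       stringsAsFactors = FALSE))
  genes <- .makeLocusGRanges(gdf$chrom, gdf$start, gdf$end,
                             data.frame(gene_id = gdf$gene_id,
                                        qtl_id = gdf$qtl_id,
                                        corrected = gdf$corrected == "yes",
                                        stringsAsFactors = FALSE))
  traitCategories <- c(
    "seed dormancy" = "seed dormancy",
    "grain yield" = "yield-related",
    "stay-green" = "yield-related",
    "flowering time" = "yield-related",
    "shoot dry weight" = "drought adaptation",
    "root dry weight" = "drought adaptation",
    "nodal root angle" = "drought adaptation",
    "total leaf area" = "drought adaptation")
  list(qtls = qtls, genes = genes,
       perQTL = data.frame(qtl_id = qdf$qtl_id, trait = qdf$trait,
                           count = qdf$total, stringsAsFactors = FALSE),
       traitCategories = traitCategories)
}
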