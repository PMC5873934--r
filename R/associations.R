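#' Gene-term association table
#'
#' One row per (gene, species, term, provenance) link. Provenance is either
#' \code{"direct"} (the species' own annotation) or \code{"transitive"}
#' (transferred from an ortholog; \code{source_species}/\code{source_gene}
#' then record where it came from). Construct with [readAssociations()] or
#' [associationTable()].
#'
#' @slot records data.frame with columns \code{gene_id}, \code{species},
#'   \code{term_id}, \code{ontology_key}, \code{provenance},
#'   \code{source_species}, \code{source_gene}, \code{evidence}.
#' @export
setClass("AssociationTable", representation(records = "data.frame"))

ASSOC_COLS <- c("gene_id", "species", "term_id", "ontology_key",
                "provenance", "source_species", "source_gene", "evidence")

setValidity("AssociationTable", function(object) {
  r <- object@records
  msgs <- character()
  if (!all(ASSOC_COLS %in% names(r)))
    msgs <- c(msgs, "missing record columns")
  else {
    if (!all(r$provenance %in% c("direct", "transitive")))
      msgs <- c(msgs, "provenance must be direct or transitive")
    tr <- r$provenance == "transitive"
    if (any(tr & (is.na(r$source_species) |
                  r$source_species == r$species)))
      msgs <- c(msgs, "transitive records need a source_species != species")
    key <- do.call(paste, c(r[c("gene_id", "species", "term_id",
                                "provenance", "source_species",
                                "source_gene")], sep = "\r"))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate records")
  }
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "AssociationTable", function(object) {
  r <- object@records
  cat("AssociationTable: ", nrow(r), " records, ",
      length(unique(r$gene_id)), " genes, ",
      length(unique(r$term_id)), " terms (",
      sum(r$provenance == "direct"), " direct / ",
      sum(r$provenance == "transitive"), " transitive)\n", sep = "")
})

.emptyRecords <- function() {
  data.frame(gene_id = character(), species = character(),
             term_id = character(), ontology_key = character(),
             provenance = character(), source_species = character(),
             source_gene = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

.dedupRecords <- function(r) {
  r[!duplicated(do.call(paste, c(r[c("gene_id", "species", "term_id",
                                     "provenance", "source_species",
                                     "source_gene")], sep = "\r"))), ,
    drop = FALSE]
}

#' Construct an AssociationTable from a data.frame
#'
#' Species names are normalised to lowercase; gene ids are opaque,
#' case-sensitive strings. Exact duplicates are collapsed.
#'
#' @param records data.frame with at least \code{gene_id}, \code{species},
#'   \code{term_id}, \code{ontology_key}; optional provenance columns and
#'   \code{evidence}.
#' @return an [AssociationTable].
#' @export
associationTable <- function(records = .emptyRecords()) {
  for (col in ASSOC_COLS)
    if (!col %in% names(records))
      records[[col]] <- rep(if (col == "provenance") "direct"
                            else NA_character_, nrow(records))
  records$species <- tolower(records$species)
  records$source_species <- tolower(records$source_species)
  records <- .dedupRecords(records[ASSOC_COLS])
  rownames(records) <- NULL
  new("AssociationTable", records = records)
}

#' @rdname AssociationTable-accessors
#' @param x an AssociationTable.
#' @export
records <- function(x) x@records

#' Accessors for AssociationTable
#'
#' @name AssociationTable-accessors
#' @return `records()` the record data.frame; `nRecords()` the row count;
#'   `assocGenes()` the unique gene ids, optionally restricted to a species.
#' @export
nRecords <- function(x) nrow(x@records)

#' @rdname AssociationTable-accessors
#' @param species optional species filter (lowercase token).
#' @export
assocGenes <- function(x, species = NULL) {
  r <- x@records
  if (!is.null(species)) r <- r[r$species == tolower(species), , drop = FALSE]
  sort(unique(r$gene_id))
}

#' Read a GAF-like association TSV
#'
#' Expected tab-separated columns: \code{gene_id}, \code{species},
#' \code{term_id}, \code{ontology_key} and optionally \code{evidence};
#' \code{#} lines are comments. Rows whose accession prefix does not match
#' their \code{ontology_key} are rejected with a warning; if more than half
#' the rows are rejected the whole file errors. Exact duplicates are
#' collapsed (count reported via message).
#'
#' @param path path to the TSV file.
#' @return an [AssociationTable] with all-direct provenance.
#' @export
readAssociations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "species", "term_id", "ontology_key")
  if (!all(need %in% names(df)))
    stop("association file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df)) {
    prefixOk <- sub(":.*$", "", df$term_id) == df$ontology_key &
      .validTermId(df$term_id)
    if (any(!prefixOk)) {
      if (mean(!prefixOk) > 0.5)
        stop("more than 50% of association rows have term/ontology ",
             "prefix mismatches")
      warning(sum(!prefixOk), " row(s) rejected: term accession prefix ",
              "does not match ontology_key")
      df <- df[prefixOk, , drop = FALSE]
    }
  }
  n0 <- nrow(df)
  tab <- associationTable(df)
  if (nRecords(tab) < n0)
    message(n0 - nRecords(tab), " exact-duplicate row(s) collapsed")
  tab
}

#' Ortholog map between species
#'
#' Symmetric many-to-many lookup of ortholog pairs, as exported from a
#' comparative-genomics resource (species, gene, species, gene).
#'
#' @slot pairs data.frame with columns \code{species_a}, \code{gene_a},
#'   \code{species_b}, \code{gene_b}, \code{homology_type}.
#' @export
setClass("OrthologMap", representation(pairs = "data.frame"))

setValidity("OrthologMap", function(object) {
  p <- object@pairs
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  if (!all(need %in% names(p))) return("missing pair columns")
  if (any(p$species_a == p$species_b))
    return("ortholog pairs must span two species")
  TRUE
})

#' @export
setMethod("show", "OrthologMap", function(object) {
  cat("OrthologMap:", nrow(object@pairs), "pairs across",
      length(unique(c(object@pairs$species_a, object@pairs$species_b))),
      "species\n")
})

#' Construct / read an ortholog map
#'
#' The TSV has columns \code{species_a gene_a species_b gene_b}
#' (optionally \code{homology_type}); lookups are symmetric and
#' many-to-many pairs are kept.
#'
#' @param pairs data.frame of pairs (for `orthologMap()`).
#' @param homologyType optional filter, e.g. `"ortholog_one2one"`; default
#'   keeps every pair.
#' @return an [OrthologMap].
#' @export
orthologMap <- function(pairs, homologyType = NULL) {
  if (!"homology_type" %in% names(pairs))
    pairs[["homology_type"]] <- rep(NA_character_, nrow(pairs))
  pairs$species_a <- tolower(pairs$species_a)
  pairs$species_b <- tolower(pairs$species_b)
  if (!is.null(homologyType))
    pairs <- pairs[pairs$homology_type %in% homologyType, , drop = FALSE]
  pairs <- unique(pairs[c("species_a", "gene_a", "species_b", "gene_b",
                          "homology_type")])
  rownames(pairs) <- NULL
  new("OrthologMap", pairs = pairs)
}

#' @rdname orthologMap
#' @param path path to the ortholog TSV.
#' @export
readOrthologs <- function(path, homologyType = NULL) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  orthologMap(df, homologyType = homologyType)
}

#' Orthologs of a gene
#'
#' Symmetric lookup: pairs are matched in both orientations.
#'
#' @param map an [OrthologMap].
#' @param species,geneId the query gene.
#' @return data.frame with columns \code{species}, \code{gene_id}.
#' @export
orthologsOf <- function(map, species, geneId) {
  species <- tolower(species)
  p <- map@pairs
  a <- p$species_a == species & p$gene_a == geneId
  b <- p$species_b == species & p$gene_b == geneId
  out <- rbind(
    data.frame(species = p$species_b[a], gene_id = p$gene_b[a],
               stringsAsFactors = FALSE),
    data.frame(species = p$species_a[b], gene_id = p$gene_a[b],
               stringsAsFactors = FALSE))
  unique(out)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' For every record (gene, term) adds records (gene, ancestor) for each
#' ancestor of the term, with unchanged provenance, so a gene annotated to a
#' specific term is implicitly annotated to every more general term. The
#' output is closed: propagating twice changes nothing. Records whose term is
#' unknown to its registry graph are dropped with a warning.
#'
#' @param assoc an [AssociationTable].
#' @param registry named list of [OntologyGraph] objects keyed by ontology
#'   key (GO/TO/PO/GRO/EO).
#' @return a propagated [AssociationTable].
#' @export
propagateAnnotations <- function(assoc, registry) {
  r <- records(assoc)
  if (!nrow(r)) return(assoc)
  known <- vapply(seq_len(nrow(r)), function(i) {
    g <- registry[[r$ontology_key[i]]]
    !is.null(g) && r$term_id[i] %in% termIds(g)
  }, logical(1))
  if (any(!known)) {
    warning(sum(!known), " record(s) with terms unknown to the registry ",
            "dropped")
    r <- r[known, , drop = FALSE]
  }
  if (!nrow(r)) return(associationTable(r))
  uniqTerms <- unique(r[c("term_id", "ontology_key")])
  anc <- lapply(seq_len(nrow(uniqTerms)), function(i)
    termAncestors(registry[[uniqTerms$ontology_key[i]]],
                  uniqTerms$term_id[i]))
  names(anc) <- uniqTerms$term_id
  extra <- lapply(seq_len(nrow(r)), function(i) {
    a <- anc[[r$term_id[i]]]
    if (!length(a)) return(NULL)
    out <- r[rep(i, length(a)), , drop = FALSE]
    out$term_id <- a
    out
  })
  allr <- rbind(r, do.call(rbind, extra))
  associationTable(allr)
}

#' Genes supported by a term set
#'
#' All genes of the species with at least one association to any member term
#' of the set. Call on a propagated table so genes annotated only to
#' descendants of the seeds are captured.
#'
#' @param assoc a propagated [AssociationTable].
#' @param termSet a [TermSet].
#' @param species species whose genes to return.
#' @return data.frame with one row per gene: \code{gene_id}, supporting
#'   \code{terms} (comma-joined), logical \code{direct} / \code{transitive}
#'   provenance flags. Sorted by gene id.
#' @export
genesForTerms <- function(assoc, termSet, species) {
  if (!length(memberIds(termSet))) stop("empty term set")
  r <- records(assoc)
  r <- r[r$species == tolower(species) &
           r$term_id %in% memberIds(termSet), , drop = FALSE]
  if (!nrow(r))
    return(data.frame(gene_id = character(), terms = character(),
                      direct = logical(), transitive = logical(),
                      stringsAsFactors = FALSE))
  sp <- split(r, r$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    terms = vapply(sp, function(d)
      paste(sort(unique(d$term_id)), collapse = ","), character(1)),
    direct = vapply(sp, function(d)
      any(d$provenance == "direct"), logical(1)),
    transitive = vapply(sp, function(d)
      any(d$provenance == "transitive"), logical(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transfer annotations to a target species via orthologs
#'
#' Implements transitive association: for each target-species gene that lacks
#' any direct association to the term set, every member-term annotation of
#' each of its orthologs (in any source species) is copied onto the gene with
#' provenance \code{transitive(source_species, source_gene)}. Genes that
#' already have a direct association to the term set receive no transitive
#' records for it; existing records are never removed or altered.
#'
#' @param assoc a propagated [AssociationTable].
#' @param orthologs an [OrthologMap].
#' @param targetSpecies species receiving transferred annotations.
#' @param termSet the [TermSet] the transfer is scoped to.
#' @return list with elements \code{table} (the augmented
#'   [AssociationTable]) and \code{summary} (named counts: \code{n_direct}
#'   target genes with direct support, \code{n_transitive} genes gaining
#'   transferred support, \code{n_unresolved} target orthology-linked genes
#'   with neither).
#' @export
transferTransitive <- function(assoc, orthologs, targetSpecies, termSet) {
  targetSpecies <- tolower(targetSpecies)
  r <- records(assoc)
  members <- memberIds(termSet)
  directGenes <- unique(r$gene_id[r$species == targetSpecies &
                                    r$provenance == "direct" &
                                    r$term_id %in% members])
  p <- orthologs@pairs
  # orient every pair as (target gene, source species, source gene)
  ta <- p$species_a == targetSpecies
  tb <- p$species_b == targetSpecies
  link <- rbind(
    data.frame(gene = p$gene_a[ta], src_species = p$species_b[ta],
               src_gene = p$gene_b[ta], stringsAsFactors = FALSE),
    data.frame(gene = p$gene_b[tb], src_species = p$species_a[tb],
               src_gene = p$gene_a[tb], stringsAsFactors = FALSE))
  link <- unique(link[!link$gene %in% directGenes, , drop = FALSE])
  src <- r[r$term_id %in% members & r$species != targetSpecies &
             r$provenance == "direct", , drop = FALSE]
  merged <- merge(link, src,
                  by.x = c("src_species", "src_gene"),
                  by.y = c("species", "gene_id"))
  gained <- character()
  tab <- assoc
  if (nrow(merged)) {
    newRec <- data.frame(
      gene_id = merged$gene, species = targetSpecies,
      term_id = merged$term_id, ontology_key = merged$ontology_key,
      provenance = "transitive", source_species = merged$src_species,
      source_gene = merged$src_gene, evidence = merged$evidence,
      stringsAsFactors = FALSE)
    gained <- unique(newRec$gene_id)
    tab <- associationTable(rbind(records(assoc), newRec))
  }
  summary <- c(n_direct = length(directGenes),
               n_transitive = length(gained),
               n_unresolved = length(setdiff(unique(link$gene), gained)))
  list(table = tab, summary = summary)
}
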