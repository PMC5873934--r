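#' Gene-by-ontology support matrix
#'
#' Records, for each candidate gene and ontology group, whether the gene has
#' at least one surviving association to the group's term set, and whether
#' that support is direct (\code{"D"}), transitive-only (\code{"T"}) or
#' absent (\code{"."}).
#'
#' @slot genes lexicographically ordered gene ids.
#' @slot keys ontology group keys (columns).
#' @slot support logical gene-by-key matrix.
#' @slot provenance character matrix of "D"/"T"/"." codes.
#' @export
setClass("SupportMatrix",
  representation(genes = "character", keys = "character",
                 support = "matrix", provenance = "matrix"))

setValidity("SupportMatrix", function(object) {
  if (!identical(dim(object@support),
                 c(length(object@genes), length(object@keys))))
    return("support dimensions do not match genes/keys")
  if (!identical(dim(object@provenance), dim(object@support)))
    return("provenance dimensions do not match support")
  if (is.unsorted(object@genes, strictly = TRUE))
    return("genes must be strictly sorted")
  if (any(object@support != (object@provenance != ".")))
    return("support must equal (provenance != '.')")
  TRUE
})

#' @export
setMethod("show", "SupportMatrix", function(object) {
  cat("SupportMatrix: ", length(object@genes), " genes x ",
      length(object@keys), " ontology groups (",
      paste(object@keys, collapse = ", "), ")\n", sep = "")
})

#' @rdname SupportMatrix-accessors
#' @param x a SupportMatrix.
#' @export
supportGenes <- function(x) x@genes

#' Accessors for SupportMatrix
#' @name SupportMatrix-accessors
#' @return `supportGenes()` the gene ids; `supportKeys()` the ontology group
#'   keys; `supportMatrix()` the logical matrix; `provenanceMatrix()` the
#'   D/T/. code matrix.
#' @export
supportKeys <- function(x) x@keys

#' @rdname SupportMatrix-accessors
#' @export
supportMatrix <- function(x) {
  m <- x@support
  dimnames(m) <- list(x@genes, x@keys)
  m
}

#' @rdname SupportMatrix-accessors
#' @export
provenanceMatrix <- function(x) {
  m <- x@provenance
  dimnames(m) <- list(x@genes, x@keys)
  m
}

.makeSupportMatrix <- function(perKey) {
  genes <- sort(unique(unlist(lapply(perKey, function(d) d$gene_id))))
  keys <- names(perKey)
  prov <- matrix(".", nrow = length(genes), ncol = length(keys))
  for (j in seq_along(keys)) {
    d <- perKey[[j]]
    if (!nrow(d)) next
    code <- ifelse(d$direct, "D", ifelse(d$transitive, "T", "."))
    prov[match(d$gene_id, genes), j] <- code
  }
  new("SupportMatrix", genes = genes, keys = keys,
      support = prov != ".", provenance = prov)
}

#' Collect candidate genes per ontology group
#'
#' Step one of the screening protocol: for each ontology group's term set,
#' transfer annotations to the target species through orthologs
#' ([transferTransitive()]) and collect the supported genes
#' ([genesForTerms()]). Genes with neither direct nor transitive support in a
#' group have \code{support = FALSE} there.
#'
#' @param assoc a propagated [AssociationTable].
#' @param orthologs an [OrthologMap].
#' @param termSets named list of [TermSet] objects, one per ontology group
#'   key.
#' @param targetSpecies the species being screened (e.g. "sorghum").
#' @return list with \code{sets} (named list of per-group gene data.frames),
#'   \code{matrix} (a [SupportMatrix]) and \code{report} (per-group
#'   identified/direct/transitive counts).
#' @export
collectPerOntology <- function(assoc, orthologs, termSets, targetSpecies) {
  if (!length(termSets) || is.null(names(termSets)) ||
      any(!nzchar(names(termSets))))
    stop("termSets must be a non-empty named list (one term set per ",
         "ontology group)")
  sets <- lapply(termSets, function(ts) {
    tr <- transferTransitive(assoc, orthologs, targetSpecies, ts)
    genesForTerms(tr$table, ts, targetSpecies)
  })
  report <- data.frame(
    ontology = names(sets),
    identified = vapply(sets, nrow, integer(1)),
    direct = vapply(sets, function(d) sum(d$direct), integer(1)),
    transitive_only = vapply(sets, function(d)
      sum(d$transitive & !d$direct), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(sets = sets, matrix = .makeSupportMatrix(sets), report = report)
}

#' Merge per-ontology gene sets into a unique candidate list
#'
#' Step two of the screening protocol: the union of the per-group gene sets,
#' de-duplicated, each gene annotated with the groups supporting it.
#'
#' @param perOntologySets named list of gene sets; each element is either a
#'   character vector of gene ids or a data.frame with a \code{gene_id}
#'   column (as produced by [collectPerOntology()]).
#' @return data.frame with columns \code{gene_id} and \code{ontologies}
#'   (comma-joined supporting group keys), sorted by gene id.
#' @export
mergeUnique <- function(perOntologySets) {
  asIds <- lapply(perOntologySets, function(s)
    if (is.data.frame(s)) s$gene_id else as.character(s))
  genes <- sort(unique(unlist(asIds)))
  keysFor <- vapply(genes, function(g)
    paste(names(asIds)[vapply(asIds, function(s) g %in% s, logical(1))],
          collapse = ","), character(1))
  data.frame(gene_id = genes, ontologies = unname(keysFor),
             stringsAsFactors = FALSE)
}

#' Genes supported by every required ontology group
#'
#' Step three of the screening protocol: keep only genes whose support row is
#' TRUE for every required key. Output is lexicographically ordered.
#'
#' @param matrix a [SupportMatrix].
#' @param requiredKeys ontology group keys that must all support a gene;
#'   must be a non-empty subset of the matrix columns.
#' @return sorted character vector of gene ids.
#' @export
allOntologyFilter <- function(matrix, requiredKeys) {
  if (!length(requiredKeys)) stop("requiredKeys must be non-empty")
  if (!all(requiredKeys %in% supportKeys(matrix)))
    stop("unknown ontology key(s): ",
         paste(setdiff(requiredKeys, supportKeys(matrix)), collapse = ", "))
  m <- supportMatrix(matrix)[, requiredKeys, drop = FALSE]
  sort(supportGenes(matrix)[rowSums(m) == length(requiredKeys)])
}

#' Screening funnel report
#'
#' Bookkeeping for the step-wise screen: per-ontology identified counts, the
#' merged unique count, and the all-ontology-support count.
#'
#' @param collected output of [collectPerOntology()].
#' @param requiredKeys keys passed to [allOntologyFilter()]; defaults to all.
#' @return data.frame of step counts.
#' @export
screenReport <- function(collected, requiredKeys = supportKeys(collected$matrix)) {
  merged <- mergeUnique(collected$sets)
  passed <- allOntologyFilter(collected$matrix, requiredKeys)
  data.frame(
    step = c(paste0("identified_", collected$report$ontology),
             "merged_unique", "all_ontology_pass"),
    count = c(collected$report$identified, nrow(merged), length(passed)),
    stringsAsFactors = FALSE)
}

#' Write a SupportMatrix as TSV
#'
#' Gene-by-ontology grid of D/T/. provenance codes.
#'
#' @param x a [SupportMatrix].
#' @param path output file path.
#' @export
writeSupportMatrix <- function(x, path) {
  df <- data.frame(gene_id = supportGenes(x), provenanceMatrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
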