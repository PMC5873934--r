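#' @import methods
#' @importFrom stats setNames
NULL

ONTOLOGY_KEYS <- c("GO", "TO", "PO", "GRO", "EO")
TRUE_PATH_RELATIONS <- c("is_a", "part_of")

#' Directed acyclic graph of ontology terms
#'
#' Holds the non-obsolete terms of one ontology (GO, TO, PO, GRO or EO) with
#' the \code{is_a} and \code{part_of} parent edges used for true-path
#' annotation propagation. Construct with [parseOBO()].
#'
#' @slot ontologyKey single ontology key, one of GO/TO/PO/GRO/EO.
#' @slot terms data.frame with columns \code{term_id}, \code{name},
#'   \code{namespace}.
#' @slot edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation}; relations are restricted to \code{is_a}/\code{part_of}.
#' @slot parentIdx,childIdx adjacency lists keyed by term id.
#' @export
setClass("OntologyGraph",
  representation(
    ontologyKey = "character",
    terms = "data.frame",
    edges = "data.frame",
    parentIdx = "list",
    childIdx = "list"
  )
)

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  if (length(object@ontologyKey) != 1L ||
      !object@ontologyKey %in% ONTOLOGY_KEYS)
    msgs <- c(msgs, "ontologyKey must be one of GO, TO, PO, GRO, EO")
  if (anyDuplicated(object@terms$term_id))
    msgs <- c(msgs, "duplicate term ids")
  if (nrow(object@edges)) {
    bad <- !object@edges$relation %in% TRUE_PATH_RELATIONS
    if (any(bad)) msgs <- c(msgs, "edges carry non true-path relations")
    unknown <- setdiff(c(object@edges$child, object@edges$parent),
                       object@terms$term_id)
    if (length(unknown))
      msgs <- c(msgs, paste("edges reference unknown terms:",
                            paste(utils::head(unknown, 3), collapse = ", ")))
    cyc <- .findCycle(object@terms$term_id, object@edges)
    if (!is.null(cyc))
      msgs <- c(msgs, paste("cycle detected:", paste(cyc, collapse = " -> ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph <", object@ontologyKey, "> with ",
      nrow(object@terms), " terms, ", nrow(object@edges), " edges\n",
      sep = "")
})

#' @rdname OntologyGraph-accessors
#' @param x,object an OntologyGraph.
#' @export
ontologyKey <- function(x) x@ontologyKey

#' Accessors for OntologyGraph
#'
#' @return `termIds()` the character vector of term accessions; `termNames()`
#'   a named character vector of term names; `nTerms()` the term count.
#' @name OntologyGraph-accessors
#' @export
termIds <- function(x) x@terms$term_id

#' @rdname OntologyGraph-accessors
#' @export
termNames <- function(x) setNames(x@terms$name, x@terms$term_id)

#' @rdname OntologyGraph-accessors
#' @export
nTerms <- function(x) nrow(x@terms)

# Kahn topological sort; returns NULL or one cycle (as a term-id path).
.findCycle <- function(ids, edges) {
  indeg <- setNames(integer(length(ids)), ids)
  kids <- split(edges$child, edges$parent)   # parent -> children (reverse)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)       # in-degree = number of parents
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (c in kids[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent edges from any remaining node until a repeat closes the cycle
  rem <- names(indeg)[indeg > 0L]
  pmap <- split(edges$parent, edges$child)
  path <- rem[[1L]]
  repeat {
    nxt <- intersect(pmap[[path[length(path)]]], rem)[1L]
    if (nxt %in% path) return(c(path[seq(match(nxt, path), length(path))], nxt))
    path <- c(path, nxt)
  }
}

#' Topological order of an ontology graph
#'
#' Returns term ids ordered so every parent precedes its children.
#' Errors if the graph is cyclic (which a valid [OntologyGraph] never is).
#'
#' @param graph an [OntologyGraph].
#' @return character vector of term ids.
#' @export
topologicalOrder <- function(graph) {
  ids <- termIds(graph)
  edges <- graph@edges
  indeg <- setNames(integer(length(ids)), ids)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(edges$child, edges$parent)
  queue <- sort(names(indeg)[indeg == 0L])
  out <- character()
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (c in sort(kids[[v]])) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(out) != length(ids)) stop("graph is cyclic")
  out
}

.validTermId <- function(id) {
  grepl(paste0("^(", paste(ONTOLOGY_KEYS, collapse = "|"), "):[0-9]+$"), id)
}

#' Parse an OBO flat file into an OntologyGraph
#'
#' Reads OBO 1.2/1.4 text. Every non-obsolete \code{[Term]} stanza becomes a
#' term; \code{is_a} and \code{relationship: part_of} lines become parent
#' edges. All other relationship types are ignored. Obsolete terms are
#' dropped with a warning and never remapped. Parent references to terms not
#' present in the file are warned about and the edge skipped.
#'
#' @param input path to an OBO file, or a character vector of OBO lines.
#' @param ontologyKey override for the graph's ontology key; inferred from
#'   the majority term prefix when `NULL`.
#' @return an [OntologyGraph].
#' @examples
#' obo <- c("[Term]", "id: GO:0009414",
#'          "name: response to water deprivation", "is_a: GO:0006950",
#'          "", "[Term]", "id: GO:0006950", "name: response to stress")
#' g <- parseOBO(obo)
#' termAncestors(g, "GO:0009414")
#' @export
parseOBO <- function(input, ontologyKey = NULL) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  lines <- sub("\\s+$", "", lines)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  termStarts <- grep("^\\[Term\\]$", lines)
  ends <- integer(0)
  if (length(starts)) {
    ends <- c(starts[-1L] - 1L, length(lines))
    names(ends) <- as.character(starts)
  }

  ids <- character(); nms <- character(); nss <- character()
  obs <- logical()
  ech <- character(); epa <- character(); erel <- character()
  for (s in termStarts) {
    e <- ends[[as.character(s)]]
    block <- lines[seq(s + 1L, max(s + 1L, e))]
    block <- block[nzchar(block) & !startsWith(block, "!")]
    getv <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(tag) + 3L))
    }
    id <- getv("id")
    if (length(id) != 1L || !nzchar(id))
      stop("malformed [Term] stanza at line ", s, ": missing id")
    nm <- getv("name"); if (!length(nm)) nm <- NA_character_
    ns <- getv("namespace"); if (!length(ns)) ns <- NA_character_
    isObs <- any(getv("is_obsolete") == "true")
    ids <- c(ids, id); nms <- c(nms, nm[1L]); nss <- c(nss, ns[1L])
    obs <- c(obs, isObs)
    if (!isObs) {
      for (p in getv("is_a")) {
        ech <- c(ech, id); epa <- c(epa, p); erel <- c(erel, "is_a")
      }
      rel <- getv("relationship")
      for (r in rel) {
        parts <- strsplit(r, "\\s+")[[1L]]
        if (length(parts) >= 2L && parts[1L] == "part_of") {
          ech <- c(ech, id); epa <- c(epa, parts[2L])
          erel <- c(erel, "part_of")
        }
      }
    }
  }
  bad <- !.validTermId(ids)
  if (any(bad))
    stop("invalid term accession(s): ", paste(utils::head(ids[bad], 3),
                                              collapse = ", "))
  if (any(obs))
    warning(sum(obs), " obsolete term(s) dropped")
  keep <- !obs
  terms <- data.frame(term_id = ids[keep], name = nms[keep],
                      namespace = nss[keep], stringsAsFactors = FALSE)
  edges <- data.frame(child = ech, parent = epa, relation = erel,
                      stringsAsFactors = FALSE)
  dangling <- !edges$parent %in% terms$term_id
  if (any(dangling)) {
    warning(sum(dangling), " edge(s) to missing parent term(s) skipped: ",
            paste(utils::head(unique(edges$parent[dangling]), 3),
                  collapse = ", "))
    edges <- edges[!dangling, , drop = FALSE]
  }
  edges <- unique(edges)
  if (is.null(ontologyKey)) {
    pref <- sub(":.*$", "", terms$term_id)
    ontologyKey <- if (nrow(terms)) names(sort(table(pref),
                                               decreasing = TRUE))[1L]
                   else "GO"
  }
  cyc <- .findCycle(terms$term_id, edges)
  if (!is.null(cyc))
    stop("cyclic is_a/part_of structure: ", paste(cyc, collapse = " -> "))
  new("OntologyGraph",
      ontologyKey = ontologyKey, terms = terms, edges = edges,
      parentIdx = .adjacency(edges, terms$term_id, up = TRUE),
      childIdx = .adjacency(edges, terms$term_id, up = FALSE))
}

.adjacency <- function(edges, ids, up = TRUE) {
  idx <- setNames(vector("list", length(ids)), ids)
  if (!nrow(edges)) return(idx)
  sp <- if (up) split(seq_len(nrow(edges)), edges$child)
        else split(seq_len(nrow(edges)), edges$parent)
  for (k in names(sp)) {
    rows <- sp[[k]]
    idx[[k]] <- data.frame(
      term = if (up) edges$parent[rows] else edges$child[rows],
      relation = edges$relation[rows], stringsAsFactors = FALSE)
  }
  idx
}

.reach <- function(idx, termId, relations) {
  if (!termId %in% names(idx)) stop("unknown term: ", termId)
  seen <- character()
  frontier <- termId
  while (length(frontier)) {
    nxt <- character()
    for (t in frontier) {
      adj <- idx[[t]]
      if (is.null(adj)) next
      nxt <- c(nxt, adj$term[adj$relation %in% relations])
    }
    nxt <- setdiff(unique(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, termId))
}

#' Ancestors and descendants of a term
#'
#' `termAncestors()` returns every term reachable from `termId` by repeatedly
#' following the given relations towards the roots (the term itself is
#' excluded); `termDescendants()` is the reverse traversal.
#'
#' @param graph an [OntologyGraph].
#' @param termId a term accession present in the graph.
#' @param relations relation names to follow (default both true-path
#'   relations, `is_a` and `part_of`).
#' @return sorted character vector of term accessions.
#' @export
termAncestors <- function(graph, termId,
                          relations = TRUE_PATH_RELATIONS) {
  if (!termId %in% termIds(graph)) stop("unknown term: ", termId)
  .reach(graph@parentIdx, termId, relations)
}

#' @rdname termAncestors
#' @export
termDescendants <- function(graph, termId,
                            relations = TRUE_PATH_RELATIONS) {
  if (!termId %in% termIds(graph)) stop("unknown term: ", termId)
  .reach(graph@childIdx, termId, relations)
}

#' Stress-related term set
#'
#' A set of ontology terms labelled for one stress or plant attribute:
#' the seed accessions (e.g. the drought-tolerance accessions used to query
#' each ontology) plus, by default, all their descendants.
#'
#' @slot ontologyKey ontology the members belong to.
#' @slot seedIds seed accessions.
#' @slot memberIds seeds plus descendant closure.
#' @slot label free-text label, e.g. "drought".
#' @export
setClass("TermSet",
  representation(ontologyKey = "character", seedIds = "character",
                 memberIds = "character", label = "character"))

setValidity("TermSet", function(object) {
  if (!all(object@seedIds %in% object@memberIds))
    return("seeds must be members")
  TRUE
})

#' @export
setMethod("show", "TermSet", function(object) {
  cat("TermSet '", object@label, "' <", object@ontologyKey, ">: ",
      length(object@seedIds), " seed(s), ", length(object@memberIds),
      " member term(s)\n", sep = "")
})

#' @rdname TermSet-accessors
#' @param x a TermSet.
#' @export
memberIds <- function(x) x@memberIds

#' Accessors for TermSet
#' @name TermSet-accessors
#' @return `seedIds()` seed accessions, `memberIds()` the full member set,
#'   `setLabel()` the label.
#' @export
seedIds <- function(x) x@seedIds

#' @rdname TermSet-accessors
#' @export
setLabel <- function(x) x@label

#' Build a term set from seed accessions
#'
#' Members are the seeds plus (when `closure = TRUE`, the default) all
#' descendants of every seed, so genes annotated to more specific terms are
#' captured.
#'
#' @param graph an [OntologyGraph].
#' @param seedIds seed accessions; must exist in `graph`.
#' @param label free-text label for the set.
#' @param closure include descendant closure (default TRUE).
#' @return a [TermSet].
#' @export
buildTermSet <- function(graph, seedIds, label = "", closure = TRUE) {
  missing <- setdiff(seedIds, termIds(graph))
  if (length(missing))
    stop("seed(s) not in ", ontologyKey(graph), " graph: ",
         paste(missing, collapse = ", "))
  members <- seedIds
  if (closure)
    members <- union(members,
                     unlist(lapply(seedIds, termDescendants, graph = graph)))
  new("TermSet", ontologyKey = ontologyKey(graph),
      seedIds = sort(unique(seedIds)), memberIds = sort(unique(members)),
      label = label)
}
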