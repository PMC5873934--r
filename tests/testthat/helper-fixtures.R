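# Shared fixture builders and independent brute-force oracles.

oboStanza <- function(id, name = paste("term", id), isa = character(),
                      partof = character(), obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("is_a: ", isa),
    if (length(partof)) paste0("relationship: part_of ", partof),
    if (obsolete) "is_obsolete: true", "")
}

chainGraph <- function() {
  # a is_a b is_a c (c is the root)
  parseOBO(c(oboStanza("GO:0000003", "c"),
             oboStanza("GO:0000002", "b", isa = "GO:0000003"),
             oboStanza("GO:0000001", "a", isa = "GO:0000002")))
}

diamondGraph <- function() {
  # a -> b, a -> c, b -> d, c -> d
  parseOBO(c(oboStanza("GO:0000004", "d"),
             oboStanza("GO:0000002", "b", isa = "GO:0000004"),
             oboStanza("GO:0000003", "c", isa = "GO:0000004"),
             oboStanza("GO:0000001", "a", isa = c("GO:0000002",
                                                  "GO:0000003"))))
}

# Brute-force reachability oracle over the parent relation: boolean matrix
# reach[i, j] = TRUE iff term j is reachable from term i via parent edges.
bruteReachability <- function(graph) {
  ids <- termIds(graph)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  e <- graph@edges
  if (nrow(e)) A[cbind(match(e$child, ids), match(e$parent, ids))] <- TRUE
  reach <- A
  repeat {
    nxt <- reach | (reach %*% A > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

randomDagGraph <- function(nTerms, seed, key = "GO") {
  parseOBO(simulateOntology(nTerms, key = key, maxParents = 3L, seed = seed),
           ontologyKey = key)
}

smallAssoc <- function(df) {
  df$species <- if (is.null(df$species)) "sorghum" else df$species
  df$ontology_key <- if (is.null(df$ontology_key))
    sub(":.*", "", df$term_id) else df$ontology_key
  associationTable(df)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# fraction of all size-n subsets of 1..N containing at least k of 1..K.
enumTail <- function(k, n, K, N) {
  if (n == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

writeTempTsv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random additive distance matrix from a random binary tree with strictly
# positive branch lengths; returns the matrix and the generating tree.
randomAdditive <- function(nTaxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(nTaxa, br = function(n) stats::runif(n, 0.1, 1))
  tree$tip.label <- sort(tree$tip.label)  # labels independent of topology
  D <- ape::cophenetic.phylo(tree)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tree, D = D)
}
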