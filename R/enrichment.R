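#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` annotated genes among `n` drawn from
#' a background of `N` genes of which `K` are annotated: the classical
#' over-representation p-value (equivalently the one-sided Fisher exact
#' test). Vectorised over its arguments.
#'
#' @param k overlap count (study genes annotated to the term).
#' @param n study-set size.
#' @param K background genes annotated to the term.
#' @param N background (universe) size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @examples
#' hypergeomTail(3, 5, 4, 10)  # 66/252
#' @export
hypergeomTail <- function(k, n, K, N) {
  stopifnot(length(k) == length(n) || length(n) == 1L,
            length(k) == length(K) || length(K) == 1L,
            length(k) == length(N) || length(N) == 1L)
  if (any(k < 0 | K < 0 | n < 0 | N < 0))
    stop("counts must be non-negative")
  if (any(k > pmin(n, K)))
    stop("k must not exceed min(n, K)")
  if (any(n > N | K > N))
    stop("n and K must not exceed N")
  # upper tail P(X >= k) = P(X > k - 1); stats::phyper is exact here
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment: on p-values sorted ascending,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)` clipped at 1, mapped back to input
#' order. Permuting the input permutes the output identically.
#'
#' @param p p-values in (0, 1].
#' @param method `"BH"` (default) or the Benjamini-Yekutieli variant `"BY"`.
#' @return adjusted values, same length and order as `p`.
#' @export
bhAdjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Term over-representation in a study gene set
#'
#' For every term annotated to at least one study gene, tests
#' over-representation of the term among the study genes relative to the
#' background universe with the hypergeometric upper tail, then adjusts
#' across terms with Benjamini-Hochberg. Rows failing the threshold are
#' flagged in the \code{significant} column, not removed.
#'
#' The background universe defaults to all genes of the species present in
#' the (propagated) association table for the ontologies represented; pass
#' `universe` to override.
#'
#' @param study character vector of study gene ids; genes absent from the
#'   background are dropped with a warning.
#' @param assoc a propagated [AssociationTable] serving as background.
#' @param species species whose annotations define the background.
#' @param registry optional named list of [OntologyGraph] objects used to
#'   attach term names.
#' @param alpha significance threshold (default 0.05; the screening gate of
#'   the pipeline uses 0.01).
#' @param correct gate on BH-adjusted q (default) rather than raw p.
#' @param universe optional explicit background gene universe.
#' @param method multiple-testing variant passed to [bhAdjust()].
#' @return data.frame (one row per term) with columns \code{term_id},
#'   \code{term_name}, \code{ontology}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{p}, \code{q}, \code{significant}, sorted by ascending
#'   p (ties by term id).
#' @export
enrichTerms <- function(study, assoc, species, registry = NULL,
                        alpha = 0.05, correct = TRUE, universe = NULL,
                        method = "BH") {
  if (!length(study)) stop("empty study set")
  r <- records(assoc)
  r <- r[r$species == tolower(species), , drop = FALSE]
  if (is.null(universe)) universe <- unique(r$gene_id)
  r <- r[r$gene_id %in% universe, , drop = FALSE]
  study <- unique(study)
  missing <- setdiff(study, universe)
  if (length(missing)) {
    warning(length(missing), " study gene(s) absent from the background ",
            "universe dropped")
    study <- setdiff(study, missing)
  }
  if (!length(study)) stop("no study genes left in the universe")
  N <- length(universe)
  n <- length(study)
  byTerm <- split(r$gene_id, r$term_id)
  K <- vapply(byTerm, function(g) length(unique(g)), integer(1))
  k <- vapply(byTerm, function(g) length(intersect(unique(g), study)),
              integer(1))
  keep <- k >= 1L
  termId <- names(byTerm)[keep]
  K <- K[keep]; k <- k[keep]
  ont <- r$ontology_key[match(termId, r$term_id)]
  nm <- rep(NA_character_, length(termId))
  if (!is.null(registry)) {
    for (key in names(registry)) {
      sel <- ont == key
      nm[sel] <- unname(termNames(registry[[key]])[termId[sel]])
    }
  }
  p <- hypergeomTail(k, n, K, N)
  q <- bhAdjust(p, method = if (identical(method, "BY")) "BY" else "BH")
  out <- data.frame(term_id = termId, term_name = nm, ontology = ont,
                    k = k, n = n, K = K, N = N, p = p, q = q,
                    significant = if (correct) q < alpha else p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "correct") <- correct
  out
}

#' Significant subset of an enrichment table
#'
#' @param table output of [enrichTerms()].
#' @return the rows flagged significant.
#' @export
significantTerms <- function(table) {
  table[table$significant, , drop = FALSE]
}
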