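#' @importFrom ape read.tree write.tree prop.part di2multi
NULL

.alnMatrix <- function(aln) {
  if (inherits(aln, "AAStringSet") || inherits(aln, "XStringSet"))
    aln <- setNames(as.character(aln), names(aln))
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment sequences need unique names")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must have equal length")
  if (nchar(aln[[1]]) < 1L) stop("alignment has zero columns")
  m <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(m) <- names(aln)
  m
}

#' Percent-divergence (p) distances from an aligned set of sequences
#'
#' `d(i, j)` is the fraction of mismatching positions over the compared
#' columns. Gap handling: \code{complete} (default) drops every column
#' containing a gap in any sequence before comparing; \code{pairwise} drops,
#' per pair, only the columns gapped in that pair.
#'
#' @param aln named character vector of equal-length aligned sequences (or a
#'   Biostrings XStringSet); gap character \code{"-"}.
#' @param gapMode \code{"complete"} or \code{"pairwise"}.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @examples
#' pDistance(c(a = "ACDE", b = "ACDF"))[1, 2]  # 0.25
#' @export
pDistance <- function(aln, gapMode = c("complete", "pairwise")) {
  gapMode <- match.arg(gapMode)
  m <- .alnMatrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  taxa <- rownames(m)
  if (gapMode == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep))
      stop("no gap-free columns remain under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    cmp <- if (gapMode == "pairwise") m[i, ] != "-" & m[j, ] != "-"
           else rep(TRUE, ncol(m))
    if (!any(cmp))
      stop("no comparable columns for pair ", taxa[i], " / ", taxa[j])
    d[i, j] <- d[j, i] <- sum(m[i, cmp] != m[j, cmp]) / sum(cmp)
  }
  d
}

#' Kimura protein distance correction
#'
#' Corrects an observed proportion of differing residues for multiple
#' substitutions with `d = -ln(1 - p - 0.2 p^2)`, the approximation used by
#' classic protein distance tools. Undefined (saturated) inputs — where the
#' logarithm's argument is non-positive — either raise an error or are capped
#' with a warning.
#'
#' @param p observed difference proportion(s), `0 <= p`.
#' @param onSaturate \code{"error"} (default) or \code{"cap"}.
#' @return corrected distance(s); saturated entries carry attribute
#'   \code{"saturated"} (logical vector) when capped.
#' @examples
#' kimuraCorrect(0.25)  # -log(0.7375)
#' @export
kimuraCorrect <- function(p, onSaturate = c("error", "cap")) {
  onSaturate <- match.arg(onSaturate)
  if (any(p < 0)) stop("p must be non-negative")
  arg <- 1 - p - 0.2 * p^2
  sat <- arg <= 0
  if (any(sat)) {
    if (onSaturate == "error")
      stop("saturated distance(s): 1 - p - 0.2p^2 <= 0 for p = ",
           paste(utils::head(p[sat], 3), collapse = ", "))
    warning(sum(sat), " saturated distance(s) capped")
  }
  out <- ifelse(sat, -log(.Machine$double.eps), -log(pmax(arg,
                                                          .Machine$double.eps)))
  if (any(sat)) attr(out, "saturated") <- sat
  out
}

.newickLabel <- function(x) {
  if (grepl("[][(){}:;,'\"[:space:]]", x))
    paste0("'", gsub("'", "''", x), "'")
  else x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining: at each step the pair (i, j)
#' minimising `Q(i, j) = (r - 2) d(i, j) - R_i - R_j` (with `R_i` the row
#' sum over active nodes) is joined; limb lengths follow the usual formulas
#' `l_i = d(i, j)/2 + (R_i - R_j) / (2 (r - 2))`. Ties in Q are broken by the
#' lexicographically smallest pair of cluster names (a cluster is named by
#' its smallest leaf label), so the construction is deterministic. Negative
#' limb lengths are clamped to zero with the deficit moved onto the sibling
#' limb (set `clampNegative = FALSE` for the raw lengths). The result is the
#' unrooted topology, returned as a \pkg{ape} \code{phylo} with a
#' trifurcating root.
#'
#' @param D symmetric numeric matrix with zero diagonal and taxa dimnames
#'   (at least 3 taxa).
#' @param clampNegative clamp negative branch lengths (default TRUE).
#' @return an \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D, clampNegative = TRUE) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D needs taxa dimnames")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(D)
  # active clusters: newick fragment, sort key = smallest contained leaf
  nwk <- vapply(labs, .newickLabel, character(1))
  key <- labs
  d <- D
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairKey <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pairKey)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (clampNegative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
      li <- max(li, 0); lj <- max(lj, 0)
    }
    newNwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":",
                     fmt(lj), ")")
    newKey <- min(key[i], key[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    nwk <- c(nwk[keep], newNwk)
    key <- c(key[keep], newKey)
    d <- d2
  }
  # closed-form limbs for the final three clusters
  ord <- order(key)
  nwk <- nwk[ord]; d <- d[ord, ord, drop = FALSE]
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clampNegative) { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  text <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb), ",",
                 nwk[3], ":", fmt(lc), ");")
  .unquoteLabels(read.tree(text = text))
}

.unquoteLabels <- function(tree) {
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tree$tip.label <- unquote(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote(tree$node.label)
  tree
}

#' Leaf-to-leaf path-length metric of a tree
#'
#' Sums branch lengths along the path between every pair of leaves; on an
#' additive distance matrix this reproduces the input exactly, which is the
#' primary correctness oracle for [neighborJoining()].
#'
#' @param tree an \code{ape::phylo} with branch lengths.
#' @return symmetric matrix over the tip labels.
#' @export
pathMetric <- function(tree) {
  m <- ape::cophenetic.phylo(tree)
  m[sort(rownames(m)), sort(colnames(m))]
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is encoded as the
#' sorted, comma-joined labels of the side not containing the
#' alphabetically smallest taxon, so the encoding is rooting-invariant.
#'
#' @param tree an \code{ape::phylo}.
#' @return character vector of split signatures (possibly empty).
#' @export
treeBipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L || is.null(tree$edge)) return(character(0))
  sigs <- vapply(prop.part(tree), function(cl) {
    tips <- tree$tip.label[cl]
    if (length(tips) <= 1L || length(tips) >= n - 1L) return(NA_character_)
    ref <- min(tree$tip.label)
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    paste(sort(side), collapse = ",")
  }, character(1))
  unique(sigs[!is.na(sigs)])
}

# per-internal-node signatures (NA for root/trivial), aligned to node.label
.nodeSignatures <- function(tree) {
  n <- length(tree$tip.label)
  pp <- prop.part(tree)
  vapply(pp, function(cl) {
    tips <- tree$tip.label[cl]
    if (length(tips) <= 1L || length(tips) >= n - 1L) return(NA_character_)
    ref <- min(tree$tip.label)
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    paste(sort(side), collapse = ",")
  }, character(1))
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `nReps` times (seeded, reproducible),
#' rebuilds a tree per replicate, and counts, for each internal edge of the
#' point tree, the replicates containing the same bipartition. Supports are
#' on the 0..`nReps` scale and stored as internal node labels.
#'
#' @param aln named character vector of aligned sequences.
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed integer seed driving the resampling.
#' @param gapMode gap handling for [pDistance()].
#' @param correction \code{"none"} or \code{"kimura"} ([kimuraCorrect()],
#'   saturated values capped).
#' @param clampNegative passed to [neighborJoining()].
#' @return list with \code{tree} (point tree, node labels = support counts),
#'   \code{supports} (named numeric vector keyed by split signature),
#'   \code{nReps}, and \code{degenerate} (TRUE when all input distances are
#'   zero, in which case the topology is arbitrary — a star).
#' @export
bootstrapNJ <- function(aln, nReps, seed = 1L,
                        gapMode = c("complete", "pairwise"),
                        correction = c("none", "kimura"),
                        clampNegative = TRUE) {
  gapMode <- match.arg(gapMode)
  correction <- match.arg(correction)
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- .alnMatrix(aln)
  build <- function(mat) {
    seqs <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
    d <- pDistance(seqs, gapMode = gapMode)
    if (correction == "kimura")
      d[] <- suppressWarnings(kimuraCorrect(as.vector(d), onSaturate = "cap"))
    neighborJoining(d, clampNegative = clampNegative)
  }
  point <- build(m)
  degenerate <- {
    d0 <- pDistance(setNames(apply(m, 1L, paste, collapse = ""),
                             rownames(m)), gapMode = gapMode)
    all(d0 == 0)
  }
  sigs <- .nodeSignatures(point)
  counts <- setNames(numeric(sum(!is.na(sigs))), sigs[!is.na(sigs)])
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (rep in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    repTree <- try(build(m[, cols, drop = FALSE]), silent = TRUE)
    if (inherits(repTree, "try-error")) next  # e.g. all-gap resample
    repSigs <- treeBipartitions(repTree)
    hit <- names(counts) %in% repSigs
    counts[hit] <- counts[hit] + 1
  }
  point$node.label <- ifelse(is.na(sigs), "", as.character(counts[sigs]))
  list(tree = point, supports = counts, nReps = nReps,
       degenerate = degenerate)
}

#' Collapse weakly supported clades
#'
#' Contracts internal edges of a bootstrapped tree whose support falls below
#' `floor * nReps` (default floor 5\%) into multifurcations.
#'
#' @param boot result of [bootstrapNJ()].
#' @param floor support floor as a fraction of replicates (default 0.05).
#' @return an \code{ape::phylo}.
#' @export
collapseLowSupport <- function(boot, floor = 0.05) {
  tree <- boot$tree
  ntip <- length(tree$tip.label)
  lab <- tree$node.label
  childIsInternal <- tree$edge[, 2] > ntip
  supp <- rep(NA_real_, nrow(tree$edge))
  supp[childIsInternal] <- suppressWarnings(
    as.numeric(lab[tree$edge[childIsInternal, 2] - ntip]))
  weak <- childIsInternal & !is.na(supp) & supp < floor * boot$nReps
  if (any(weak)) {
    # zero-length internal edges (including any produced by clamping) are
    # contracted together with the weakly supported ones
    tree$edge.length[weak] <- 0
    tree <- di2multi(tree, tol = 1e-10)
  }
  tree
}

#' Write a tree as Newick text
#'
#' Branch lengths are written with 6 decimals and internal node labels (e.g.
#' bootstrap supports) are preserved; labels containing Newick
#' metacharacters are single-quoted. The output round-trips through
#' [readNewickTree()] losslessly (topology exactly, lengths within 1e-6).
#'
#' @param tree an \code{ape::phylo}.
#' @param path output path; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.6f", x)
  rec <- function(node) {
    if (node <= ntip) return(.newickLabel(tree$tip.label[node]))
    rows <- children[[as.character(node)]]
    sub <- vapply(rows, function(e) {
      child <- tree$edge[e, 2]
      s <- rec(child)
      if (!is.null(tree$edge.length))
        s <- paste0(s, ":", fmt(tree$edge.length[e]))
      s
    }, character(1))
    lab <- if (!is.null(tree$node.label)) {
      l <- tree$node.label[node - ntip]
      if (is.na(l) || !nzchar(l)) "" else .newickLabel(l)
    } else ""
    paste0("(", paste(sub, collapse = ","), ")", lab)
  }
  root <- ntip + 1L
  text <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' @rdname writeNewickTree
#' @param input a path to a Newick file, or a Newick string.
#' @export
readNewickTree <- function(input) {
  tree <- if (file.exists(input)) read.tree(input)
          else read.tree(text = input)
  .unquoteLabels(tree)
}
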