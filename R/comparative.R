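#' Partition named gene sets into disjoint Venn regions
#'
#' Every gene of the universe (the union of all sets) is assigned to exactly
#' one region according to its membership bit-vector across the named sets —
#' the decomposition a Venn diagram displays. Region keys are the sorted set
#' labels joined with \code{"+"}.
#'
#' @param sets named list (2 to 8 elements) of character gene-id vectors;
#'   labels must be unique.
#' @return list with \code{regions} (named list, region key -> sorted gene
#'   vector; only non-empty regions appear), \code{labels} and
#'   \code{universe}. Use [vennCounts()] for the full 2^n - 1 count table.
#' @examples
#' p <- vennPartition(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' p$regions
#' @export
vennPartition <- function(sets) {
  if (length(sets) < 2L || length(sets) > 8L)
    stop("between 2 and 8 sets required")
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stop("sets must have unique non-empty labels")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(row)
    paste(sort(labels[row]), collapse = "+"))
  regions <- split(universe, key)
  regions <- lapply(regions, sort)
  list(regions = regions, labels = labels, universe = universe)
}

#' Region counts of a Venn partition
#'
#' All `2^n - 1` possible membership regions, empty ones reported with
#' count 0.
#'
#' @param partition output of [vennPartition()].
#' @return data.frame with columns \code{region} and \code{count}.
#' @export
vennCounts <- function(partition) {
  labels <- partition$labels
  n <- length(labels)
  keys <- character()
  for (size in seq_len(n))
    keys <- c(keys, apply(utils::combn(sort(labels), size), 2L,
                          paste, collapse = "+"))
  counts <- vapply(keys, function(k) {
    r <- partition$regions[[k]]
    if (is.null(r)) 0L else length(r)
  }, integer(1))
  data.frame(region = keys, count = unname(counts), stringsAsFactors = FALSE)
}

#' Classify a focal set's genes by breadth of stress response
#'
#' Genes of the focal stress set are labelled by how many stress sets their
#' Venn region spans: 1 = \code{specific}, 2 = \code{dual}, 3 = \code{triple},
#' all sets = \code{universal}; intermediate breadths (possible with five or
#' more sets) are labelled \code{"<k>-way"}.
#'
#' @param partition output of [vennPartition()].
#' @param focal one of the partition's labels.
#' @return named character vector: gene id -> class, over the focal set.
#' @export
multistressClassify <- function(partition, focal) {
  if (!focal %in% partition$labels)
    stop("unknown focal label: ", focal)
  nAll <- length(partition$labels)
  out <- character()
  for (key in names(partition$regions)) {
    parts <- strsplit(key, "+", fixed = TRUE)[[1]]
    if (!focal %in% parts) next
    k <- length(parts)
    cls <- if (k == nAll) "universal"
           else switch(as.character(k), "1" = "specific", "2" = "dual",
                       "3" = "triple", paste0(k, "-way"))
    genes <- partition$regions[[key]]
    out[genes] <- cls
  }
  out[order(names(out))]
}

#' Percentages with half-away-from-zero rounding
#'
#' `100 * numerators / denominator`, rounded half away from zero to the
#' requested number of decimals — the convention under which 21.89 prints as
#' 21.9 and 31.54 as 32 (banker's rounding would disagree on .5 ties).
#'
#' @param numerators non-negative counts.
#' @param denominator positive total.
#' @param decimals decimal places to keep (default 1).
#' @return numeric vector of percentages.
#' @examples
#' percentageReport(c(37, 84, 48), 169, 1)  # 21.9 49.7 28.4
#' @export
percentageReport <- function(numerators, denominator, decimals = 1) {
  if (length(denominator) != 1L || denominator <= 0)
    stop("denominator must be a single positive count")
  if (any(numerators < 0)) stop("numerators must be non-negative")
  x <- 100 * numerators / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

ORTHOLOGY_SPECIES <- c("maize", "rice", "arabidopsis")

#' Orthology subclass of a gene from species presence
#'
#' Labels a sorghum gene by the set of species in which orthologs occur,
#' following the naming scheme \code{SO<M|R|A>} for sorghum orthologs in
#' maize/rice/Arabidopsis (letters concatenated in that order) prefixed with
#' \code{Sorghum_} when the gene is also sorghum-specific, and plain
#' \code{Sorghum} for sorghum-specific genes without orthologs. The scheme
#' generates 15 labels for the 15 non-empty presence vectors; the one
#' all-absent vector is invalid.
#'
#' @param presence named logical vector with elements \code{sorghum},
#'   \code{maize}, \code{rice}, \code{arabidopsis}.
#' @return single class label.
#' @examples
#' orthologyClass(c(sorghum = FALSE, maize = TRUE, rice = TRUE,
#'                  arabidopsis = FALSE))  # "SOMR"
#' @export
orthologyClass <- function(presence) {
  need <- c("sorghum", ORTHOLOGY_SPECIES)
  if (!all(need %in% names(presence)))
    stop("presence must name: ", paste(need, collapse = ", "))
  presence <- as.logical(presence[need])
  if (!any(presence)) stop("gene must occur in at least one species")
  letters3 <- c(maize = "M", rice = "R", arabidopsis = "A")
  suffix <- paste(letters3[presence[-1]], collapse = "")
  if (presence[1] && !nzchar(suffix)) return("Sorghum")
  if (presence[1]) return(paste0("Sorghum_SO", suffix))
  paste0("SO", suffix)
}

#' Orthology class mapping table
#'
#' Enumerates all 15 non-empty species-presence vectors with their class
#' labels, documenting that [orthologyClass()] is a bijection on them.
#'
#' @return data.frame with logical columns \code{sorghum}, \code{maize},
#'   \code{rice}, \code{arabidopsis} and the \code{class} label.
#' @export
orthologyClassTable <- function() {
  grid <- expand.grid(sorghum = c(FALSE, TRUE), maize = c(FALSE, TRUE),
                      rice = c(FALSE, TRUE), arabidopsis = c(FALSE, TRUE))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  grid$class <- apply(grid, 1L, function(row)
    orthologyClass(setNames(as.logical(row),
                            c("sorghum", "maize", "rice", "arabidopsis"))))
  rownames(grid) <- NULL
  grid
}

#' Write a Venn partition as TSV
#'
#' Columns \code{region}, \code{count}, \code{genes} (comma-joined), one row
#' per possible region.
#'
#' @param partition output of [vennPartition()].
#' @param path output file path.
#' @export
writeVennPartition <- function(partition, path) {
  counts <- vennCounts(partition)
  counts$genes <- vapply(counts$region, function(k) {
    r <- partition$regions[[k]]
    if (is.null(r)) "" else paste(r, collapse = ",")
  }, character(1))
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
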