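#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame mcols "mcols<-"
NULL

#' Normalise chromosome labels
#'
#' Maps labels such as `"Chr 1"`, `"CHR1"`, `"1"` to `"chr1"`.
#'
#' @param x character vector of chromosome labels.
#' @return normalised labels.
#' @export
normalizeChrom <- function(x) {
  x <- tolower(gsub("\\s+", "", x))
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

.makeLocusGRanges <- function(chrom, start, end, meta) {
  if (any(start < 1 | end < start))
    stop("invalid coordinates: need 1 <= start <= end")
  gr <- GRanges(normalizeChrom(chrom), IRanges(start, end))
  mcols(gr) <- DataFrame(meta)
  gr
}

#' Read gene loci as GRanges
#'
#' Supported formats: \code{"tsv"} (columns \code{gene_id chrom start end}
#' with 1-based inclusive coordinates, optional \code{strand}), \code{"bed"}
#' (0-based half-open; converted on read) and \code{"gff3"} (via
#' \pkg{rtracklayer}; gene id taken from the ID attribute). Chromosome names
#' are normalised on load.
#'
#' @param path input file.
#' @param format one of "tsv", "bed", "gff3".
#' @return GRanges with a \code{gene_id} metadata column.
#' @export
readGeneLoci <- function(path, format = c("tsv", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    return(.makeLocusGRanges(df$chrom, as.numeric(df$start),
                             as.numeric(df$end),
                             data.frame(gene_id = df$gene_id,
                                        stringsAsFactors = FALSE)))
  }
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    gene <- if (ncol(df) >= 4L) df[[4]] else paste0("feature", seq_len(nrow(df)))
    return(.makeLocusGRanges(df[[1]], df[[2]] + 1L, df[[3]],
                             data.frame(gene_id = gene,
                                        stringsAsFactors = FALSE)))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 input requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  id <- if ("ID" %in% names(mcols(gr))) mcols(gr)$ID else
    paste0("feature", seq_along(gr))
  .makeLocusGRanges(as.character(seqnames(gr)), start(gr), end(gr),
                    data.frame(gene_id = as.character(id),
                               stringsAsFactors = FALSE))
}

#' Read a QTL region table as GRanges
#'
#' Tab-separated columns \code{qtl_id trait chrom start end} and optionally
#' \code{ref}; coordinates 1-based inclusive; chromosome labels normalised.
#'
#' @param path input TSV.
#' @return GRanges with metadata columns \code{qtl_id}, \code{trait},
#'   \code{ref}.
#' @export
readQTLRegions <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(df$qtl_id)) stop("duplicate qtl_id values")
  meta <- data.frame(qtl_id = df$qtl_id, trait = df$trait,
                     ref = if ("ref" %in% names(df)) df$ref else NA_character_,
                     stringsAsFactors = FALSE)
  .makeLocusGRanges(df$chrom, as.numeric(df$start), as.numeric(df$end), meta)
}

#' Co-localize genes within QTL regions
#'
#' Assigns gene `g` to QTL `q` when both lie on the same chromosome and, in
#' the default \code{containment} mode, the gene interval falls entirely
#' within the QTL interval (`q.start <= g.start` and `g.end <= q.end`); in
#' \code{overlap} mode any intersection suffices. A gene contained in several
#' (overlapping) QTLs is assigned to each; the de-duplicated gene total is
#' reported alongside.
#'
#' @param genes GRanges of gene loci (metadata column \code{gene_id}).
#' @param qtls GRanges of QTL regions (metadata columns \code{qtl_id},
#'   \code{trait}).
#' @param mode \code{"containment"} (default) or \code{"overlap"}.
#' @return list with \code{assignments} (data.frame \code{qtl_id, trait,
#'   gene_id}, ordered by qtl then gene), \code{perQTL} (data.frame
#'   \code{qtl_id, trait, count} over all QTLs), \code{total} (sum of
#'   per-QTL counts) and \code{uniqueGenes} (de-duplicated gene count).
#' @export
colocalize <- function(genes, qtls, mode = c("containment", "overlap")) {
  mode <- match.arg(mode)
  hits <- findOverlaps(genes, qtls,
                       type = if (mode == "containment") "within" else "any")
  qtlIds <- as.character(mcols(qtls)$qtl_id)
  traits <- as.character(mcols(qtls)$trait)
  assignments <- data.frame(
    qtl_id = qtlIds[subjectHits(hits)],
    trait = traits[subjectHits(hits)],
    gene_id = as.character(mcols(genes)$gene_id)[queryHits(hits)],
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$qtl_id, assignments$gene_id), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  counts <- table(factor(assignments$qtl_id, levels = qtlIds))
  perQTL <- data.frame(qtl_id = qtlIds, trait = traits,
                       count = as.integer(counts),
                       stringsAsFactors = FALSE)
  list(assignments = assignments, perQTL = perQTL,
       total = nrow(assignments),
       uniqueGenes = length(unique(assignments$gene_id)))
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Standard 12-column tabular output: query, subject, \% identity, alignment
#' length, mismatches, gap opens, q.start, q.end, s.start, s.end, e-value,
#' bit score.
#'
#' @param path input TSV (no header).
#' @return data.frame with the 12 standard columns.
#' @export
readBlastTab <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 12L) stop("expected 12-column BLAST outfmt 6 input")
  names(df)[1:12] <- c("query_id", "subject_id", "pct_identity",
                       "aln_length", "mismatches", "gap_opens",
                       "q_start", "q_end", "s_start", "s_end",
                       "evalue", "bit_score")
  df
}

#' Select the best alignment hit per query
#'
#' Hits above the e-value ceiling are discarded; among the survivors of each
#' query the unique best hit is chosen by descending bit score, then
#' ascending e-value, then descending percent identity, then descending
#' alignment length, with the lexicographically smallest subject id as the
#' final (total-order) tie break. The selection is invariant under input row
#' permutation.
#'
#' @param hits data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_length}, \code{evalue},
#'   \code{bit_score} (see [readBlastTab()]).
#' @param evalueMax e-value ceiling (default 1e-10).
#' @return data.frame with at most one row per surviving query, ordered by
#'   query id.
#' @export
bestHits <- function(hits, evalueMax = 1e-10) {
  keep <- hits[hits$evalue <= evalueMax, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  ord <- order(keep$query_id, -keep$bit_score, keep$evalue,
               -keep$pct_identity, -keep$aln_length, keep$subject_id)
  keep <- keep[ord, , drop = FALSE]
  out <- keep[!duplicated(keep$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Roll up co-localization counts by trait category
#'
#' Maps each QTL's trait to a category and totals the per-QTL gene counts per
#' category, with percentages of the grand total ([percentageReport()]
#' convention). Unmapped traits fall into \code{"other"} with a warning.
#'
#' @param perQTL data.frame with columns \code{qtl_id}, \code{trait},
#'   \code{count} — either \code{colocalize()$perQTL} or a table of known
#'   per-QTL totals.
#' @param traitCategories named character vector: trait -> category.
#' @param decimals decimal places for percentages (default 1).
#' @return data.frame with columns \code{category}, \code{count},
#'   \code{pct}; attribute \code{"total"} carries the grand total.
#' @export
summarizeByTrait <- function(perQTL, traitCategories, decimals = 1) {
  cat <- unname(traitCategories[perQTL$trait])
  if (any(is.na(cat))) {
    warning("unmapped trait(s) assigned to 'other': ",
            paste(unique(perQTL$trait[is.na(cat)]), collapse = ", "))
    cat[is.na(cat)] <- "other"
  }
  counts <- tapply(perQTL$count, cat, sum)
  total <- sum(perQTL$count)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    pct = percentageReport(as.integer(counts), total,
                                           decimals),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  out
}
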