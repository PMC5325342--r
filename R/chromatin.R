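#' Strand-aware promoter windows
#'
#' The promoter of a gene is the \code{upstream_bp} window immediately
#' upstream of its transcription start site, ending at (and excluding) the
#' TSS base: for a + strand gene at [s, e) this is [s - upstream_bp, s); for
#' a - strand gene, [e, e + upstream_bp). Windows are clipped at the
#' chromosome origin.
#'
#' @param annotation \code{GRanges} gene annotation (strand required for
#'   every gene).
#' @param upstream_bp window size in bp upstream of the TSS (default 1000).
#' @return \code{GRanges} of promoter windows named by gene id, carrying a
#'   \code{gene_id} metadata column.
#' @export
promoterWindows <- function(annotation, upstream_bp = 1000) {
  st <- as.character(GenomicRanges::strand(annotation))
  if (any(st == "*"))
    stop("strand unknown for gene(s): ",
         paste(annotation$gene_id[st == "*"], collapse = ", "))
  prom <- suppressWarnings(
    GenomicRanges::promoters(annotation, upstream = upstream_bp, downstream = 0))
  prom <- GenomicRanges::restrict(prom, start = 1L)
  names(prom) <- prom$gene_id
  prom
}

#' Promoter overlap calls against a region set
#'
#' A promoter is called euchromatinized when at least one ChIP-enriched
#' region overlaps it by \code{min_overlap_bp} or more. Overlap follows the
#' half-open BED semantics of the inputs: regions merely touching a window
#' boundary do not overlap it.
#'
#' @param promoters \code{GRanges} from \code{\link{promoterWindows}}.
#' @param regions \code{GRanges} of enriched regions (one sample).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return Named logical vector, one entry per promoter/gene.
#' @export
overlapCalls <- function(promoters, regions, min_overlap_bp = 1) {
  extra <- setdiff(as.character(unique(GenomicRanges::seqnames(regions))),
                   as.character(unique(GenomicRanges::seqnames(promoters))))
  if (length(extra))
    warning("region chromosome(s) absent from annotation, ignored: ",
            paste(extra, collapse = ", "))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    promoters, regions, minoverlap = min_overlap_bp, ignore.strand = TRUE))
  out <- logical(length(promoters))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  names(out) <- names(promoters)
  out
}

#' Per-gene, per-cell-line promoter euchromatinization matrix
#'
#' Applies \code{\link{overlapCalls}} to one treated-vs-naive enriched
#' region set per cell line, yielding a complete genes x lines logical
#' matrix ("euchromatinized" = an enriched region overlaps the promoter
#' window).
#'
#' @param region_sets named list of \code{GRanges}, one per cell line.
#' @param annotation \code{GRanges} gene annotation.
#' @param upstream_bp promoter window size (default 1000).
#' @param min_overlap_bp minimum overlap (default 1).
#' @return Logical matrix, genes x cell lines, with a \code{params}
#'   attribute recording the window and overlap settings.
#' @export
euchromatinMatrix <- function(region_sets, annotation, upstream_bp = 1000,
                              min_overlap_bp = 1) {
  if (is.null(names(region_sets)) || any(!nzchar(names(region_sets))))
    stop("region_sets must be named by cell line")
  if (anyDuplicated(names(region_sets)))
    stop("duplicate cell line(s): ",
         paste(unique(names(region_sets)[duplicated(names(region_sets))]),
               collapse = ", "))
  prom <- promoterWindows(annotation, upstream_bp)
  calls <- vapply(region_sets, function(rs)
    overlapCalls(prom, rs, min_overlap_bp), logical(length(prom)))
  if (is.null(dim(calls)))
    calls <- matrix(calls, nrow = length(prom),
                    dimnames = list(names(prom), names(region_sets)))
  rownames(calls) <- names(prom)
  attr(calls, "params") <- list(upstream_bp = upstream_bp,
                                min_overlap_bp = min_overlap_bp)
  calls
}
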