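#' @importFrom GenomicRanges GRanges seqnames start end strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

.readTsvBody <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a count matrix with sample metadata
#'
#' The matrix TSV has a header of sample ids and gene ids in the first
#' column; the metadata TSV has columns \code{sample_id}, \code{cell_line},
#' \code{lineage}, \code{condition} and \code{library_size}. Lines starting
#' with \code{#} are ignored in both files. Sample order of the result
#' follows the metadata file.
#'
#' @param path count matrix TSV.
#' @param meta_path sample metadata TSV.
#' @param library_sizes_from \code{"metadata"} (default; total mapped reads,
#'   which may exceed the annotated-gene column sums) or \code{"colsums"} to
#'   fall back to column sums.
#' @return A \linkS4class{CountSet}.
#' @export
readCountMatrix <- function(path, meta_path,
                            library_sizes_from = c("metadata", "colsums")) {
  library_sizes_from <- match.arg(library_sizes_from)
  tab <- .readTsvBody(path)
  if (ncol(tab) < 2) stop("count matrix needs a gene-id column and >= 1 sample")
  gene_ids <- tab[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  }
  storage.mode(num) <- "integer"
  rownames(num) <- gene_ids
  meta <- .readTsvBody(meta_path)
  need <- c("sample_id", "cell_line", "lineage", "condition", "library_size")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta$library_size <- as.numeric(meta$library_size)
  if (library_sizes_from == "colsums")
    meta$library_size <- colSums(num)[meta$sample_id]
  CountSet(num, meta)
}

#' Write a CountSet to a count TSV and a metadata TSV
#'
#' @param x a \linkS4class{CountSet}.
#' @param path,meta_path output TSV paths.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(x, path, meta_path) {
  cnt <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(cnt), cnt, check.names = FALSE)
  .writeTsv(df, path)
  .writeTsv(as.data.frame(SummarizedExperiment::colData(x)), meta_path)
  invisible(path)
}

#' Read gene annotation from a 6-column TSV
#'
#' Columns: \code{gene_id}, \code{chrom}, \code{start}, \code{end} (0-based
#' half-open, as in BED), \code{strand} (+/-), \code{exonic_length}. The
#' result is a \link[GenomicRanges]{GRanges} (1-based closed internally, the
#' Bioconductor convention) carrying \code{gene_id} and \code{exonic_length}
#' metadata columns; writing it back with \code{\link{writeGeneAnnotation}}
#' restores the original 0-based coordinates bit-exactly.
#'
#' @param path annotation TSV.
#' @return A \code{GRanges}, named by gene id.
#' @export
readGeneAnnotation <- function(path) {
  tab <- .readTsvBody(path)
  need <- c("gene_id", "chrom", "start", "end", "strand", "exonic_length")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  start0 <- as.numeric(tab$start); end0 <- as.numeric(tab$end)
  if (any(is.na(start0)) || any(is.na(end0))) stop("non-numeric coordinate in annotation")
  bad <- start0 >= end0
  if (any(bad)) stop("start >= end for gene(s): ",
                     paste(tab$gene_id[bad], collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id(s) in annotation")
  if (!all(tab$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every gene; offending: ",
         paste(tab$gene_id[!tab$strand %in% c("+", "-")], collapse = ", "))
  len <- as.numeric(tab$exonic_length)
  if (any(is.na(len)) || any(len <= 0)) stop("exonic_length must be positive")
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(start0 + 1, end0),
                               strand = tab$strand,
                               gene_id = tab$gene_id,
                               exonic_length = as.integer(len))
  names(gr) <- tab$gene_id
  gr
}

#' Write gene annotation to the 6-column TSV format
#'
#' @param annotation a \code{GRanges} as returned by
#'   \code{\link{readGeneAnnotation}} or \code{\link{simAnnotation}}.
#' @param path output TSV path.
#' @export
writeGeneAnnotation <- function(annotation, path) {
  df <- data.frame(gene_id = annotation$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(annotation)),
                   start = GenomicRanges::start(annotation) - 1L,
                   end = GenomicRanges::end(annotation),
                   strand = as.character(GenomicRanges::strand(annotation)),
                   exonic_length = annotation$exonic_length)
  .writeTsv(df, path)
}

#' Read ChIP-enriched regions from a BED3+ file
#'
#' Track, browser and \code{#} comment lines are tolerated. Coordinates are
#' validated (numeric, start < end) with the offending line number reported.
#' Overlapping intervals are kept as given (no merging). An optional fifth
#' BED column is carried as a \code{score} metadata column.
#'
#' @param path BED file path.
#' @param sample_id optional sample label stored in \code{metadata()}.
#' @return A \code{GRanges} (1-based closed; BED's 0-based half-open
#'   intervals are converted on read and restored on write).
#' @export
readRegions <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(GenomicRanges::GRanges())
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", idx[which(nf < 3)[1]], ": fewer than 3 BED fields")
  chrom <- vapply(fields, `[`, "", 1)
  s0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  e0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (anyNA(s0) || anyNA(e0))
    stop("line ", idx[which(is.na(s0) | is.na(e0))[1]], ": non-numeric coordinate")
  if (any(s0 >= e0))
    stop("line ", idx[which(s0 >= e0)[1]], ": start >= end")
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0), score = score)
  if (!is.null(sample_id)) S4Vectors::metadata(gr)$sample_id <- sample_id
  gr
}

#' Write regions to BED
#'
#' Intervals are written 0-based half-open; \code{score} is emitted as BED
#' column 5 when present (with a "." name column).
#'
#' @param regions a \code{GRanges}.
#' @param path output BED path.
#' @export
writeRegionsBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions))
  sc <- GenomicRanges::mcols(regions)$score
  if (!is.null(sc) && !all(is.na(sc))) {
    df$name <- "."
    df$score <- ifelse(is.na(sc), 0, sc)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members. Duplicate members
#' within a line are dropped with a warning; duplicate set names are an
#' error; lines with fewer than 3 fields are an error.
#'
#' @param path GMT file path.
#' @param universe,universe_size optional universe declaration passed to
#'   \code{\link{GeneSetCollection}}.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, universe = character(0), universe_size = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT line ", which(nf < 3)[1], ": fewer than 3 fields")
  nm <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in set '", f[1], "' deduplicated", call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  GeneSetCollection(sets, universe = universe, universe_size = universe_size)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output GMT path.
#' @param description description field written for every set (column 2).
#' @export
writeGMT <- function(x, path, description = "na") {
  lines <- vapply(names(x@sets), function(nm) {
    paste(c(nm, description, x@sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a dose-response plate table (CSV)
#'
#' Expected columns: \code{cell_line}, \code{vpa_status} (\code{naive} or
#' \code{treated}), \code{concentration} (uM; 0 for no-drug control wells),
#' \code{replicate}, \code{fluorescence} (positive).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
readDoseResponse <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("cell_line", "vpa_status", "concentration", "replicate", "fluorescence")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("dose-response table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(tab$vpa_status %in% c("naive", "treated")))
    stop("vpa_status must be 'naive' or 'treated'")
  if (any(is.na(tab$concentration)) || any(tab$concentration < 0))
    stop("concentration must be >= 0 (0 = control wells)")
  .assertPositive(tab$fluorescence, "fluorescence")
  tab
}
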