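#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' CountSet: gene-level read counts for an unreplicated treatment panel
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding one integer
#' count assay (\code{"counts"}) for a panel of cell lines profiled once per
#' condition (VPA-naive and VPA-treated), with per-sample library sizes
#' carried in \code{colData}. Library sizes are the total mapped reads of
#' each sample and may exceed the column sums (reads mapping outside
#' annotated genes still count towards the sequencing depth used by RPKM and
#' the Audic-Claverie test).
#'
#' Required \code{colData} columns: \code{sample_id}, \code{cell_line},
#' \code{lineage} (\code{"adherent"} or \code{"stem"}), \code{condition}
#' (\code{"naive"} or \code{"vpa"}), \code{library_size}.
#'
#' @aliases CountSet-class
#' @exportClass CountSet
setClass("CountSet", contains = "SummarizedExperiment")

.validCountSet <- function(object) {
  msg <- character()
  cnt <- SummarizedExperiment::assay(object, "counts")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "cell_line", "lineage", "condition", "library_size")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (anyDuplicated(rownames(cnt)))
    msg <- c(msg, "duplicate gene ids")
  if (!length(msg)) {
    if (!all(cd$lineage %in% c("adherent", "stem")))
      msg <- c(msg, "lineage must be 'adherent' or 'stem'")
    if (!all(cd$condition %in% c("naive", "vpa")))
      msg <- c(msg, "condition must be 'naive' or 'vpa'")
    if (any(cd$library_size <= 0) || any(cd$library_size != round(cd$library_size)))
      msg <- c(msg, "library_size must be positive integers")
    if (anyDuplicated(paste(cd$cell_line, cd$condition)))
      msg <- c(msg, "duplicate (cell_line, condition) pair")
  }
  if (length(msg)) msg else TRUE
}
setValidity("CountSet", .validCountSet)

#' Construct a CountSet
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames.
#' @param meta data.frame with one row per sample: \code{sample_id},
#'   \code{cell_line}, \code{lineage}, \code{condition}, \code{library_size}.
#'   Sample order of the result follows \code{meta}.
#' @return A \linkS4class{CountSet}.
#' @examples
#' m <- matrix(c(5L, 0L, 7L, 2L), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"), cell_line = "U1",
#'                    lineage = "adherent", condition = c("naive", "vpa"),
#'                    library_size = c(1e6, 2e6))
#' CountSet(m, meta)
#' @export
CountSet <- function(counts, meta) {
  stopifnot(is.matrix(counts))
  meta <- as.data.frame(meta)
  if (!all(colnames(counts) %in% meta$sample_id))
    stop("sample(s) in count matrix missing from metadata: ",
         paste(setdiff(colnames(counts), meta$sample_id), collapse = ", "))
  if (!all(meta$sample_id %in% colnames(counts)))
    stop("sample(s) in metadata missing from count matrix: ",
         paste(setdiff(meta$sample_id, colnames(counts)), collapse = ", "))
  counts <- counts[, meta$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  cd <- S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("CountSet", se)
}

#' @describeIn CountSet library sizes (total mapped reads) per sample
#' @param x a CountSet
#' @export
librarySizes <- function(x) {
  ls <- SummarizedExperiment::colData(x)$library_size
  names(ls) <- colnames(x)
  ls
}

#' @describeIn CountSet cell line of each sample
#' @export
cellLines <- function(x) SummarizedExperiment::colData(x)$cell_line

#' @describeIn CountSet lineage (adherent/stem) of each sample
#' @export
lineages <- function(x) SummarizedExperiment::colData(x)$lineage

#' @describeIn CountSet treatment condition (naive/vpa) of each sample
#' @export
sampleConditions <- function(x) SummarizedExperiment::colData(x)$condition

setMethod("show", "CountSet", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CountSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  cell lines:", length(unique(cd$cell_line)),
      sprintf("(%d adherent, %d stem)",
              length(unique(cd$cell_line[cd$lineage == "adherent"])),
              length(unique(cd$cell_line[cd$lineage == "stem"]))), "\n")
  cat("  library sizes:", paste(range(cd$library_size), collapse = " - "), "\n")
})

#' GeneSetCollection: named gene sets with an optional universe
#'
#' Holds named sets of gene identifiers (as read from a GMT file) together
#' with an optional gene universe, given either as an explicit id list or as
#' a bare universe size (the annotation universes of genome browsers are
#' rarely distributed as id lists).
#'
#' @slot sets named list of character vectors, each with unique members.
#' @slot universe character vector of gene ids, or empty if unknown.
#' @slot universeSize integer; \code{NA} when no universe is declared.
#' @aliases GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character",
                        universeSize = "integer"),
         prototype(sets = list(), universe = character(0),
                   universeSize = NA_integer_))

.validGSC <- function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must be uniquely named")
  if (any(vapply(object@sets, anyDuplicated, 0L) > 0))
    msg <- c(msg, "set members must be unique within a set")
  if (length(object@universe)) {
    out <- vapply(object@sets, function(s) any(!s %in% object@universe), TRUE)
    if (any(out))
      msg <- c(msg, paste0("set(s) not contained in universe: ",
                           paste(names(object@sets)[out], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GeneSetCollection", .validGSC)

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors.
#' @param universe optional character vector of gene ids (a superset of every
#'   set).
#' @param universe_size optional integer universe size, for when the id list
#'   is not available.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, universe = character(0),
                              universe_size = NA_integer_) {
  if (length(universe) && is.na(universe_size))
    universe_size <- length(unique(universe))
  new("GeneSetCollection", sets = sets, universe = as.character(universe),
      universeSize = as.integer(universe_size))
}

#' @describeIn GeneSetCollection the named list of sets
#' @param x a GeneSetCollection
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection declared universe size (NA if none)
#' @export
universeSize <- function(x) {
  if (length(x@universe)) length(unique(x@universe)) else x@universeSize
}

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "set(s)\n")
  sz <- vapply(object@sets, length, 0L)
  if (length(sz)) cat("  sizes:", paste(range(sz), collapse = " - "), "\n")
  us <- universeSize(object)
  cat("  universe:", if (is.na(us)) "undeclared" else us, "\n")
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' ConsensusSignature: genes with two-lineage majority support
#'
#' Result of cross-line consensus filtering: the genes called up-regulated
#' (adjusted p below threshold, fold change at or above the cutoff) in at
#' least \code{min_support} cell lines of \emph{both} lineages, with the
#' per-gene support counts.
#'
#' @slot genes character vector of signature members.
#' @slot support data.frame with columns \code{gene_id},
#'   \code{n_adherent_up}, \code{n_stem_up} for all genes tested.
#' @slot fcCutoff numeric fold-change cutoff defining this tier.
#' @slot params list of the filtering parameters used.
#' @aliases ConsensusSignature-class
#' @exportClass ConsensusSignature
setClass("ConsensusSignature",
         representation(genes = "character", support = "data.frame",
                        fcCutoff = "numeric", params = "list"))

setMethod("show", "ConsensusSignature", function(object) {
  p <- object@params
  cat("ConsensusSignature:", length(object@genes), "gene(s) at fold change >=",
      object@fcCutoff, "\n")
  cat(sprintf("  rule: up in >= %d of %d adherent AND >= %d of %d stem lines (q < %g)\n",
              p$min_support, p$n_adherent, p$min_support, p$n_stem, p$q_thresh))
})

setMethod("length", "ConsensusSignature", function(x) length(x@genes))

#' @describeIn ConsensusSignature member gene ids
#' @param x a ConsensusSignature
#' @export
signatureGenes <- function(x) x@genes

#' @describeIn ConsensusSignature per-gene lineage support counts
#' @export
supportCounts <- function(x) x@support
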