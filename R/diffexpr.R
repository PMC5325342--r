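#' @useDynLib glioVPA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Audic-Claverie conditional probability
#'
#' Probability of observing \code{y} reads for a gene in a library of
#' \code{N2} total reads given \code{x} reads in a library of \code{N1},
#' under the null hypothesis of equal underlying expression:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.}
#' Evaluated in log space (lgamma) to avoid factorial overflow. For fixed
#' \code{x} the probabilities over all \code{y} sum to one.
#'
#' @param y,x observed counts (non-negative integers; vectorized, recycled).
#' @param N1,N2 library sizes (total mapped reads, positive).
#' @return Probabilities in (0, 1].
#' @examples
#' acConditional(1, 2, 1e6, 1e6)  # choose(3,2)/2^4 = 0.1875
#' @export
acConditional <- function(y, x, N1, N2) {
  .assertCount(x, "x"); .assertCount(y, "y")
  .assertPositive(N1, "N1"); .assertPositive(N2, "N2")
  n <- max(length(x), length(y), length(N1), length(N2))
  .ac_conditional_cpp(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
                      rep_len(as.numeric(N1), n), rep_len(as.numeric(N2), n))
}

#' Audic-Claverie tail p-value
#'
#' Tail probability of the conditional distribution
#' \code{\link{acConditional}}: \code{"up"} sums \eqn{y' \ge y} (evidence
#' for higher expression in library 2), \code{"down"} sums \eqn{y' \le y},
#' \code{"two_sided"} doubles the smaller tail (capped at 1).
#'
#' @inheritParams acConditional
#' @param alternative tail to sum.
#' @return p-values in (0, 1].
#' @examples
#' acPValue(0, 0, 1e6, 1e6, "up")  # full tail: 1
#' @export
acPValue <- function(x, y, N1, N2,
                     alternative = c("up", "down", "two_sided")) {
  alternative <- match.arg(alternative)
  .assertCount(x, "x"); .assertCount(y, "y")
  .assertPositive(N1, "N1"); .assertPositive(N2, "N2")
  n <- max(length(x), length(y), length(N1), length(N2))
  alt <- match(alternative, c("up", "down", "two_sided"))
  .ac_pvalue_cpp(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
                 rep_len(as.numeric(N1), n), rep_len(as.numeric(N2), n), alt)
}

#' RPKM expression values
#'
#' Reads per kilobase of exon per million mapped reads:
#' \code{count * 1e9 / (exonic_length * library_size)}.
#'
#' @param x a \linkS4class{CountSet}.
#' @param annotation \code{GRanges} with \code{gene_id} and
#'   \code{exonic_length} metadata columns covering every counted gene.
#' @return Numeric matrix, genes x samples.
#' @export
rpkm <- function(x, annotation) {
  ls <- librarySizes(x)
  if (any(ls <= 0)) stop("zero or negative library size")
  cnt <- SummarizedExperiment::assay(x, "counts")
  miss <- setdiff(rownames(cnt), annotation$gene_id)
  if (length(miss))
    stop("missing annotation for gene(s): ", paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10))
  len <- annotation$exonic_length[match(rownames(cnt), annotation$gene_id)]
  cnt * 1e9 / (len * rep(ls, each = nrow(cnt)))
}

#' Normalized fold change on counts-per-million with a pseudocount
#'
#' \code{fc = (cpm(y) + pseudo) / (cpm(x) + pseudo)}, where
#' \code{cpm(x) = 1e6 * x / N1}. The pseudocount (in CPM units) keeps the
#' ratio defined at zero counts and shrinks extreme ratios toward 1.
#'
#' @inheritParams acConditional
#' @param pseudo pseudocount in CPM (default 0.5). Must be positive when a
#'   zero naive count is admissible.
#' @return Fold changes (treated / naive).
#' @export
foldChange <- function(x, y, N1, N2, pseudo = 0.5) {
  .assertCount(x, "x"); .assertCount(y, "y")
  .assertPositive(N1, "N1"); .assertPositive(N2, "N2")
  if (pseudo < 0) stop("pseudo must be >= 0")
  if (pseudo == 0 && any(x == 0))
    stop("x = 0 with pseudo = 0: fold change undefined")
  (y / N2 * 1e6 + pseudo) / (x / N1 * 1e6 + pseudo)
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around \code{stats::p.adjust(method = "BH")}.
#'
#' @param p p-values in (0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-cell-line pairwise differential expression (treated vs naive)
#'
#' Audic-Claverie test of the VPA-treated against the VPA-naive sample of
#' one cell line, BH-adjusted across all genes of that line. \code{direction}
#' is \code{"up"} when \code{q < alpha} and \code{fc > 1}, \code{"down"}
#' when \code{q < alpha} and \code{fc < 1}, else \code{"none"} (with the
#' default one-sided \code{"up"} alternative, down-regulation is by
#' construction never significant; use \code{"two_sided"} or \code{"down"}
#' to call it).
#'
#' @param x a \linkS4class{CountSet}.
#' @param cell_line cell line to test (must have exactly one naive and one
#'   vpa sample).
#' @param alpha adjusted-p threshold (default 0.01).
#' @param pseudo_cpm pseudocount for \code{\link{foldChange}}.
#' @param alternative test sidedness (default \code{"up"}).
#' @return data.frame: gene_id, cell_line, x (naive count), y (treated
#'   count), N1, N2, fc, p_raw, q, direction.
#' @export
differentialTable <- function(x, cell_line, alpha = 0.01, pseudo_cpm = 0.5,
                              alternative = c("up", "down", "two_sided")) {
  alternative <- match.arg(alternative)
  cd <- SummarizedExperiment::colData(x)
  i_n <- which(cd$cell_line == cell_line & cd$condition == "naive")
  i_v <- which(cd$cell_line == cell_line & cd$condition == "vpa")
  if (length(i_n) != 1 || length(i_v) != 1)
    stop("cell line '", cell_line, "' must have exactly one naive and one vpa sample")
  cnt <- SummarizedExperiment::assay(x, "counts")
  if (nrow(cnt) == 0) stop("count matrix has no genes")
  xn <- cnt[, i_n]; yv <- cnt[, i_v]
  N1 <- cd$library_size[i_n]; N2 <- cd$library_size[i_v]
  p <- acPValue(xn, yv, N1, N2, alternative)
  q <- bhAdjust(p)
  fc <- foldChange(xn, yv, N1, N2, pseudo_cpm)
  direction <- rep("none", nrow(cnt))
  direction[q < alpha & fc > 1] <- "up"
  direction[q < alpha & fc < 1] <- "down"
  data.frame(gene_id = rownames(cnt), cell_line = cell_line,
             x = unname(xn), y = unname(yv), N1 = N1, N2 = N2,
             fc = unname(fc), p_raw = unname(p), q = unname(q),
             direction = direction, row.names = NULL)
}

#' Differential tables for every cell line in a panel
#'
#' @inheritParams differentialTable
#' @return Named list of per-line data.frames (see
#'   \code{\link{differentialTable}}), with a \code{"lineage"} attribute
#'   mapping cell line to lineage.
#' @export
differentialTables <- function(x, alpha = 0.01, pseudo_cpm = 0.5,
                               alternative = c("up", "down", "two_sided")) {
  alternative <- match.arg(alternative)
  cd <- SummarizedExperiment::colData(x)
  lines <- unique(cd$cell_line)
  out <- lapply(lines, function(cl)
    differentialTable(x, cl, alpha, pseudo_cpm, alternative))
  names(out) <- lines
  attr(out, "lineage") <- stats::setNames(
    cd$lineage[match(lines, cd$cell_line)], lines)
  out
}

#' PCA on the most variable genes
#'
#' Genes are ranked by cross-sample variance of \code{log2(RPKM + 1)} (or of
#' the raw values with \code{log_transform = FALSE}); the top \code{n_top}
#' are retained and samples are projected by centered PCA. Ties in the
#' variance ranking are broken by gene id (lexicographic); each component's
#' sign is fixed so that its largest-magnitude loading is positive.
#'
#' @param expr numeric expression matrix (genes x samples), e.g. from
#'   \code{\link{rpkm}}.
#' @param n_top number of most-variable genes to keep (default 1800).
#' @param log_transform apply \code{log2(x + 1)} first (default TRUE).
#' @return list with \code{scores} (samples x PC), \code{loadings} (genes x
#'   PC), \code{variance_explained} (fractions, non-increasing) and
#'   \code{genes} (the genes used).
#' @export
pcaTopVariable <- function(expr, n_top = 1800, log_transform = TRUE) {
  if (ncol(expr) < 2) stop("PCA needs at least 2 samples")
  if (n_top > nrow(expr)) stop("n_top exceeds the number of genes")
  m <- if (log_transform) log2(expr + 1) else expr
  v <- apply(m, 1, stats::var)
  ord <- order(-v, rownames(m))
  keep <- ord[seq_len(n_top)]
  sub <- m[keep, , drop = FALSE]
  if (all(apply(sub, 1, stats::var) == 0))
    stop("selected genes have zero variance; PCA is degenerate")
  pc <- stats::prcomp(t(sub), center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, TRUE)
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = ve, genes = rownames(sub))
}
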