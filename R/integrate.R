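.lineageOf <- function(de_tables, lineage_of = NULL) {
  lin <- lineage_of %||% attr(de_tables, "lineage")
  if (is.null(lin))
    stop("lineage mapping required: pass 'lineage_of' or use differentialTables()")
  miss <- setdiff(names(de_tables), names(lin))
  if (length(miss))
    stop("no lineage declared for cell line(s): ", paste(miss, collapse = ", "))
  lin[names(de_tables)]
}

.upCallMatrix <- function(de_tables, q_thresh, fc_cutoff) {
  genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  calls <- vapply(de_tables, function(tab) {
    up <- tab$direction == "up" & tab$q < q_thresh & tab$fc >= fc_cutoff
    # genes absent from a line's table count as non-supporting
    out <- logical(length(genes))
    out[match(tab$gene_id[up], genes)] <- TRUE
    out
  }, logical(length(genes)))
  rownames(calls) <- genes
  calls
}

.lineageSupport <- function(calls, lineage) {
  lineage <- lineage[colnames(calls)]
  cbind(n_adherent_up = rowSums(calls[, lineage == "adherent", drop = FALSE]),
        n_stem_up = rowSums(calls[, lineage == "stem", drop = FALSE]))
}

#' Cross-line consensus of up-regulated genes
#'
#' A gene enters the consensus signature when it is called up-regulated
#' (\code{direction == "up"}, \code{q < q_thresh}, \code{fc >= fc_cutoff})
#' in at least \code{min_support} cell lines of \emph{both} the adherent and
#' the stem lineage — the two-lineage majority rule used to narrow
#' per-line hit lists down to a robust treatment signature.
#'
#' @param de_tables named list of per-line tables from
#'   \code{\link{differentialTable}} (or \code{\link{differentialTables}},
#'   which also carries the lineage mapping).
#' @param fc_cutoff fold-change cutoff defining the tier.
#' @param q_thresh adjusted-p threshold (default 0.01).
#' @param min_support minimum supporting lines per lineage (default 4).
#' @param lineage_of optional named character vector, cell line -> lineage.
#' @return A \linkS4class{ConsensusSignature}.
#' @export
consensusUpregulated <- function(de_tables, fc_cutoff, q_thresh = 0.01,
                                 min_support = 4, lineage_of = NULL) {
  lin <- .lineageOf(de_tables, lineage_of)
  n_adh <- sum(lin == "adherent"); n_stem <- sum(lin == "stem")
  if (n_adh < min_support || n_stem < min_support)
    stop(sprintf("min_support = %d exceeds lineage size (%d adherent, %d stem)",
                 min_support, n_adh, n_stem))
  calls <- .upCallMatrix(de_tables, q_thresh, fc_cutoff)
  sup <- .lineageSupport(calls, lin)
  keep <- sup[, "n_adherent_up"] >= min_support & sup[, "n_stem_up"] >= min_support
  new("ConsensusSignature",
      genes = rownames(calls)[keep],
      support = data.frame(gene_id = rownames(calls), sup, row.names = NULL),
      fcCutoff = fc_cutoff,
      params = list(q_thresh = q_thresh, min_support = min_support,
                    n_adherent = n_adh, n_stem = n_stem))
}

#' Fold-change tier table with euchromatin intersection
#'
#' Builds the consensus signature at each fold-change cutoff and, when a
#' promoter euchromatinization matrix is supplied, intersects each tier with
#' the genes whose promoters are euchromatinized under the same
#' two-lineage majority rule (at least \code{min_support} TRUE calls in both
#' lineages). Signatures are nested: the list at a stricter cutoff is a
#' subset of the list at any looser one.
#'
#' @inheritParams consensusUpregulated
#' @param euchromatin optional logical genes x cell-lines matrix from
#'   \code{\link{euchromatinMatrix}}; must cover every gene in the tables.
#' @param cutoffs strictly decreasing fold-change cutoffs (default 5,4,3,2).
#' @return list with \code{table} (data.frame: fc_cutoff, n_consensus,
#'   n_euchromatin_consensus, n_intersect), \code{genes} and
#'   \code{intersect_genes} (per-tier gene lists), and
#'   \code{euchromatin_genes}.
#' @export
fcTierTable <- function(de_tables, euchromatin = NULL, cutoffs = c(5, 4, 3, 2),
                        q_thresh = 0.01, min_support = 4, lineage_of = NULL) {
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly decreasing")
  lin <- .lineageOf(de_tables, lineage_of)
  sigs <- lapply(cutoffs, function(fc)
    consensusUpregulated(de_tables, fc, q_thresh, min_support, lineage_of = lin))
  genes <- lapply(sigs, signatureGenes)
  names(genes) <- paste0("fc_ge_", cutoffs)
  euch_genes <- character(0)
  if (!is.null(euchromatin)) {
    all_genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
    miss <- setdiff(all_genes, rownames(euchromatin))
    if (length(miss))
      stop("euchromatin matrix lacks gene(s) present in DE tables: ",
           paste(utils::head(miss, 10), collapse = ", "))
    elin <- lin[colnames(euchromatin)]
    if (anyNA(elin))
      stop("euchromatin matrix column(s) without declared lineage")
    e_adh <- rowSums(euchromatin[, elin == "adherent", drop = FALSE])
    e_stem <- rowSums(euchromatin[, elin == "stem", drop = FALSE])
    euch_genes <- rownames(euchromatin)[e_adh >= min_support & e_stem >= min_support]
  }
  inter <- lapply(genes, intersect, y = euch_genes)
  list(table = data.frame(
         fc_cutoff = cutoffs,
         n_consensus = lengths(genes),
         n_euchromatin_consensus = length(euch_genes),
         n_intersect = lengths(inter), row.names = NULL),
       genes = genes, intersect_genes = inter, euchromatin_genes = euch_genes)
}

#' Enrichment test on counts
#'
#' Tests whether a candidate list of \code{n} genes containing \code{k}
#' family members is enriched for a family of \code{K} members in an
#' \code{N}-gene universe. The default \code{"genome"} convention is
#' Fisher's exact test on the table \code{[[k, K], [n - k, N - K]]},
#' comparing the list against the whole genome (the genome column is not
#' reduced by the list). The \code{"draw"} convention instead treats the
#' list as a draw of \code{n} from the universe,
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)}, and uses its tail. Both are
#' exact; they differ slightly because the genome convention counts the
#' list twice (once in each column).
#'
#' @param k family members in the list.
#' @param n list size.
#' @param K family size in the universe.
#' @param N universe size.
#' @param sided \code{"greater"} (enrichment tail, default) or
#'   \code{"two_sided"} (sum of point probabilities no larger than the
#'   observed one).
#' @param convention \code{"genome"} or \code{"draw"} (see Details).
#' @return One-row data.frame: k, n, K, N, expected (\code{n*K/N}),
#'   odds_ratio, p.
#' @examples
#' enrichmentTest(16, 497, 397, 46111)  # p ~ 1.18e-5
#' @export
enrichmentTest <- function(k, n, K, N, sided = c("greater", "two_sided"),
                           convention = c("genome", "draw")) {
  sided <- match.arg(sided); convention <- match.arg(convention)
  .assertCount(c(k, n, K, N), "k, n, K, N")
  if (n > N || K > N) stop("n and K must not exceed N")
  if (k > min(n, K)) stop("inconsistent counts: k > min(n, K)")
  if (convention == "genome") {
    # margins of [[k, K], [n-k, N-K]]: row1 = k+K, row2 = (n-k)+(N-K), col1 = n
    m <- k + K; mm <- (n - k) + (N - K)
    if (sided == "greater") {
      p <- stats::phyper(k - 1, m, mm, n, lower.tail = FALSE)
    } else {
      lo <- max(0, n - mm); hi <- min(n, m)
      d <- stats::dhyper(lo:hi, m, mm, n)
      p <- sum(d[d <= stats::dhyper(k, m, mm, n) * (1 + 1e-7)])
    }
    or <- (k * (N - K)) / (K * (n - k))
  } else {
    if (sided == "greater") {
      p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      lo <- max(0, n - (N - K)); hi <- min(n, K)
      d <- stats::dhyper(lo:hi, K, N - K, n)
      p <- sum(d[d <= stats::dhyper(k, K, N - K, n) * (1 + 1e-7)])
    }
    or <- (k * (N - K - n + k)) / ((n - k) * (K - k))
  }
  data.frame(k = k, n = n, K = K, N = N, expected = n * K / N,
             odds_ratio = or, p = min(p, 1))
}

#' Gene-family enrichment of a candidate list
#'
#' Gene-list front end to \code{\link{enrichmentTest}}: counts the overlap
#' of a (deduplicated) candidate list with a gene family and tests
#' enrichment against the universe.
#'
#' @param list_genes candidate gene ids (duplicates dropped with a warning).
#' @param family family member gene ids.
#' @param universe optional universe gene ids; when given, list and family
#'   are intersected with it. Otherwise \code{universe_size} must be given.
#' @param universe_size integer universe size (e.g. the annotation's gene
#'   count) when the universe id list is not available.
#' @inheritParams enrichmentTest
#' @return One-row data.frame as in \code{\link{enrichmentTest}}.
#' @export
familyEnrichment <- function(list_genes, family, universe = NULL,
                             universe_size = NULL,
                             sided = c("greater", "two_sided"),
                             convention = c("genome", "draw")) {
  if (anyDuplicated(list_genes)) {
    warning("duplicate gene id(s) in candidate list deduplicated")
    list_genes <- unique(list_genes)
  }
  family <- unique(family)
  if (!is.null(universe)) {
    universe <- unique(universe)
    bad <- setdiff(list_genes, universe)
    if (length(bad))
      stop("candidate gene(s) outside the universe: ",
           paste(utils::head(bad, 10), collapse = ", "))
    family <- intersect(family, universe)
    N <- length(universe)
  } else {
    if (is.null(universe_size)) stop("supply 'universe' or 'universe_size'")
    N <- as.integer(universe_size)
  }
  enrichmentTest(k = length(intersect(list_genes, family)),
                 n = length(list_genes), K = length(family), N = N,
                 sided = sided, convention = convention)
}
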