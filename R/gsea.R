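#' Ranking metric for gene set enrichment
#'
#' Mean log2 fold change across the per-line differential tables, one value
#' per gene (genes missing from a table contribute nothing to its mean;
#' genes absent from every table are dropped with a warning). The result is
#' sorted descending, ties broken lexicographically by gene id so the
#' ranking is deterministic.
#'
#' @param de_tables list of tables from \code{\link{differentialTable}}.
#' @return Named numeric vector, sorted descending.
#' @export
rankingMetric <- function(de_tables) {
  if (!length(de_tables)) stop("at least one differential table required")
  genes <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  acc <- numeric(length(genes)); cnt <- integer(length(genes))
  for (tab in de_tables) {
    i <- match(tab$gene_id, genes)
    acc[i] <- acc[i] + log2(tab$fc)
    cnt[i] <- cnt[i] + 1L
  }
  drop <- cnt == 0L
  if (any(drop)) {
    warning("gene(s) absent from all tables dropped: ",
            paste(utils::head(genes[drop], 5), collapse = ", "))
    genes <- genes[!drop]; acc <- acc[!drop]; cnt <- cnt[!drop]
  }
  metric <- acc / cnt
  names(metric) <- genes
  metric[order(-metric, names(metric))]
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating \eqn{|m_i|^p / N_R} at each gene
#' set hit (with \eqn{N_R} the sum of \eqn{|m|^p} over hits) and
#' \eqn{1/(N - N_h)} at each miss; the enrichment score is the running-sum
#' deviation of largest magnitude. \code{exponent = 0} gives the unweighted
#' Kolmogorov-Smirnov-like statistic; \code{exponent = 1} (default) weights
#' hits by their metric.
#'
#' @param ranked named numeric metric, sorted descending (see
#'   \code{\link{rankingMetric}}).
#' @param gene_set character vector of set members.
#' @param exponent hit-weighting exponent p (default 1).
#' @return list with \code{es}, \code{running_sum} (length N) and
#'   \code{hit_positions}.
#' @export
enrichmentScore <- function(ranked, gene_set, exponent = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% gene_set
  Nh <- sum(hit)
  if (Nh == 0) stop("gene set has no member in the ranked list")
  if (Nh == N) stop("gene set covers the whole ranked list")
  rs <- .runningES(abs(ranked)^exponent, hit)
  es <- rs[which.max(abs(rs))]
  list(es = unname(es), running_sum = unname(rs), hit_positions = which(hit))
}

# running sum P_hit - P_miss from precomputed |metric|^p weights and a hit
# indicator; shared by the observed and the permutation path
.runningES <- function(w, hit) {
  w[!hit] <- 0
  NR <- sum(w)
  p_hit <- if (NR > 0) cumsum(w) / NR else cumsum(hit) / sum(hit)
  p_miss <- cumsum(!hit) / (length(hit) - sum(hit))
  p_hit - p_miss
}

.esOnly <- function(w, hit) {
  rs <- .runningES(w, hit)
  rs[which.max(abs(rs))]
}

# leading edge: hits up to the ES extremum (positive ES) or from it on
# (negative ES)
.leadingEdge <- function(ranked, hit_positions, running_sum, es) {
  peak <- which.max(abs(running_sum))
  idx <- if (es >= 0) hit_positions[hit_positions <= peak]
         else hit_positions[hit_positions >= peak]
  names(ranked)[idx]
}

#' Gene set enrichment analysis with a gene-set permutation null
#'
#' For each set, computes the observed enrichment score, a null of
#' \code{n_perm} random same-size sets drawn from the ranked universe, the
#' normalized enrichment score NES = ES / mean(|null ES| of matching sign),
#' a nominal p with an add-one rule,
#' \eqn{p = (1 + \#\{|ES_{null}| \ge |ES|\}) / (n_{perm} + 1)}
#' (never zero, calibrated under the null), and an FDR q from the pooled
#' sign-matched null NES distribution. Gene-set (not phenotype) permutation
#' is used because an unreplicated one-pair-per-line design has no
#' phenotype labels to permute.
#'
#' @inheritParams enrichmentScore
#' @param collection a \linkS4class{GeneSetCollection} (or named list of
#'   character vectors).
#' @param n_perm number of permutations (at least 100; default 1000).
#' @param seed integer RNG seed; results are reproducible bit-for-bit.
#' @return data.frame: set, size, es, nes, p_nominal, fdr_q, leading_edge
#'   (comma-separated), n_perm, seed.
#' @export
runGSEA <- function(ranked, collection, n_perm = 1000, seed = 1, exponent = 1) {
  sets <- if (is(collection, "GeneSetCollection")) geneSets(collection)
          else collection
  if (n_perm < 100) stop("n_perm must be at least 100")
  N <- length(ranked)
  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), 0L)
  if (any(sizes == 0)) stop("set(s) with no member in the ranked list: ",
                            paste(names(sets)[sizes == 0], collapse = ", "))
  if (any(sizes >= N)) stop("set(s) as large as the ranked universe")
  absw <- abs(ranked)^exponent
  withSeed(seed, {
    obs <- lapply(sets, function(s) enrichmentScore(ranked, s, exponent))
    null_es <- lapply(seq_along(sets), function(j) {
      vapply(seq_len(n_perm), function(i) {
        hit <- logical(N)
        hit[sample.int(N, sizes[j])] <- TRUE
        .esOnly(absw, hit)
      }, 0)
    })
  })
  es <- vapply(obs, `[[`, 0, "es")
  res <- lapply(seq_along(sets), function(j) {
    e <- es[j]; nul <- null_es[[j]]
    same <- nul[sign(nul) == sign(e)]
    mean_same <- mean(abs(same))
    nes <- if (length(same) && mean_same > 0) e / mean_same else NA_real_
    p <- (1 + sum(abs(nul) >= abs(e))) / (n_perm + 1)
    pos_mean <- mean(nul[nul >= 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    nnes <- ifelse(nul >= 0, nul / pos_mean, nul / neg_mean)
    list(nes = nes, p = p, null_nes = nnes)
  })
  nes <- vapply(res, `[[`, 0, "nes")
  pooled <- unlist(lapply(res, `[[`, "null_nes"))
  pooled <- pooled[is.finite(pooled)]
  fdr <- vapply(seq_along(sets), function(j) {
    ne <- nes[j]
    if (!is.finite(ne)) return(NA_real_)
    if (ne >= 0) {
      num_pool <- sum(pooled >= 0)
      num <- if (num_pool) sum(pooled >= ne) / num_pool else 0
      den_pool <- sum(nes >= 0)
      den <- sum(nes >= ne) / den_pool
    } else {
      num_pool <- sum(pooled < 0)
      num <- if (num_pool) sum(pooled <= ne) / num_pool else 0
      den_pool <- sum(nes < 0)
      den <- sum(nes <= ne) / den_pool
    }
    min(1, num / den)
  }, 0)
  le <- vapply(seq_along(sets), function(j)
    paste(.leadingEdge(ranked, obs[[j]]$hit_positions,
                       obs[[j]]$running_sum, es[j]), collapse = ","), "")
  data.frame(set = names(sets), size = sizes, es = es, nes = nes,
             p_nominal = vapply(res, `[[`, 0, "p"), fdr_q = fdr,
             leading_edge = le, n_perm = n_perm, seed = seed,
             row.names = NULL)
}
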