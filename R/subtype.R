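#' Per-sample signature score
#'
#' Mean, over the signature genes present in the matrix, of the per-gene
#' z-scored \code{log2(expr + 1)} values. Genes with zero cross-sample
#' spread carry no information and contribute a z-score of 0. Monotone in
#' signature-gene expression and invariant to uniform affine rescaling of
#' the expression matrix.
#'
#' @param expr numeric expression matrix (genes x samples), e.g. RPKM.
#' @param signature character vector of signature gene ids.
#' @return Named numeric score per sample.
#' @export
signatureScore <- function(expr, signature) {
  if (ncol(expr) < 2) stop("scoring needs at least 2 samples")
  genes <- intersect(rownames(expr), unique(signature))
  if (!length(genes)) stop("no signature gene present in the expression matrix")
  m <- log2(expr[genes, , drop = FALSE] + 1)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  colMeans(z)
}

# exact null distribution of W+ = sum of ranks with positive sign, over all
# 2^n equiprobable sign assignments; mid-ranks doubled to stay integral
.signedRankDistribution <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Exact Wilcoxon signed-rank test for paired scores
#'
#' Two-sided paired test of \code{after} vs \code{before}. Zero differences
#' are dropped (the classic signed-rank convention) and tied absolute
#' differences receive mid-ranks. For \code{n <= exact_limit} pairs the
#' p-value comes from the exact null distribution of \eqn{W^+} over all
#' \eqn{2^n} sign assignments (computed by convolution); beyond that a
#' normal approximation with continuity and tie correction is used.
#'
#' @param before,after paired score vectors of equal length.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return list with \code{W} (sum of positive-difference ranks),
#'   \code{p_two_sided}, \code{n_pairs} (after dropping zeros) and
#'   \code{method}.
#' @examples
#' wilcoxonSignedRankExact(rep(0, 7), 1:7)$p_two_sided  # 2/2^7
#' @export
wilcoxonSignedRankExact <- function(before, after, exact_limit = 25) {
  if (length(before) != length(after)) stop("paired vectors of equal length required")
  d <- after - before
  d <- d[d != 0]
  if (!length(d)) stop("degenerate: all differences are zero")
  n <- length(d)
  if (n < 3) stop("fewer than 3 non-zero differences")
  rk <- rank(abs(d))  # mid-ranks for ties
  W <- sum(rk[d > 0])
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * rk))
    f <- .signedRankDistribution(ranks2)
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(f[(w2 + 1):length(f)])
    p_le <- sum(f[1:(w2 + 1)])
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(W = W, p_two_sided = p, n_pairs = n, method = method)
}

#' Mesenchymal/proneural subtype scoring and paired treatment comparison
#'
#' Scores every sample against both subtype signatures
#' (\code{\link{signatureScore}}), calls the prevailing subtype per sample
#' (argmax; \code{"indeterminate"} on an exact tie), and tests the paired
#' treatment shift of each signature score separately per lineage across
#' cell lines with the exact Wilcoxon signed-rank test (naive vs VPA pairs).
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param meta data.frame with \code{sample_id}, \code{cell_line},
#'   \code{lineage}, \code{condition} matching \code{colnames(expr)}.
#' @param mes_signature,pn_signature mesenchymal / proneural signature gene
#'   ids.
#' @return list with \code{samples} (per-sample scores and call) and
#'   \code{tests} (per lineage x signature: n_pairs, W, p_two_sided;
#'   \code{NA} when fewer than 3 usable pairs).
#' @export
classifySubtype <- function(expr, meta, mes_signature, pn_signature) {
  meta <- as.data.frame(meta)
  if (!all(colnames(expr) %in% meta$sample_id))
    stop("sample(s) missing from metadata")
  mes <- signatureScore(expr, mes_signature)
  pn <- signatureScore(expr, pn_signature)
  call <- ifelse(mes > pn, "mesenchymal",
                 ifelse(pn > mes, "proneural", "indeterminate"))
  samples <- data.frame(sample_id = colnames(expr),
                        mesenchymal_score = unname(mes),
                        proneural_score = unname(pn),
                        call = unname(call), row.names = NULL)
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  tests <- do.call(rbind, lapply(c("adherent", "stem"), function(lg) {
    do.call(rbind, lapply(c("mesenchymal", "proneural"), function(sg) {
      sc <- if (sg == "mesenchymal") mes else pn
      cls <- unique(meta$cell_line[meta$lineage == lg])
      pick <- function(cl, cond) {
        i <- which(meta$cell_line == cl & meta$condition == cond)
        if (length(i) == 1) sc[i] else NA_real_
      }
      b <- vapply(cls, pick, 0, cond = "naive")
      a <- vapply(cls, pick, 0, cond = "vpa")
      ok <- !is.na(b) & !is.na(a)
      wt <- tryCatch(wilcoxonSignedRankExact(b[ok], a[ok]),
                     error = function(e) list(W = NA_real_,
                                              p_two_sided = NA_real_,
                                              n_pairs = sum(ok)))
      data.frame(lineage = lg, signature = sg, n_pairs = wt$n_pairs,
                 W = wt$W, p_two_sided = wt$p_two_sided)
    }))
  }))
  list(samples = samples, tests = tests)
}
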