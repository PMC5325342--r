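# small in-code fixtures shared across test files

# a 2-line mini panel (1 adherent, 1 stem) with hand-set counts
miniCountSet <- function(counts = NULL) {
  if (is.null(counts))
    counts <- matrix(c(5L, 0L, 10L, 50L, 3L, 8L, 20L, 40L),
                     nrow = 2, byrow = TRUE,
                     dimnames = list(c("gA", "gB"),
                                     c("L1_naive", "L1_vpa", "L2_naive", "L2_vpa")))
  meta <- data.frame(
    sample_id = colnames(counts),
    cell_line = sub("_.*", "", colnames(counts)),
    lineage = ifelse(sub("_.*", "", colnames(counts)) == "L1", "adherent", "stem"),
    condition = sub(".*_", "", colnames(counts)),
    library_size = rep(1e6, ncol(counts)))
  CountSet(counts, meta)
}

# hand-built per-line DE tables with prescribed up-calls, for consensus tests:
# `up` is a named list cell_line -> character vector of up genes; every up
# gene gets q = 1e-4 and fc = fc_up, others q = 0.5 and fc = 1
fakeDETables <- function(genes, up, lineage_of, fc_up = 10) {
  tabs <- lapply(names(lineage_of), function(cl) {
    is_up <- genes %in% (up[[cl]] %||% character(0))
    data.frame(gene_id = genes, cell_line = cl,
               x = 10L, y = ifelse(is_up, 100L, 10L), N1 = 1e6, N2 = 1e6,
               fc = ifelse(is_up, fc_up, 1),
               p_raw = ifelse(is_up, 1e-6, 0.5),
               q = ifelse(is_up, 1e-4, 0.5),
               direction = ifelse(is_up, "up", "none"))
  })
  names(tabs) <- names(lineage_of)
  attr(tabs, "lineage") <- lineage_of
  tabs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force all-pairs interval overlap oracle (1-based closed GRanges)
bruteOverlap <- function(promoters, regions, min_overlap_bp = 1) {
  ps <- GenomicRanges::start(promoters); pe <- GenomicRanges::end(promoters)
  pc <- as.character(GenomicRanges::seqnames(promoters))
  rs <- GenomicRanges::start(regions); re <- GenomicRanges::end(regions)
  rc <- as.character(GenomicRanges::seqnames(regions))
  vapply(seq_along(promoters), function(i) {
    same <- rc == pc[i]
    if (!any(same)) return(FALSE)
    ov <- pmin(pe[i], re[same]) - pmax(ps[i], rs[same]) + 1
    any(ov >= min_overlap_bp)
  }, TRUE)
}

# exact Wilcoxon signed-rank oracle: full enumeration of all 2^n sign vectors
enumSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wnull <- signs %*% rk
  p_ge <- mean(Wnull >= W - 1e-9)
  p_le <- mean(Wnull <= W + 1e-9)
  list(W = W, p = min(1, 2 * min(p_ge, p_le)))
}
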