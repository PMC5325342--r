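test_that("exact Wilcoxon matches full 2^n enumeration for n <= 12", {
  withr::with_seed(19, {
    for (n in 3:12) {
      d <- round(rnorm(n), 1)           # rounding creates occasional ties
      d[d == 0] <- 0.5
      got <- wilcoxonSignedRankExact(rep(0, n), d)
      oracle <- enumSignedRank(d)
      expect_equal(got$W, oracle$W)
      expect_equal(got$p_two_sided, oracle$p, tolerance = 1e-12)
    }
  })
})

test_that("seven concordant pairs give the classic 2/128 p-value", {
  res <- wilcoxonSignedRankExact(rep(0, 7), 1:7)
  expect_equal(res$p_two_sided, 0.015625)
  expect_equal(res$W, 28)
  expect_equal(res$n_pairs, 7)
  expect_equal(res$method, "exact")
})

test_that("swapping before/after preserves p and reflects W", {
  withr::with_seed(23, {
    b <- rnorm(9); a <- b + rnorm(9, 0.4)
    f <- wilcoxonSignedRankExact(b, a)
    r <- wilcoxonSignedRankExact(a, b)
    expect_equal(f$p_two_sided, r$p_two_sided, tolerance = 1e-12)
    n <- f$n_pairs
    expect_equal(r$W, n * (n + 1) / 2 - f$W)
  })
})

test_that("exact p agrees with wilcox.test on tie-free data", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      b <- rnorm(10); a <- b + rnorm(10)
      got <- wilcoxonSignedRankExact(b, a)$p_two_sided
      ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-12)
    }
  })
})

test_that("zero differences are dropped and degenerate input rejected", {
  res <- wilcoxonSignedRankExact(c(1, 2, 3, 4, 5), c(1, 3, 4, 5, 6))
  expect_equal(res$n_pairs, 4)
  expect_error(wilcoxonSignedRankExact(1:5, 1:5), "degenerate")
  expect_error(wilcoxonSignedRankExact(c(1, 2, 3), c(1, 2, 4)), "fewer than 3")
})

test_that("large n falls back to a sane normal approximation", {
  withr::with_seed(37, {
    b <- rnorm(40); a <- b + 0.8 + rnorm(40, sd = 0.5)
    res <- wilcoxonSignedRankExact(b, a)
    ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
    expect_equal(res$method, "normal")
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 0.02)
  })
})

test_that("signature scores are monotone and affine-invariant", {
  withr::with_seed(41, {
    expr <- matrix(rlnorm(50 * 6, 3, 1), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
    sig <- sprintf("g%02d", 1:10)
    expr2 <- expr
    expr2[sig, "s3"] <- expr2[sig, "s3"] * 50  # s3 uniformly highest
    sc <- signatureScore(expr2, sig)
    expect_equal(names(which.max(sc)), "s3")
    # two identical samples score identically
    expr3 <- cbind(expr, s7 = expr[, "s1"])
    sc3 <- signatureScore(expr3, sig)
    expect_equal(sc3[["s7"]], sc3[["s1"]])
    expect_error(signatureScore(expr, c("none1", "none2")), "no signature gene")
  })
})

mkSubtypePanel <- function(mes_hi, pn_hi, shift = 0, seed = 47) {
  withr::with_seed(seed, {
    lines <- c(sprintf("A%d", 1:4), sprintf("S%d", 1:4))
    meta <- expand.grid(condition = c("naive", "vpa"), cell_line = lines,
                        stringsAsFactors = FALSE)[, 2:1]
    meta$lineage <- ifelse(grepl("^A", meta$cell_line), "adherent", "stem")
    meta$sample_id <- paste(meta$cell_line, meta$condition, sep = "_")
    genes <- sprintf("g%02d", 1:60)
    mes <- genes[1:15]; pn <- genes[16:30]
    expr <- matrix(rlnorm(60 * nrow(meta), 3, 0.3), 60, nrow(meta),
                   dimnames = list(genes, meta$sample_id))
    adh <- meta$lineage == "adherent"
    expr[mes, adh] <- expr[mes, adh] * mes_hi
    expr[pn, !adh] <- expr[pn, !adh] * pn_hi
    if (shift > 0) {
      vpa <- meta$condition == "vpa"
      expr[mes, !adh & vpa] <- expr[mes, !adh & vpa] * shift
      expr[pn, adh & vpa] <- expr[pn, adh & vpa] * shift
    }
    list(expr = expr, meta = meta, mes = mes, pn = pn)
  })
}

test_that("planted subtype structure yields correct calls per lineage", {
  p <- mkSubtypePanel(mes_hi = 6, pn_hi = 6)
  res <- classifySubtype(p$expr, p$meta, p$mes, p$pn)
  calls <- res$samples$call
  adh <- grepl("^A", res$samples$sample_id)
  expect_true(all(calls[adh] == "mesenchymal"))
  expect_true(all(calls[!adh] == "proneural"))
})

test_that("a within-subtype shift moves scores significantly without flipping calls", {
  p <- mkSubtypePanel(mes_hi = 8, pn_hi = 8, shift = 2.5)
  res <- classifySubtype(p$expr, p$meta, p$mes, p$pn)
  adh <- grepl("^A", res$samples$sample_id)
  expect_true(all(res$samples$call[adh] == "mesenchymal"))
  expect_true(all(res$samples$call[!adh] == "proneural"))
  tt <- res$tests
  p_stem_mes <- tt$p_two_sided[tt$lineage == "stem" & tt$signature == "mesenchymal"]
  p_adh_pn <- tt$p_two_sided[tt$lineage == "adherent" & tt$signature == "proneural"]
  expect_lt(p_stem_mes, 0.15)  # n = 4 pairs: minimum attainable p is 0.125
  expect_lt(p_adh_pn, 0.15)
})

test_that("symmetric signatures on symmetric data tie to indeterminate", {
  expr <- matrix(5, 20, 4, dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     cell_line = c("L1", "L1", "L2", "L2"),
                     lineage = c("adherent", "adherent", "stem", "stem"),
                     condition = c("naive", "vpa", "naive", "vpa"))
  res <- classifySubtype(expr, meta, sprintf("g%02d", 1:5), sprintf("g%02d", 6:10))
  expect_true(all(res$samples$call == "indeterminate"))
})
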