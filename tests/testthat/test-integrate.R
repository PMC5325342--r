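lin14 <- setNames(rep(c("adherent", "stem"), each = 7),
                  c(sprintf("A%d", 1:7), sprintf("S%d", 1:7)))

test_that("consensus applies the two-lineage majority rule", {
  genes <- c("full", "border", "short")
  up <- c(lapply(setNames(nm = sprintf("A%d", 1:7)), function(x) c("full", "border")),
          lapply(setNames(nm = sprintf("S%d", 1:4)), function(x) c("full", "border")),
          lapply(setNames(nm = sprintf("S%d", 5:7)), function(x) "full"))
  up$S1 <- c(up$S1, "short"); up$S2 <- c(up$S2, "short"); up$S3 <- c(up$S3, "short")
  tabs <- fakeDETables(genes, up, lin14)
  sig <- consensusUpregulated(tabs, fc_cutoff = 5)
  expect_setequal(signatureGenes(sig), c("full", "border"))  # 7/7+7/7 and 7/7+4/7 in
  sup <- supportCounts(sig)
  expect_equal(sup$n_stem_up[sup$gene_id == "border"], 4)
  expect_equal(sup$n_stem_up[sup$gene_id == "short"], 3)     # 3/7 stem: excluded
  expect_error(consensusUpregulated(tabs, 5, min_support = 8),
               "exceeds lineage size")
})

test_that("consensus on a (2,2)-line toy matches exhaustive enumeration", {
  lin <- setNames(c("adherent", "adherent", "stem", "stem"),
                  c("A1", "A2", "S1", "S2"))
  genes <- c("gx", "gy", "gz")
  # enumerate every support pattern for 3 genes over 4 lines
  withr::with_seed(12, {
    for (rep in 1:25) {
      up <- lapply(setNames(nm = names(lin)), function(l)
        genes[runif(3) < 0.5])
      tabs <- fakeDETables(genes, up, lin)
      sig <- consensusUpregulated(tabs, fc_cutoff = 2, min_support = 2)
      manual <- genes[vapply(genes, function(g) {
        na <- sum(vapply(c("A1", "A2"), function(l) g %in% up[[l]], TRUE))
        ns <- sum(vapply(c("S1", "S2"), function(l) g %in% up[[l]], TRUE))
        na >= 2 && ns >= 2
      }, TRUE)]
      expect_setequal(signatureGenes(sig), manual)
    }
  })
})

test_that("genes missing from a line's table count as non-supporting", {
  lin <- setNames(c("adherent", "adherent", "stem", "stem"),
                  c("A1", "A2", "S1", "S2"))
  tabs <- fakeDETables(c("g1", "g2"),
                       lapply(setNames(nm = names(lin)), function(l) c("g1", "g2")),
                       lin)
  tabs$A1 <- tabs$A1[tabs$A1$gene_id != "g2", ]  # g2 absent from A1
  sig <- consensusUpregulated(tabs, fc_cutoff = 2, min_support = 2)
  # g2 is supported by only 1 of 2 adherent lines, so it drops out
  expect_setequal(signatureGenes(sig), "g1")
  sup <- supportCounts(sig)
  expect_equal(sup$n_adherent_up[sup$gene_id == "g2"], 1)
  expect_equal(sup$n_stem_up[sup$gene_id == "g2"], 2)
})

test_that("tier signatures are nested and intersections behave", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      genes <- sprintf("g%03d", 1:40)
      fcs <- setNames(runif(40, 1, 8), genes)
      tabs <- lapply(setNames(nm = names(lin14)), function(l) {
        noise <- runif(40, 0.7, 1.4)
        data.frame(gene_id = genes, cell_line = l, x = 10L, y = 10L,
                   N1 = 1e6, N2 = 1e6, fc = fcs * noise,
                   p_raw = ifelse(fcs * noise > 1.5, 1e-5, 0.5),
                   q = ifelse(fcs * noise > 1.5, 1e-4, 0.5),
                   direction = ifelse(fcs * noise > 1.5, "up", "none"))
      })
      attr(tabs, "lineage") <- lin14
      tiers <- fcTierTable(tabs, cutoffs = c(5, 4, 3, 2))
      g <- tiers$genes
      expect_true(all(g$fc_ge_5 %in% g$fc_ge_4))
      expect_true(all(g$fc_ge_4 %in% g$fc_ge_3))
      expect_true(all(g$fc_ge_3 %in% g$fc_ge_2))
      expect_true(all(diff(tiers$table$n_consensus) >= 0))
    }
  })
  expect_error(fcTierTable(fakeDETables("g1", list(), lin14),
                           cutoffs = c(2, 3)), "strictly decreasing")
})

test_that("all-FALSE euchromatin gives empty intersections; planted tiers recover", {
  genes <- sprintf("g%02d", 1:30)
  fc_of <- setNames(c(rep(6, 2), rep(4.5, 2), rep(3.5, 2), rep(2.5, 2),
                      rep(1, 22)), genes)
  tabs <- lapply(setNames(nm = names(lin14)), function(l)
    data.frame(gene_id = genes, cell_line = l, x = 10L, y = 10L,
               N1 = 1e6, N2 = 1e6, fc = fc_of,
               p_raw = ifelse(fc_of > 1, 1e-5, 0.5),
               q = ifelse(fc_of > 1, 1e-4, 0.5),
               direction = ifelse(fc_of > 1, "up", "none")))
  attr(tabs, "lineage") <- lin14
  euch_all <- matrix(TRUE, 30, 14, dimnames = list(genes, names(lin14)))
  tiers <- fcTierTable(tabs, euchromatin = euch_all)
  expect_equal(tiers$table$n_intersect, c(2, 4, 6, 8))  # planted tier sizes
  euch_none <- matrix(FALSE, 30, 14, dimnames = list(genes, names(lin14)))
  tiers0 <- fcTierTable(tabs, euchromatin = euch_none)
  expect_equal(tiers0$table$n_intersect, rep(0L, 4))
  expect_error(fcTierTable(tabs, euchromatin = euch_all[1:5, ]),
               "lacks gene")
})

test_that("enrichment reproduces the published SLC example", {
  res <- enrichmentTest(16, 497, 397, 46111)
  expect_equal(signif(res$p, 3), 1.18e-5)
  expect_equal(res$expected, 497 * 397 / 46111)
  # cross-check against fisher.test on the same list-vs-genome table
  ft <- fisher.test(matrix(c(16, 497 - 16, 397, 46111 - 397), 2),
                    alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-12)
})

test_that("enrichment tails match brute-force summation on small universes", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      N <- sample(20:60, 1); K <- sample(3:(N - 5), 1)
      n <- sample(3:(N - 2), 1); k <- sample(0:min(n, K), 1)
      # draw convention: direct summation of hypergeometric point masses
      pm <- function(j) choose(K, j) * choose(N - K, n - j) / choose(N, n)
      js <- max(0, n - (N - K)):min(n, K)
      oracle_g <- sum(vapply(js[js >= k], pm, 0))
      got <- enrichmentTest(k, n, K, N, convention = "draw")
      expect_equal(got$p, oracle_g, tolerance = 1e-12)
      probs <- vapply(js, pm, 0)
      oracle_2 <- sum(probs[probs <= pm(k) * (1 + 1e-7)])
      got2 <- enrichmentTest(k, n, K, N, sided = "two_sided",
                             convention = "draw")
      expect_equal(got2$p, oracle_2, tolerance = 1e-12)
    }
  })
  expect_equal(enrichmentTest(0, 10, 5, 100)$p, 1)
  expect_error(enrichmentTest(6, 5, 10, 100), "k > min")
})

test_that("familyEnrichment is invariant to order and duplicates", {
  fam <- sprintf("f%d", 1:20)
  lst <- c(sprintf("f%d", 1:5), sprintf("o%d", 1:45))
  a <- familyEnrichment(lst, fam, universe_size = 1000)
  b <- familyEnrichment(rev(lst), rev(fam), universe_size = 1000)
  expect_equal(a, b)
  expect_warning(d <- familyEnrichment(c(lst, "f1"), fam, universe_size = 1000),
                 "deduplicated")
  expect_equal(d$k, a$k)
  expect_equal(d$n, a$n)
  expect_error(familyEnrichment(c("zz", lst), fam, universe = c(lst, fam)),
               "outside the universe")
})
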