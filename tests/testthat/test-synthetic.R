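test_that("generators are pure functions of parameters and seed", {
  a1 <- simAnnotation(60, 2, seed = 5)
  a2 <- simAnnotation(60, 2, seed = 5)
  expect_identical(a1, a2)
  s1 <- simCounts(a1, seed = 6, frac_up = 0.2, family_size = 10,
                  family_planted = 5)
  s2 <- simCounts(a1, seed = 6, frac_up = 0.2, family_size = 10,
                  family_planted = 5)
  expect_identical(SummarizedExperiment::assay(s1$counts, "counts"),
                   SummarizedExperiment::assay(s2$counts, "counts"))
  expect_identical(s1$truth, s2$truth)
  r1 <- simChipRegions(a1, c("L1", "L2"), a1$gene_id[1:5], seed = 7)
  r2 <- simChipRegions(a1, c("L1", "L2"), a1$gene_id[1:5], seed = 7)
  expect_identical(r1, r2)
  d1 <- simDoseResponse(data.frame(cell_line = "L", vpa_status = "naive",
                                   bottom = 0, top = 100, hill = -1,
                                   log_ic50 = 3), seed = 8)
  d2 <- simDoseResponse(data.frame(cell_line = "L", vpa_status = "naive",
                                   bottom = 0, top = 100, hill = -1,
                                   log_ic50 = 3), seed = 8)
  expect_identical(d1, d2)
})

test_that("synthetic annotation has non-overlapping bodies and sane lengths", {
  ann <- simAnnotation(150, 3, seed = 9)
  expect_equal(length(ann), 150L)
  w <- GenomicRanges::width(ann)
  expect_true(all(w >= 500 & w <= 1e5))
  for (ch in unique(as.character(GenomicRanges::seqnames(ann)))) {
    sub <- ann[as.character(GenomicRanges::seqnames(ann)) == ch]
    sub <- sub[order(GenomicRanges::start(sub))]
    if (length(sub) > 1)
      expect_true(all(GenomicRanges::start(sub)[-1] >
                        GenomicRanges::end(sub)[-length(sub)]))
  }
  expect_true(all(ann$exonic_length > 0))
  expect_equal(length(simAnnotation(1, 1, seed = 2)), 1L)
})

test_that("generated counts pass container validation and carry the design", {
  ann <- simAnnotation(100, 2, seed = 10)
  sim <- simCounts(ann, seed = 11, frac_up = 0.1, family_size = 10,
                   family_planted = 4, support_per_lineage = 4)
  cs <- sim$counts
  expect_s4_class(cs, "CountSet")
  expect_true(validObject(cs))
  expect_equal(ncol(cs), 28L)
  expect_equal(sum(lineages(cs) == "adherent"), 14L)
  tr <- sim$truth
  expect_equal(length(tr$planted_up), 10L)
  expect_equal(sum(tr$planted_up %in% tr$family), 4L)
  expect_true(all(lengths(tr$support_adherent) == 4L))
  expect_error(simCounts(ann, family_size = 500), "family larger")
})

test_that("a null panel produces near-zero calls at q < 0.01", {
  ann <- simAnnotation(800, 2, seed = 12)
  sim <- simCounts(ann, frac_up = 0, family_size = 5, family_planted = 0,
                   noise = "poisson", seed = 13)
  de <- differentialTables(sim$counts)
  n_up <- sum(vapply(de, function(t) sum(t$direction == "up"), 0L))
  # 800 genes x 14 lines under the null; BH controls false calls
  expect_lte(n_up, 5L)
})

test_that("chip concordance limits behave as planted", {
  ann <- simAnnotation(120, 2, seed = 14)
  conc <- ann$gene_id[1:30]
  full <- simChipRegions(ann, "L1", conc, concordance_prob = 1,
                         background_per_chrom = 0, seed = 15)
  m <- euchromatinMatrix(full, ann)
  expect_setequal(rownames(m)[m[, "L1"]], conc)
  none <- simChipRegions(ann, "L1", conc, concordance_prob = 0,
                         background_per_chrom = 0, seed = 16)
  m0 <- euchromatinMatrix(none, ann)
  expect_false(any(m0))
})

test_that("background-only regions hit promoters at roughly the expected rate", {
  ann <- simAnnotation(400, 2, seed = 17)
  bg <- simChipRegions(ann, "L1", character(0), concordance_prob = 0,
                       background_per_chrom = 200, seed = 18)
  m <- euchromatinMatrix(bg, ann)
  rate <- mean(m[, "L1"])
  # expected hit rate: promoters ~1 kb, background regions ~1.1 kb mean width,
  # 200 per chromosome on chromosomes of ~ gene-packed span
  span <- sum(as.numeric(tapply(GenomicRanges::end(ann),
                                as.character(GenomicRanges::seqnames(ann)), max)))
  expected <- 1 - exp(-400 * (1000 + 1100) / span)
  expect_gt(rate, expected * 0.4)
  expect_lt(rate, min(1, expected * 2.5))
})

test_that("simulateStudy writes a complete, readable dataset", {
  dir <- withr::local_tempdir()
  out <- simulateStudy(dir, n_genes = 150, n_chroms = 2, seed = 3,
                       frac_up = 0.1, family_size = 15, family_planted = 8)
  expect_true(all(file.exists(unlist(out$paths[c("counts", "meta", "annotation",
                                                 "gene_sets", "dose_response",
                                                 "truth")]))))
  cs <- readCountMatrix(out$paths$counts, out$paths$meta)
  expect_equal(nrow(cs), 150L)
  beds <- list.files(out$paths$regions_dir, pattern = "\\.bed$")
  expect_equal(length(beds), 14L)
  truth <- jsonlite::read_json(out$paths$truth)
  expect_equal(length(truth$planted_up), 15L)
})
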