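simCurve <- function(bottom = 0, top = 100, hill = -1, ic50 = 1000,
                     doses = c(1, 5, 20, 100, 500, 1500, 4000, 8000),
                     noise_sd = 0, replicates = 3, seed = 1) {
  sim <- simDoseResponse(
    data.frame(cell_line = "L", vpa_status = "naive", bottom = bottom,
               top = top, hill = hill, log_ic50 = log10(ic50)),
    doses = doses, noise_sd = noise_sd, replicates = replicates, seed = seed)
  sim$table
}

test_that("noise-free curves are recovered to four significant figures", {
  tab <- simCurve()
  fit <- fit4PL(tab$concentration, tab$fluorescence)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  expect_equal(fit$hill, -1, tolerance = 1e-4)
  expect_equal(fit$ic50, 1000, tolerance = 1e-4)
  # symmetric curve from 0 to 100: midpoint and absolute IC50 coincide
  expect_equal(fit$ic50_abs, 1000, tolerance = 1e-4)
  expect_false(fit$extrapolated)
})

test_that("asymmetric curves distinguish midpoint from absolute IC50", {
  tab <- simCurve(bottom = 20, top = 100, hill = -1.3, ic50 = 800)
  fit <- fit4PL(tab$concentration, tab$fluorescence)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 800, tolerance = 1e-4)
  # absolute IC50 solves bottom + (top-bottom)/(1 + 10^((logI-logc)h)) = 50
  logc <- fit$log_ic50 - log10((100 - 20) / (50 - 20) - 1) / fit$hill
  expect_equal(fit$ic50_abs, 10^logc, tolerance = 1e-6)
  expect_gt(fit$ic50_abs, fit$ic50)  # bottom above zero pushes the 50% point right
})

test_that("flat responses are flagged as non-converged", {
  tab <- simCurve(bottom = 100, top = 100)
  fit <- fit4PL(tab$concentration, tab$fluorescence)
  expect_false(fit$converged)
})

test_that("IC50 recovery under 5% noise is accurate over seeds", {
  errs <- vapply(1:8, function(s) {
    tab <- simCurve(noise_sd = 5, seed = s)
    fit <- fit4PL(tab$concentration, tab$fluorescence)
    abs(fit$ic50 - 1000) / 1000
  }, 0)
  expect_lt(median(errs), 0.15)
})

test_that("IC50 estimates are equivariant under concentration rescaling", {
  tab <- simCurve(noise_sd = 3, seed = 4)
  f1 <- fit4PL(tab$concentration, tab$fluorescence)
  f2 <- fit4PL(tab$concentration * 7, tab$fluorescence)
  expect_equal(f2$ic50, 7 * f1$ic50, tolerance = 1e-6)
  expect_equal(f2$ic50_abs, 7 * f1$ic50_abs, tolerance = 1e-6)
})

test_that("fitDoseResponse fits every curve of a plate table", {
  sim <- simDoseResponse(
    data.frame(cell_line = "U1", vpa_status = c("naive", "treated"),
               bottom = 5, top = 100, hill = -1,
               log_ic50 = log10(c(2000, 800))),
    noise_sd = 2, seed = 11)
  fits <- fitDoseResponse(sim$table)
  expect_equal(nrow(fits), 2L)
  red <- ic50Reduction(fits$ic50[fits$vpa_status == "naive"],
                       fits$ic50[fits$vpa_status == "treated"])
  expect_equal(red, 1 - 800 / 2000, tolerance = 0.15)
})

test_that("IC50 reduction follows its sign convention", {
  expect_equal(ic50Reduction(2000, 1000), 0.5)
  expect_equal(ic50Reduction(1500, 1500), 0)
  expect_lt(ic50Reduction(1000, 2000), 0)
  expect_error(ic50Reduction(-1, 5), "positive")
})

mkRescue <- function(vals) {
  do.call(rbind, lapply(names(vals), function(si) {
    v <- vals[[si]]
    data.frame(sirna = si,
               vpa = c(TRUE, TRUE, FALSE, FALSE),
               tmz = c(TRUE, FALSE, TRUE, FALSE),
               value = v)
  }))
}

test_that("siRNA rescue normalizes to control and detects rescue", {
  # siCTRL: VPA halves the TMZ-relative survival (sensitization)
  ctrl <- c(40, 100, 80, 100)
  tab <- mkRescue(list(siCTRL = ctrl, siSAME = ctrl,
                       siRESCUE = c(80, 100, 80, 100)))
  res <- sirnaRescue(tab)
  expect_equal(res$relative[res$sirna == "siCTRL"], 1)
  expect_equal(res$relative[res$sirna == "siSAME"], 1)
  expect_equal(res$relative[res$sirna == "siRESCUE"], 2)
  expect_equal(res$interpretation[res$sirna == "siRESCUE"], "desensitized")
})

test_that("rescue ratios are scale-invariant per siRNA", {
  withr::with_seed(61, {
    v <- runif(4, 50, 150)
    tab <- mkRescue(list(siCTRL = runif(4, 50, 150), siX = v, siY = v * 3.7))
    res <- sirnaRescue(tab)
    expect_equal(res$relative[res$sirna == "siX"],
                 res$relative[res$sirna == "siY"], tolerance = 1e-12)
  })
})

test_that("rescue input validation catches missing conditions", {
  tab <- mkRescue(list(siCTRL = c(40, 100, 80, 100)))
  tab2 <- rbind(tab, data.frame(sirna = "siZ", vpa = TRUE, tmz = TRUE, value = 50))
  expect_error(sirnaRescue(tab2), "missing condition")
  expect_error(sirnaRescue(tab, control = "siNONE"), "absent")
})

test_that("delta-delta-Ct fold changes match scalar recomputation", {
  expect_equal(ddctFold(20, 18, 22, 20), 1)     # ddCt = 0
  expect_equal(ddctFold(19, 20, 22, 22), 2)     # ddCt = -1
  withr::with_seed(67, {
    ct <- matrix(runif(40, 15, 35), 10)
    got <- ddctFold(ct[, 1], ct[, 2], ct[, 3], ct[, 4])
    oracle <- vapply(1:10, function(i)
      2^(-((ct[i, 1] - ct[i, 2]) - (ct[i, 3] - ct[i, 4]))), 0)
    expect_equal(got, oracle)
  })
  expect_error(ddctFold(Inf, 1, 1, 1), "finite")
})
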