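#' Default pipeline configuration
#'
#' The defaults reproduce the analysis parameter set the package is built
#' around: adjusted p < 0.01 per line, fold-change tiers 5/4/3/2, majority
#' support of at least 4 of 7 lines per lineage, a 1000-bp promoter window
#' upstream of the TSS.
#'
#' @param ... overrides of any default (e.g. \code{q_thresh = 0.05}); every
#'   override is echoed to the run log.
#' @return Named list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    counts = NULL, meta = NULL, annotation = NULL,
    regions_dir = NULL, gene_sets = NULL, dose_response = NULL,
    family_set = "FAMILY", mes_set = "MES_SIGNATURE", pn_set = "PN_SIGNATURE",
    universe_size = NULL,          # default: annotation gene count
    q_thresh = 0.01, fc_cutoffs = c(5, 4, 3, 2), min_support = 4,
    pseudo_cpm = 0.5, upstream_bp = 1000, min_overlap_bp = 1,
    gsea_n_perm = 1000, seed = 1,
    run_chip = TRUE, run_gsea = TRUE, run_subtype = TRUE,
    run_pharmacology = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  attr(cfg, "overrides") <- names(over)
  cfg
}

.cfgError <- function(...) stop("config error: ", ..., call. = FALSE)

.checkConfig <- function(cfg) {
  for (f in c("counts", "meta", "annotation")) {
    if (is.null(cfg[[f]])) .cfgError("required input '", f, "' not set")
    if (!file.exists(cfg[[f]])) .cfgError("'", f, "' not found: ", cfg[[f]])
  }
  if (isTRUE(cfg$run_chip)) {
    if (is.null(cfg$regions_dir)) .cfgError("chip stage enabled but regions_dir not set")
    if (!dir.exists(cfg$regions_dir)) .cfgError("regions_dir not found: ", cfg$regions_dir)
  }
  if ((isTRUE(cfg$run_gsea) || isTRUE(cfg$run_subtype)) && is.null(cfg$gene_sets))
    .cfgError("gsea/subtype stage enabled but gene_sets GMT not set")
  if (!is.null(cfg$gene_sets) && !file.exists(cfg$gene_sets))
    .cfgError("gene_sets not found: ", cfg$gene_sets)
  if (isTRUE(cfg$run_pharmacology) && !is.null(cfg$dose_response) &&
      !file.exists(cfg$dose_response))
    .cfgError("dose_response not found: ", cfg$dose_response)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates differential expression -> promoter overlap -> consensus
#' tiers -> family enrichment -> GSEA -> subtype scoring (-> dose-response
#' fitting), writing each stage's table, a run log and a machine-readable
#' JSON summary into \code{out_dir}. Configuration is validated before any
#' computation; any stage failure aborts with the stage name. Re-running
#' with identical config and inputs reproduces the outputs (stochastic
#' stages are governed by \code{cfg$seed}).
#'
#' @param cfg configuration list from \code{\link{pipelineConfig}}.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(cfg, out_dir) {
  .checkConfig(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "[%H:%M:%S] "), ..., "\n",
                            sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  over <- attr(cfg, "overrides")
  logf("glioVPA ", as.character(utils::packageVersion("glioVPA")))
  for (nm in (over %||% character(0)))
    logf("override: ", nm, " = ", paste(format(cfg[[nm]]), collapse = ","))
  stage <- function(name, expr) {
    logf("stage ", name, " start")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  summary <- list(config = cfg[order(names(cfg))],
                  versions = list(glioVPA = as.character(utils::packageVersion("glioVPA")),
                                  R = paste(R.version$major, R.version$minor, sep = ".")))

  cs <- stage("read", readCountMatrix(cfg$counts, cfg$meta))
  ann <- stage("read", readGeneAnnotation(cfg$annotation))
  de <- stage("de", differentialTables(cs, alpha = cfg$q_thresh,
                                       pseudo_cpm = cfg$pseudo_cpm))
  de_all <- do.call(rbind, de)
  .writeTsv(de_all, file.path(out_dir, "de_tables.tsv"),
            list(q_thresh = cfg$q_thresh, pseudo_cpm = cfg$pseudo_cpm))
  summary$n_up_per_line <- lapply(de, function(t) sum(t$direction == "up"))

  euch <- NULL
  if (isTRUE(cfg$run_chip)) {
    euch <- stage("chip-overlap", {
      beds <- list.files(cfg$regions_dir, pattern = "\\.bed$", full.names = TRUE)
      if (!length(beds)) stop("no BED files in ", cfg$regions_dir)
      rs <- lapply(beds, readRegions)
      names(rs) <- sub("\\.bed$", "", basename(beds))
      euchromatinMatrix(rs, ann, cfg$upstream_bp, cfg$min_overlap_bp)
    })
    .writeTsv(data.frame(gene_id = rownames(euch), euch * 1L,
                         check.names = FALSE),
              file.path(out_dir, "euchromatin_calls.tsv"),
              attr(euch, "params"))
  }

  tiers <- stage("consensus", fcTierTable(de, euchromatin = euch,
                                          cutoffs = cfg$fc_cutoffs,
                                          q_thresh = cfg$q_thresh,
                                          min_support = cfg$min_support))
  .writeTsv(tiers$table, file.path(out_dir, "tier_table.tsv"),
            list(min_support = cfg$min_support))
  summary$tiers <- tiers$table

  gsc <- NULL
  if (!is.null(cfg$gene_sets))
    gsc <- stage("read", readGMT(cfg$gene_sets))
  if (!is.null(gsc) && cfg$family_set %in% names(gsc)) {
    N <- cfg$universe_size %||% length(ann)
    enr <- stage("enrich", {
      do.call(rbind, lapply(seq_along(cfg$fc_cutoffs), function(i) {
        genes <- tiers$genes[[i]]
        if (!length(genes)) return(NULL)
        cbind(fc_cutoff = cfg$fc_cutoffs[i],
              familyEnrichment(genes, geneSets(gsc)[[cfg$family_set]],
                               universe_size = N))
      }))
    })
    if (!is.null(enr)) {
      .writeTsv(enr, file.path(out_dir, "family_enrichment.tsv"),
                list(universe_size = N))
      summary$family_enrichment <- enr
    }
  }

  if (isTRUE(cfg$run_gsea) && !is.null(gsc)) {
    gres <- stage("gsea", {
      ranked <- rankingMetric(de)
      keep <- vapply(geneSets(gsc),
                     function(s) sum(names(ranked) %in% s) > 0, TRUE)
      runGSEA(ranked, geneSets(gsc)[keep], n_perm = cfg$gsea_n_perm,
              seed = cfg$seed)
    })
    .writeTsv(gres, file.path(out_dir, "gsea.tsv"),
              list(n_perm = cfg$gsea_n_perm, seed = cfg$seed))
    summary$gsea <- gres[, c("set", "size", "es", "nes", "p_nominal", "fdr_q")]
  }

  if (isTRUE(cfg$run_subtype) && !is.null(gsc) &&
      all(c(cfg$mes_set, cfg$pn_set) %in% names(gsc))) {
    sub <- stage("subtype", {
      expr <- rpkm(cs, ann)
      classifySubtype(expr, as.data.frame(SummarizedExperiment::colData(cs)),
                      geneSets(gsc)[[cfg$mes_set]], geneSets(gsc)[[cfg$pn_set]])
    })
    .writeTsv(sub$samples, file.path(out_dir, "subtype_calls.tsv"))
    .writeTsv(sub$tests, file.path(out_dir, "subtype_tests.tsv"))
    summary$subtype_tests <- sub$tests
  }

  if (isTRUE(cfg$run_pharmacology) && !is.null(cfg$dose_response)) {
    fits <- stage("doseresponse", fitDoseResponse(readDoseResponse(cfg$dose_response)))
    .writeTsv(fits, file.path(out_dir, "dose_response_fits.tsv"))
    summary$dose_response <- fits
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logf("done")
  invisible(summary)
}
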