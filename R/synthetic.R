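#' Generate a synthetic gene annotation
#'
#' Non-overlapping gene bodies laid out with random gaps across
#' \code{n_chroms} chromosomes; gene lengths log-uniform between 500 bp and
#' 100 kb; random strands; exonic length a random fraction of the body.
#' A pure function of (parameters, seed).
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chroms number of chromosomes (default 3).
#' @param seed integer RNG seed.
#' @return \code{GRanges} annotation as from \code{\link{readGeneAnnotation}}.
#' @export
simAnnotation <- function(n_genes, n_chroms = 3, seed = 1) {
  stopifnot(n_genes >= 1, n_chroms >= 1)
  withSeed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    chrom <- paste0("chr", sort(rep_len(seq_len(n_chroms), n_genes)))
    len <- round(exp(stats::runif(n_genes, log(500), log(1e5))))
    gap <- round(stats::runif(n_genes, 2000, 20000))
    start1 <- integer(n_genes)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start1[i] <- cumsum(gap[i]) + c(0, cumsum(len[i][-length(i)]))
    }
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    exonic <- pmax(100L, as.integer(round(len * stats::runif(n_genes, 0.3, 0.9))))
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start1 + 1, start1 + len),
                                 strand = strand, gene_id = gene_id,
                                 exonic_length = exonic)
    names(gr) <- gene_id
    gr
  })
}

#' Simulate an unreplicated two-condition count panel with planted effects
#'
#' Emulates the study design this package targets: a panel of cell lines
#' (default 7 adherent + 7 stem), each sequenced once VPA-naive and once
#' VPA-treated. Baseline per-gene abundances are log-normal; counts are
#' negative-binomial around \code{abundance x library_size} (a Poisson mode
#' exists for exact-calibration experiments — the Audic-Claverie test
#' assumes Poisson sampling, so the default NB noise deliberately stresses
#' it as real data would). A fraction of genes is planted as
#' treatment-upregulated with log2 effects drawn from
#' \code{effect_log2fc}, each carried by a random subset of
#' \code{support_per_lineage} lines per lineage; a designated gene family is
#' preferentially planted. Optional subtype blocks give lineage-specific
#' baselines plus a cross-lineage treatment shift, mirroring
#' mesenchymal/proneural scoring structure.
#'
#' @param annotation \code{GRanges} from \code{\link{simAnnotation}}.
#' @param n_adherent,n_stem cell lines per lineage (default 7 + 7).
#' @param frac_up fraction of genes planted as up-regulated (default 0.05).
#' @param effect_log2fc range of planted log2 fold changes (default 1-3).
#' @param family_size,family_planted size of the designated family and how
#'   many of its members are planted (defaults 30 and 12).
#' @param support_per_lineage supporting lines per lineage for each planted
#'   gene (default 5; set 4 or 3 to probe the majority-rule boundary).
#' @param dispersion NB dispersion (default 0.1); ignored for Poisson noise.
#' @param library_size_range sampled library sizes (default 5e6-2e7 reads).
#' @param noise \code{"nb"} (default) or \code{"poisson"}.
#' @param n_subtype_genes genes per subtype signature block (default 0 =
#'   none).
#' @param subtype_lineage_log2fc baseline elevation of mesenchymal genes in
#'   adherent lines and proneural genes in stem lines (default 1.5).
#' @param subtype_treatment_log2fc treated-sample shift of mesenchymal genes
#'   in stem lines and proneural genes in adherent lines (default 0.5).
#' @param seed integer RNG seed.
#' @return list: \code{counts} (a \linkS4class{CountSet}) and \code{truth}
#'   (manifest: planted genes, effects, per-lineage supporting lines, family
#'   and subtype gene sets, all parameters and the seed).
#' @export
simCounts <- function(annotation, n_adherent = 7, n_stem = 7,
                      frac_up = 0.05, effect_log2fc = c(1, 3),
                      family_size = 30, family_planted = 12,
                      support_per_lineage = 5, dispersion = 0.1,
                      library_size_range = c(5e6, 2e7),
                      noise = c("nb", "poisson"),
                      n_subtype_genes = 0,
                      subtype_lineage_log2fc = 1.5,
                      subtype_treatment_log2fc = 0.5,
                      seed = 1) {
  noise <- match.arg(noise)
  genes <- annotation$gene_id
  ng <- length(genes)
  if (family_size > ng) stop("family larger than the gene count")
  if (family_planted > family_size) stop("family_planted exceeds family_size")
  n_up <- round(frac_up * ng)
  if (n_up < family_planted) stop("frac_up too small for family_planted")
  lines_a <- sprintf("A%d", seq_len(n_adherent))
  lines_s <- sprintf("S%d", seq_len(n_stem))
  if (support_per_lineage > min(n_adherent, n_stem))
    stop("support_per_lineage exceeds lineage size")
  withSeed(seed, {
    family <- sample(genes, family_size)
    planted <- c(sample(family, family_planted),
                 sample(setdiff(genes, family), n_up - family_planted))
    effects <- stats::setNames(
      stats::runif(n_up, effect_log2fc[1], effect_log2fc[2]), planted)
    support_a <- lapply(planted, function(g) sample(lines_a, support_per_lineage))
    support_s <- lapply(planted, function(g) sample(lines_s, support_per_lineage))
    names(support_a) <- names(support_s) <- planted
    mes_genes <- pn_genes <- character(0)
    if (n_subtype_genes > 0) {
      pool <- setdiff(genes, planted)
      mes_genes <- sample(pool, n_subtype_genes)
      pn_genes <- sample(setdiff(pool, mes_genes), n_subtype_genes)
    }
    baseline <- stats::rlnorm(ng, meanlog = log(20), sdlog = 1.5)
    names(baseline) <- genes
    meta <- expand.grid(condition = c("naive", "vpa"),
                        cell_line = c(lines_a, lines_s),
                        stringsAsFactors = FALSE)[, 2:1]
    meta$lineage <- ifelse(meta$cell_line %in% lines_a, "adherent", "stem")
    meta$sample_id <- paste(meta$cell_line, meta$condition, sep = "_")
    meta$library_size <- round(stats::runif(nrow(meta), library_size_range[1],
                                            library_size_range[2]))
    cnt <- matrix(0L, ng, nrow(meta), dimnames = list(genes, meta$sample_id))
    for (j in seq_len(nrow(meta))) {
      mu <- baseline
      if (n_subtype_genes > 0) {
        if (meta$lineage[j] == "adherent")
          mu[mes_genes] <- mu[mes_genes] * 2^subtype_lineage_log2fc
        else
          mu[pn_genes] <- mu[pn_genes] * 2^subtype_lineage_log2fc
      }
      if (meta$condition[j] == "vpa") {
        sup <- if (meta$lineage[j] == "adherent") support_a else support_s
        carry <- planted[vapply(sup, function(s) meta$cell_line[j] %in% s, TRUE)]
        mu[carry] <- mu[carry] * 2^effects[carry]
        if (n_subtype_genes > 0) {
          shift_genes <- if (meta$lineage[j] == "stem") mes_genes else pn_genes
          mu[shift_genes] <- mu[shift_genes] * 2^subtype_treatment_log2fc
        }
      }
      mu <- mu * meta$library_size[j] / 1e6
      cnt[, j] <- if (noise == "poisson" || dispersion <= 0)
        stats::rpois(ng, mu)
      else stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
    }
    truth <- list(planted_up = planted, effects = as.list(effects),
                  baseline_cpm = as.list(baseline[planted]),
                  support_adherent = support_a, support_stem = support_s,
                  family = family, mes_genes = mes_genes, pn_genes = pn_genes,
                  params = list(n_adherent = n_adherent, n_stem = n_stem,
                                frac_up = frac_up,
                                effect_log2fc = effect_log2fc,
                                family_size = family_size,
                                family_planted = family_planted,
                                support_per_lineage = support_per_lineage,
                                dispersion = dispersion,
                                library_size_range = library_size_range,
                                noise = noise,
                                n_subtype_genes = n_subtype_genes,
                                subtype_lineage_log2fc = subtype_lineage_log2fc,
                                subtype_treatment_log2fc = subtype_treatment_log2fc),
                  seed = seed)
    list(counts = CountSet(cnt, meta[, c("sample_id", "cell_line", "lineage",
                                         "condition", "library_size")]),
         truth = truth)
  })
}

#' Simulate per-line ChIP-enriched region sets concordant with promoters
#'
#' For each cell line, each concordant gene's promoter window receives an
#' overlapping enriched region with probability \code{concordance_prob};
#' uniform background regions are added per chromosome.
#'
#' @param annotation \code{GRanges} annotation.
#' @param line_ids character vector of cell line names.
#' @param concordant_genes gene ids whose promoters respond to treatment.
#' @param concordance_prob per-line probability of a concordant region
#'   (default 0.9).
#' @param background_per_chrom background regions per chromosome (default 50).
#' @param upstream_bp promoter window used for placement (default 1000).
#' @param seed integer RNG seed.
#' @return Named list of \code{GRanges}, one per line.
#' @export
simChipRegions <- function(annotation, line_ids, concordant_genes,
                           concordance_prob = 0.9, background_per_chrom = 50,
                           upstream_bp = 1000, seed = 1) {
  stopifnot(concordance_prob >= 0, concordance_prob <= 1)
  prom <- promoterWindows(annotation, upstream_bp)
  chroms <- as.character(unique(GenomicRanges::seqnames(annotation)))
  span <- vapply(chroms, function(ch)
    max(GenomicRanges::end(annotation)[
      as.character(GenomicRanges::seqnames(annotation)) == ch]) + 10000, 0)
  withSeed(seed, {
    out <- lapply(line_ids, function(l) {
      hit <- concordant_genes[stats::runif(length(concordant_genes)) <
                                concordance_prob]
      p <- prom[hit]
      if (length(p)) {
        ext <- round(stats::runif(length(p), 0, 500))
        conc <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(p),
          IRanges::IRanges(pmax(1, GenomicRanges::start(p) - ext),
                           GenomicRanges::end(p) + ext))
      } else conc <- GenomicRanges::GRanges()
      bg <- do.call(c, lapply(chroms, function(ch) {
        if (background_per_chrom == 0) return(GenomicRanges::GRanges())
        st <- round(stats::runif(background_per_chrom, 1, span[ch]))
        wd <- round(stats::runif(background_per_chrom, 200, 2000))
        GenomicRanges::GRanges(factor(ch, levels = chroms),
                               IRanges::IRanges(st, st + wd - 1))
      }))
      gr <- suppressWarnings(c(conc, bg))
      GenomicRanges::mcols(gr)$score <- round(stats::runif(length(gr), 1, 100))
      GenomicRanges::strand(gr) <- "*"
      gr
    })
    names(out) <- line_ids
    out
  })
}

#' Simulate dose-response plate tables from known 4PL curves
#'
#' Evaluates each true curve at the given doses, adds Gaussian noise on the
#' percent scale and converts to fluorescence readings with control wells at
#' concentration 0 — the in-silico analogue of a triplicate 96-well
#' resazurin assay.
#'
#' @param params data.frame with columns \code{cell_line},
#'   \code{vpa_status}, \code{bottom}, \code{top}, \code{hill},
#'   \code{log_ic50} (one row per curve; \code{top} is the control level,
#'   100 = untreated growth).
#' @param doses positive concentrations (uM); default eight doses spanning
#'   1-8000 uM.
#' @param noise_sd Gaussian noise SD in percent-of-control units (default 5).
#' @param replicates wells per dose (default 3).
#' @param base_fluorescence control-level fluorescence scale (default 20000).
#' @param seed integer RNG seed.
#' @return list: \code{table} (dose-response data.frame as accepted by
#'   \code{\link{fitDoseResponse}}) and \code{truth} (the input parameters
#'   plus generator settings).
#' @export
simDoseResponse <- function(params,
                            doses = c(1, 5, 20, 100, 500, 1500, 4000, 8000),
                            noise_sd = 5, replicates = 3,
                            base_fluorescence = 20000, seed = 1) {
  stopifnot(all(doses > 0))
  withSeed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      conc <- rep(c(0, doses), each = replicates)
      resp <- ifelse(conc == 0, p$top,
                     .fourPL(log10(pmax(conc, .Machine$double.xmin)),
                             p$bottom, p$top, p$hill, p$log_ic50))
      resp <- resp + stats::rnorm(length(conc), 0, noise_sd)
      data.frame(cell_line = p$cell_line, vpa_status = p$vpa_status,
                 concentration = conc,
                 replicate = rep(seq_len(replicates), length.out = length(conc)),
                 fluorescence = pmax(base_fluorescence * resp / 100, 1e-6))
    }))
    list(table = rows,
         truth = list(params = params, doses = doses, noise_sd = noise_sd,
                      replicates = replicates,
                      base_fluorescence = base_fluorescence, seed = seed))
  })
}

#' Simulate and write a complete study dataset to a directory
#'
#' Generates annotation, the count panel with planted effects, per-line
#' ChIP region sets concordant with the planted genes' promoters, gene-set
#' GMT files (the planted family plus subtype signatures), dose-response
#' plates with a known IC50 shift, and a ground-truth manifest, then writes
#' everything as plain-text files ready for \code{\link{runPipeline}}.
#'
#' @param out_dir output directory (created if missing).
#' @param n_genes,n_chroms annotation size (defaults 5000 genes, 5
#'   chromosomes).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param ... passed on to \code{\link{simCounts}}.
#' @return Invisibly, a list with the file paths and the truth manifest.
#' @export
simulateStudy <- function(out_dir, n_genes = 5000, n_chroms = 5, seed = 1, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "regions"), showWarnings = FALSE)
  ann <- simAnnotation(n_genes, n_chroms, seed = seed)
  sim <- simCounts(ann, n_subtype_genes = 30, seed = seed + 1L, ...)
  cs <- sim$counts; truth <- sim$truth
  lines <- unique(cellLines(cs))
  regions <- simChipRegions(ann, lines, truth$planted_up, seed = seed + 2L)
  dr <- simDoseResponse(
    data.frame(cell_line = "A1", vpa_status = c("naive", "treated"),
               bottom = 5, top = 100, hill = -1,
               log_ic50 = log10(c(2000, 800))),
    seed = seed + 3L)
  paths <- list(
    counts = file.path(out_dir, "counts.tsv"),
    meta = file.path(out_dir, "meta.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    regions_dir = file.path(out_dir, "regions"),
    gene_sets = file.path(out_dir, "gene_sets.gmt"),
    dose_response = file.path(out_dir, "dose_response.csv"),
    truth = file.path(out_dir, "truth.json"))
  writeCountMatrix(cs, paths$counts, paths$meta)
  writeGeneAnnotation(ann, paths$annotation)
  for (l in lines)
    writeRegionsBed(regions[[l]], file.path(paths$regions_dir, paste0(l, ".bed")))
  gsc <- GeneSetCollection(list(FAMILY = truth$family,
                                MES_SIGNATURE = truth$mes_genes,
                                PN_SIGNATURE = truth$pn_genes))
  writeGMT(gsc, paths$gene_sets)
  utils::write.csv(dr$table, paths$dose_response, row.names = FALSE)
  truth$dose_response <- dr$truth
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth))
}
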