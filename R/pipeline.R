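.pipelineDefaults <- list(
  upstream = 2000, downstream = 500, mergeDistance = 250,
  minMeanCount = 3, minMeanFpm = 1.5,
  lfcThreshold = 0.5, alpha = 0.05, pseudo = 0.5,
  corrHalfWindow = 100000, netHalfWindow = 200000,
  geneLfcThreshold = 0.9,
  screenQ = 0.1, signatureSize = 6,
  seed = 1)

.pipelinePathKeys <- c("gtf", "chromSizes", "peakBeds", "fragmentBeds",
                       "geneExpr", "meta", "survival", "outDir")

#' Read and validate a pipeline configuration
#'
#' YAML keys are either input/output paths (`gtf`, `chromSizes`, `peakBeds`,
#' `fragmentBeds` — a map sample id to BED path —, `geneExpr`, `meta`,
#' optional `survival`, optional `outDir`) or stage parameters; parameters
#' default to the study values (2000/500 bp exclusion flanks, 250 bp merge,
#' count 3 / FPM 1.5, log2FC 0.5 at adjusted p 0.05, 100 kb correlation and
#' 200 kb net-change half-windows, screen q 0.1, signature size 6). Unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  validatePipelineConfig(raw)
}

#' @rdname readPipelineConfig
#' @param config a named list (as read from YAML).
#' @export
validatePipelineConfig <- function(config) {
  known <- c(.pipelinePathKeys, names(.pipelineDefaults))
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  for (k in names(.pipelineDefaults))
    if (is.null(config[[k]])) config[[k]] <- .pipelineDefaults[[k]]
  need <- c("gtf", "chromSizes", "peakBeds", "fragmentBeds", "geneExpr", "meta")
  miss <- need[vapply(need, function(k) is.null(config[[k]]), logical(1))]
  if (length(miss))
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  config
}

.writeTsv <- function(x, path, rowLabel = NULL) {
  x <- as.data.frame(x)
  if (!is.null(rowLabel)) x <- cbind(stats::setNames(
    data.frame(rownames(x), stringsAsFactors = FALSE), rowLabel), x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the eRNA discovery pipeline end to end
#'
#' Executes regions (exclusion zones, union peak set, intergenic filter) ->
#' quantify (midpoint counting, FPM, candidate filter, directionality) ->
#' differential (NB Wald, BH, cohort labels) -> linkage (nearest gene,
#' windowed best correlation, net enhancer change, gene-set overlap) ->
#' sample clustering -> survival signature (skipped with a notice when no
#' survival table is configured). The returned `summary` reproduces the
#' stage-wise region funnel.
#'
#' @param config list from [readPipelineConfig()] /
#'   [validatePipelineConfig()].
#' @return list with `summary` (named numeric funnel and headline stats) and
#'   the per-stage results (`se`, `candidates`, `de`, `linkage`, `net`,
#'   `binShift`, `overlap`, `clustering`, `screen`, `model`, `km`, `config`).
#' @export
runPipeline <- function(config) {
  config <- validatePipelineConfig(config)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- regions ------------------------------------------------------------
  res <- stage("regions", {
    chromSizes <- readChromSizes(config$chromSizes)
    ann <- readGeneAnnotation(config$gtf, chromSizes)
    zones <- buildExclusionZones(ann, config$upstream, config$downstream)
    peakSets <- lapply(config$peakBeds, readBed)
    unionPeaks <- mergePeakSets(peakSets, config$mergeDistance)
    intergenic <- filterIntergenicPeaks(unionPeaks, zones)
    names(intergenic) <- sprintf("region_%05d", seq_along(intergenic))
    list(ann = ann, zones = zones, unionPeaks = unionPeaks,
         intergenic = intergenic)
  })

  ## -- quantify -----------------------------------------------------------
  quant <- stage("quantify", {
    meta <- utils::read.table(config$meta, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    frags <- lapply(config$fragmentBeds, readFragmentsBed)
    names(frags) <- names(config$fragmentBeds)
    frags <- frags[meta$sample_id]
    cohort <- factor(meta$cohort)
    se <- quantifyRegions(res$intergenic, frags,
                          colData = S4Vectors::DataFrame(cohort = cohort))
    cand <- filterCandidates(se, config$minMeanCount, config$minMeanFpm)
    list(se = se, cand = cand, cohort = cohort,
         dirScores = regionDirectionality(cand))
  })

  ## -- differential -------------------------------------------------------
  de <- stage("differential",
    ernaDifferential(quant$cand, quant$cohort,
                     lfcThreshold = config$lfcThreshold,
                     alpha = config$alpha, pseudo = config$pseudo))

  ## -- linkage ------------------------------------------------------------
  link <- stage("linkage", {
    geneExpr <- as.matrix(utils::read.table(config$geneExpr, header = TRUE,
                                            sep = "\t", row.names = 1,
                                            check.names = FALSE))
    candRegions <- SummarizedExperiment::rowRanges(quant$cand)
    ernaExpr <- fpm(quant$cand)
    nearest <- nearestGeneTss(candRegions, res$ann)
    corr <- windowedBestCorrelation(ernaExpr, geneExpr, candRegions, res$ann,
                                    halfWindow = config$corrHalfWindow)
    net <- netEnhancerChange(res$ann, candRegions, de$label,
                             halfWindow = config$netHalfWindow)
    geneLfc <- geneExpressionShift(geneExpr, quant$cohort)
    binShift <- binExpressionShift(net, geneLfc)
    deeGenes <- unique(nearest$geneId[de$label != "unclassified"])
    degGenes <- names(geneLfc)[abs(geneLfc) > config$geneLfcThreshold]
    overlap <- overlapTest(deeGenes[!is.na(deeGenes)], degGenes,
                           res$ann$gene_id)
    list(geneExpr = geneExpr, nearest = nearest, corr = corr, net = net,
         geneLfc = geneLfc, binShift = binShift, overlap = overlap)
  })

  ## -- classification -----------------------------------------------------
  clust <- stage("classification", {
    cl <- correlationCluster(log2(fpm(quant$cand) + 1), k = 2)
    list(clustering = cl,
         misclassified = misclassificationCount(cl, quant$cohort))
  })

  ## -- survival -----------------------------------------------------------
  surv <- NULL
  if (!is.null(config$survival) && file.exists(config$survival)) {
    surv <- stage("survival", {
      st <- utils::read.table(config$survival, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      st <- st[match(colnames(link$geneExpr), st$sample_id), ]
      screen <- univariateScreen(link$geneExpr, st$time, st$event,
                                 qThreshold = config$screenQ)
      model <- buildRiskModel(link$geneExpr, st$time, st$event,
                              signatureSize = config$signatureSize,
                              qThreshold = config$screenQ, screen = screen)
      km <- NULL
      if (!is.null(model)) {
        grp <- riskGroups(model, link$geneExpr)
        if (nlevels(droplevels(grp)) == 2L)
          km <- kmLogrank(grp, st$time, st$event)
      }
      list(surv = st, screen = screen, model = model, km = km)
    })
  } else message("no survival table configured: survival stage skipped")

  summary <- c(
    unionPeaks = length(res$unionPeaks),
    intergenicRegions = length(res$intergenic),
    candidateRegions = nrow(quant$cand),
    aSpecific = sum(de$label == "A_specific"),
    bSpecific = sum(de$label == "B_specific"),
    discarded = sum(de$discarded),
    misclassified = clust$misclassified,
    netChangeKruskalP = link$binShift$p,
    overlapFisherP = link$overlap$pFisher)
  if (!is.null(surv) && !is.null(surv$km))
    summary <- c(summary, logrankP = surv$km$p)

  out <- list(summary = summary, se = quant$se, candidates = quant$cand,
              dirScores = quant$dirScores, de = de,
              linkage = link$corr$table, nearest = link$nearest,
              net = link$net, binShift = link$binShift,
              overlap = link$overlap, clustering = clust$clustering,
              misclassified = clust$misclassified,
              screen = surv$screen, model = surv$model, km = surv$km,
              regions = res, config = config)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    o <- function(f) file.path(config$outDir, f)
    writeBed(res$intergenic, o("regions.bed"))
    writeBed(SummarizedExperiment::rowRanges(quant$cand), o("candidates.bed"))
    .writeTsv(regionCounts(quant$se), o("counts.tsv"), "region_id")
    .writeTsv(fpm(quant$cand), o("fpm.tsv"), "region_id")
    .writeTsv(data.frame(score = quant$dirScores), o("directionality.tsv"),
              "region_id")
    .writeTsv(as.data.frame(de), o("de.tsv"), "region_id")
    .writeTsv(as.data.frame(link$corr$table), o("linkage.tsv"))
    .writeTsv(as.data.frame(link$net), o("netchange.tsv"))
    .writeTsv(data.frame(cluster = clusterLabels(clust$clustering)),
              o("cluster_labels.tsv"), "sample_id")
    if (!is.null(surv)) {
      .writeTsv(surv$screen, o("screen.tsv"))
      if (!is.null(surv$model))
        jsonlite::write_json(list(genes = signatureGenes(surv$model),
                                  beta = unname(surv$model@beta),
                                  threshold = surv$model@threshold),
                             o("model.json"), auto_unbox = TRUE, digits = NA)
    }
    .writeTsv(data.frame(value = unlist(summary)), o("summary.tsv"), "stat")
    yaml::write_yaml(config[order(names(config))], o("config_used.yaml"))
  }
  out
}
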