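#' Simulation configuration with planted ground truth
#'
#' Defines the study conditions for the synthetic cohort: a toy genome of
#' `nChroms` chromosomes, `nGenes` genes, intergenic ATAC peaks plus decoy
#' peaks hidden inside exclusion zones, `nPlantedErnas` planted
#' differentially transcribed eRNA regions (half gained in cohort B, half
#' lost), negative-binomial stranded counts, eRNA-coupled target-gene
#' expression and Cox-driven survival times. All downstream stages derive
#' their own RNG stream from `seed`.
#'
#' @param seed master seed (mandatory).
#' @param ... overrides of the defaults listed below.
#' @return a validated list of class `SimConfig`.
#' @details Defaults: 2 chromosomes of 2 Mb; 60 genes; 300 intergenic and 100
#'   decoy peaks; 40 planted eRNAs at |log2FC| 2; cohorts of 20 + 20 samples;
#'   NB mean 50 with dispersion 0.1; lognormal per-sample enhancer activity
#'   with SD 0.8 at planted regions; bidirectional strand split 0.5; window
#'   coupling 0.7 of every in-window gene to the enhancer's cohort-level
#'   activation plus a target-specific coupling of 2 to the enhancer's
#'   per-sample activity residual, against Gaussian expression noise SD 0.5
#'   (target signal:noise well above 2); lognormal library sizes around 1e6;
#'   Cox effect 0.7 with 20% censoring.
#' @export
simConfig <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    nChroms = 2L, chromLength = 2e6, nGenes = 60L,
    nIntergenicPeaks = 300L, nDecoyPeaks = 100L, nPlantedErnas = 40L,
    nA = 20L, nB = 20L,
    nbMean = 50, nbDispersion = 0.1, plantedLog2FC = 2,
    activitySd = 0.8, bidirFraction = 0.5,
    targetCoupling = 2.0, windowCoupling = 0.7, noiseSd = 0.5,
    exprBaselineMean = 8, exprBaselineSd = 1,
    libSizeMeanLog = log(1e6), libSizeSdLog = 0.15,
    survBeta = 0.7, censoringFraction = 0.2, baselineHazard = 0.05,
    fragmentLength = 100L,
    upstream = 2000L, downstream = 500L, mergeDistance = 250L,
    corrHalfWindow = 1e5, netHalfWindow = 2e5,
    nAtacSamples = 4L, peakJitter = 30L,
    geneWidthRange = c(2000L, 8000L), peakWidthRange = c(200L, 800L))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown SimConfig field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (is.na(cfg$seed)) stop("seed is mandatory")
  stopifnot(cfg$nA >= 2, cfg$nB >= 2, cfg$bidirFraction >= 0,
            cfg$bidirFraction <= 1, cfg$censoringFraction >= 0,
            cfg$censoringFraction < 1, cfg$nbDispersion >= 0,
            cfg$nPlantedErnas <= cfg$nIntergenicPeaks)
  structure(cfg, class = "SimConfig")
}

## peak slots: fixed-pitch positions inside the intergenic gaps, far enough
## from zone edges that per-sample jitter cannot leak into a zone and far
## enough apart that distinct peaks never satisfy the merge criterion
.peakSlots <- function(zones, chromSizes, slotSize = 1100L, pad = 50L) {
  slots <- NULL
  for (chr in names(chromSizes)) {
    z <- zones[seqnames(zones) == chr]
    gapsGr <- GenomicRanges::setdiff(
      GRanges(chr, IRanges(1L, chromSizes[[chr]])), z, ignore.strand = TRUE)
    for (i in seq_along(gapsGr)) {
      w <- width(gapsGr)[i]
      n <- (w - 2L * pad) %/% slotSize
      if (n < 1L) next
      st <- start(gapsGr)[i] + pad + (seq_len(n) - 1L) * slotSize
      slots <- rbind(slots, data.frame(chrom = chr, start = st))
    }
  }
  slots
}

#' Simulate the toy genome: genes, intergenic peaks and decoys
#'
#' Genes are laid out on a regular pitch with random offsets, widths and
#' strands, leaving intergenic gaps that host the ATAC peaks. Planted eRNA
#' peaks are placed close to their designated target gene's TSS (within the
#' correlation window); decoy peaks are placed wholly inside gene bodies so
#' the intergenic filter must remove every one of them.
#'
#' @param cfg a [simConfig()].
#' @return list with `genes` (`GRanges`), `chromSizes`, `peaks` (`GRanges`
#'   with `class`, `planted`, `direction`, `targetGene` columns), `zones`,
#'   and `truth`.
#' @export
simulateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed + 11L)
  chromSizes <- stats::setNames(rep(as.integer(cfg$chromLength), cfg$nChroms),
                                paste0("chr", seq_len(cfg$nChroms)))
  nPer <- diff(round(seq(0, cfg$nGenes, length.out = cfg$nChroms + 1)))
  gw <- cfg$geneWidthRange
  margin <- 2000L
  geneRows <- NULL
  gid <- 0L
  for (ci in seq_len(cfg$nChroms)) {
    if (nPer[ci] == 0L) next
    unit <- cfg$chromLength %/% nPer[ci]
    minUnit <- gw[2] + cfg$upstream + cfg$downstream + 2L * margin
    if (unit < minUnit)
      stop("infeasible packing: increase chromLength (need >= ",
           minUnit * nPer[ci], " bp per chromosome)")
    for (i in seq_len(nPer[ci])) {
      gid <- gid + 1L
      w <- sample(gw[1]:gw[2], 1L)
      lo <- cfg$upstream + margin
      hi <- unit - w - cfg$downstream - margin
      off <- sample(lo:hi, 1L)
      st <- (i - 1L) * unit + off + 1L
      geneRows <- rbind(geneRows, data.frame(
        chrom = names(chromSizes)[ci], start = st, end = st + w - 1L,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("gene_%03d", gid)))
    }
  }
  genes <- GRanges(geneRows$chrom, IRanges(geneRows$start, geneRows$end),
                   strand = geneRows$strand,
                   seqinfo = Seqinfo(names(chromSizes), unname(chromSizes)))
  genes$gene_id <- geneRows$gene_id
  names(genes) <- genes$gene_id
  zones <- buildExclusionZones(genes, cfg$upstream, cfg$downstream)

  slots <- .peakSlots(zones, chromSizes)
  if (is.null(slots) || nrow(slots) < cfg$nIntergenicPeaks)
    stop("infeasible packing: not enough intergenic space for ",
         cfg$nIntergenicPeaks, " peaks; increase chromLength")
  slotFree <- rep(TRUE, nrow(slots))
  slotCentre <- slots$start + 550L

  ## planted design: half gained (up in cohort B), half lost; one fifth of
  ## each direction's targets receive two eRNAs so net-change bins +-2 are
  ## populated
  nGain <- cfg$nPlantedErnas %/% 2L
  nLoss <- cfg$nPlantedErnas - nGain
  plan <- function(nDir) {
    nDouble <- min(nDir %/% 5L, nDir %/% 2L)
    c(double = nDouble, single = nDir - 2L * nDouble)
  }
  pg <- plan(nGain); pl <- plan(nLoss)
  tssAll <- .tss0(genes)
  geneChr <- as.character(seqnames(genes))
  geneOrder <- sample(seq_along(genes))
  geneFree <- rep(TRUE, length(genes))
  safeWin <- cfg$corrHalfWindow - 10000

  assignTargets <- function(counts2, direction) {
    want <- c(rep(2L, counts2[["double"]]), rep(1L, counts2[["single"]]))
    rows <- NULL
    for (k in want) {
      placed <- FALSE
      for (g in geneOrder) {
        if (!geneFree[g]) next
        near <- which(slotFree & slots$chrom == geneChr[g] &
                        abs(slotCentre - tssAll[g]) <= safeWin)
        if (length(near) < k) next
        near <- near[order(abs(slotCentre[near] - tssAll[g]))][seq_len(k)]
        slotFree[near] <<- FALSE
        geneFree[g] <<- FALSE
        rows <- rbind(rows, data.frame(slot = near, direction = direction,
                                       targetGene = genes$gene_id[g]))
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible packing: no free slots near a free gene")
    }
    rows
  }
  planted <- rbind(assignTargets(pg, "gain"), assignTargets(pl, "loss"))

  nBg <- cfg$nIntergenicPeaks - nrow(planted)
  bgSlots <- sample(which(slotFree), nBg)
  pw <- cfg$peakWidthRange
  mkPeak <- function(slotIdx) {
    w <- sample(pw[1]:pw[2], nrow <- length(slotIdx), replace = TRUE)
    off <- vapply(1100L - 300L - w, function(m) sample(0:m, 1L), integer(1))
    GRanges(slots$chrom[slotIdx],
            IRanges(slots$start[slotIdx] + off, width = w),
            seqinfo = seqinfo(genes))
  }
  interPeaks <- mkPeak(c(planted$slot, bgSlots))
  names(interPeaks) <- sprintf("peak_%04d", seq_along(interPeaks))
  interPeaks$class <- "intergenic"
  interPeaks$planted <- c(rep(TRUE, nrow(planted)), rep(FALSE, nBg))
  interPeaks$direction <- c(planted$direction, rep(NA_character_, nBg))
  interPeaks$targetGene <- c(planted$targetGene, rep(NA_character_, nBg))

  decoyGene <- sample(seq_along(genes), cfg$nDecoyPeaks, replace = TRUE)
  dw <- pmin(width(genes)[decoyGene] - 1L,
             sample(pw[1]:pw[2], cfg$nDecoyPeaks, replace = TRUE))
  dOff <- vapply(width(genes)[decoyGene] - dw,
                 function(m) sample(0:m, 1L), integer(1))
  decoys <- GRanges(seqnames(genes)[decoyGene],
                    IRanges(start(genes)[decoyGene] + dOff, width = dw),
                    seqinfo = seqinfo(genes))
  names(decoys) <- sprintf("decoy_%04d", seq_along(decoys))
  decoys$class <- "decoy"
  decoys$planted <- FALSE
  decoys$direction <- NA_character_
  decoys$targetGene <- NA_character_

  peaks <- sort(c(interPeaks, decoys), ignore.strand = TRUE)
  truth <- list(
    plantedIds = names(interPeaks)[interPeaks$planted],
    directions = stats::setNames(interPeaks$direction[interPeaks$planted],
                                 names(interPeaks)[interPeaks$planted]),
    targets = stats::setNames(interPeaks$targetGene[interPeaks$planted],
                              names(interPeaks)[interPeaks$planted]),
    decoyIds = names(decoys))
  list(genes = genes, chromSizes = chromSizes, peaks = peaks, zones = zones,
       truth = truth)
}

#' Simulate stranded NB counts, coupled gene expression and metadata
#'
#' Background regions draw NB counts with a common mean in both cohorts;
#' planted "gain" regions have their mean multiplied by `2^plantedLog2FC` in
#' cohort B (and "loss" regions in cohort A). Counts are split between
#' strands binomially with the bidirectional fraction. Each planted eRNA
#' adds `windowCoupling` times its standardised count signal to every gene
#' within the net-change window of its centre — so a gene's expected
#' expression shift is proportional to the net eRNA change around it — and
#' additionally couples its designated target gene with strength
#' `targetCoupling` to the within-cohort residual of that signal, which
#' makes the target the most correlated gene without altering cohort-level
#' fold changes.
#'
#' @param cfg a [simConfig()].
#' @param genome output of [simulateGenome()].
#' @return list with `se` (an [ErnaExperiment-class] over all peaks), `meta`
#'   (sample_id, cohort), `geneExpr`, and an extended `truth` (true labels,
#'   per-gene expected net change).
#' @export
simulateCounts <- function(cfg, genome) {
  set.seed(cfg$seed + 22L)
  nS <- cfg$nA + cfg$nB
  sampleIds <- c(sprintf("BO_%02d", seq_len(cfg$nA)),
                 sprintf("OAC_%02d", seq_len(cfg$nB)))
  cohort <- factor(rep(c("BO", "OAC"), c(cfg$nA, cfg$nB)),
                   levels = c("BO", "OAC"))
  peaks <- genome$peaks
  nR <- length(peaks)
  mu <- matrix(cfg$nbMean, nR, nS, dimnames = list(names(peaks), sampleIds))
  gain <- !is.na(peaks$direction) & peaks$direction == "gain"
  loss <- !is.na(peaks$direction) & peaks$direction == "loss"
  ## planted regions carry a latent per-sample enhancer activity: the cohort
  ## effect (log 2^lfc in the elevated cohort) plus idiosyncratic lognormal
  ## variation shared with the coupled genes below; the exp(sd^2/2) factor
  ## keeps cohort mean counts at nbMean and nbMean * 2^lfc exactly
  lfcLn <- log(2) * cfg$plantedLog2FC
  activity <- delta <- matrix(0, nR, nS, dimnames = dimnames(mu))
  for (i in which(gain | loss)) {
    elevated <- if (gain[i]) cohort == "OAC" else cohort == "BO"
    delta[i, ] <- stats::rnorm(nS, 0, cfg$activitySd)
    activity[i, ] <- ifelse(elevated, lfcLn, 0) + delta[i, ]
    mu[i, ] <- cfg$nbMean * exp(activity[i, ] - cfg$activitySd^2 / 2)
  }
  size <- if (cfg$nbDispersion > 0) 1 / cfg$nbDispersion else Inf
  counts <- matrix(stats::rnbinom(nR * nS, mu = mu, size = size), nR, nS,
                   dimnames = dimnames(mu))
  plus <- matrix(stats::rbinom(nR * nS, counts, cfg$bidirFraction), nR, nS,
                 dimnames = dimnames(mu))
  minus <- counts - plus
  libSizes <- round(stats::rlnorm(nS, cfg$libSizeMeanLog, cfg$libSizeSdLog))
  se <- ErnaExperiment(peaks, counts, plus, minus, libSizes,
                       colData = S4Vectors::DataFrame(cohort = cohort))

  genes <- genome$genes
  nG <- length(genes)
  baseline <- stats::rnorm(nG, cfg$exprBaselineMean, cfg$exprBaselineSd)
  geneExpr <- matrix(stats::rnorm(nG * nS, 0, cfg$noiseSd), nG, nS,
                     dimnames = list(genes$gene_id, sampleIds)) + baseline
  tss <- .tss0(genes)
  gchr <- as.character(seqnames(genes))
  cen <- .centre0(peaks)
  pchr <- as.character(seqnames(peaks))
  for (pid in genome$truth$plantedIds) {
    i <- match(pid, names(peaks))
    elevated <- if (peaks$direction[i] == "gain") cohort == "OAC" else cohort == "BO"
    zBetween <- as.numeric(scale(as.numeric(elevated)))
    zRes <- as.numeric(scale(delta[i, ]))
    tgt <- genome$truth$targets[[pid]]
    nbr <- which(gchr == pchr[i] & abs(tss - cen[i]) <= cfg$netHalfWindow)
    ## genes near the enhancer respond to its cohort-level activation; the
    ## designated target additionally tracks its enhancer's sample-to-sample
    ## activity, which is what the correlation linkage has to find
    for (g in nbr)
      geneExpr[g, ] <- geneExpr[g, ] + cfg$windowCoupling * zBetween
    geneExpr[match(tgt, genes$gene_id), ] <-
      geneExpr[match(tgt, genes$gene_id), ] + cfg$targetCoupling * zRes
  }

  trueLabels <- rep("unclassified", nR)
  trueLabels[gain] <- "B_specific"
  trueLabels[loss] <- "A_specific"
  names(trueLabels) <- names(peaks)
  truth <- genome$truth
  truth$trueLabels <- trueLabels
  meta <- data.frame(sample_id = sampleIds, cohort = as.character(cohort),
                     stringsAsFactors = FALSE)
  list(se = se, meta = meta, geneExpr = geneExpr, truth = truth)
}

#' Expand simulated counts into per-sample fragment sets
#'
#' Each count becomes one fragment of `fragmentLength` bp whose midpoint is
#' uniform within its region (so midpoint counting must reproduce the count
#' matrix exactly); the library size of a sample is its total fragment count.
#'
#' @param cfg a [simConfig()].
#' @param genome output of [simulateGenome()].
#' @param sim output of [simulateCounts()].
#' @return named list of stranded fragment `GRanges`, one per sample.
#' @export
makeFragments <- function(cfg, genome, sim) {
  set.seed(cfg$seed + 33L)
  peaks <- genome$peaks
  half <- cfg$fragmentLength %/% 2L
  pl <- plusCounts(sim$se)
  mi <- minusCounts(sim$se)
  sl <- genome$chromSizes
  lapply(stats::setNames(nm = colnames(sim$se)), function(s) {
    repPlus <- rep(seq_along(peaks), pl[, s])
    repMinus <- rep(seq_along(peaks), mi[, s])
    idx <- c(repPlus, repMinus)
    strands <- rep(c("+", "-"), c(length(repPlus), length(repMinus)))
    lo <- start(peaks)[idx] - 1L
    hi <- end(peaks)[idx] - 1L
    mid <- lo + floor(stats::runif(length(idx)) * (hi - lo + 1L))
    st <- pmax(0L, mid - half)
    en <- pmin(sl[as.character(seqnames(peaks))[idx]], mid + half)
    ord <- sample(length(idx))
    fr <- GRanges(as.character(seqnames(peaks))[idx][ord],
                  IRanges(st[ord] + 1L, en[ord]), strand = strands[ord],
                  seqinfo = seqinfo(peaks))
    attr(fr, "librarySize") <- length(fr)
    fr
  })
}

#' Simulate survival driven by one gene's expression
#'
#' Hazard is `baselineHazard * exp(beta * z)` with `z` the standardised
#' expression of the driver gene; event times are exponential given the
#' hazard and censoring times are uniform on `(0, cmax)` with `cmax`
#' calibrated to the target censoring fraction.
#'
#' @param cfg a [simConfig()].
#' @param expr gene x sample expression matrix.
#' @param gene driver gene id (default: first row).
#' @return list with `surv` (`data.frame`: sample_id, time, event) and
#'   `truth` (`gene`, `beta`).
#' @export
simulateSurvival <- function(cfg, expr, gene = rownames(expr)[1]) {
  set.seed(cfg$seed + 44L)
  stopifnot(gene %in% rownames(expr))
  n <- ncol(expr)
  z <- as.numeric(scale(as.numeric(expr[gene, ])))
  hazard <- cfg$baselineHazard * exp(cfg$survBeta * z)
  tEvent <- stats::rexp(n, rate = hazard)
  if (cfg$censoringFraction > 0) {
    u <- stats::runif(n)
    cmax <- stats::uniroot(function(cc) mean(cc * u < tEvent) - cfg$censoringFraction,
                           c(1e-9, 1e3 * max(tEvent)))$root
    cens <- cmax * u
  } else cens <- rep(Inf, n)
  time <- pmin(tEvent, cens)
  list(surv = data.frame(sample_id = colnames(expr), time = time,
                         event = as.integer(tEvent <= cens),
                         stringsAsFactors = FALSE),
       truth = list(gene = gene, beta = cfg$survBeta))
}

#' Simulate the full synthetic study
#'
#' Runs [simulateGenome()], [simulateCounts()] and [simulateSurvival()] (the
#' survival driver is the first planted gain target, so the signature search
#' has a recoverable gene), each on its own RNG stream derived from the
#' master seed.
#'
#' @param cfg a [simConfig()].
#' @return list with `genome`, `se`, `meta`, `geneExpr`, `surv`, `truth`.
#' @export
simulateStudy <- function(cfg) {
  genome <- simulateGenome(cfg)
  sim <- simulateCounts(cfg, genome)
  driver <- unname(sim$truth$targets[sim$truth$directions == "gain"][1])
  if (is.na(driver) || is.null(driver)) driver <- rownames(sim$geneExpr)[1]
  sv <- simulateSurvival(cfg, sim$geneExpr, gene = driver)
  truth <- sim$truth
  truth$survGene <- sv$truth$gene
  truth$survBeta <- sv$truth$beta
  list(genome = genome, se = sim$se, meta = sim$meta, geneExpr = sim$geneExpr,
       surv = sv$surv, truth = truth)
}

#' Write a simulated study to disk in standard text formats
#'
#' Emits `genome.gtf`, `chrom.sizes`, per-ATAC-sample peak BEDs (random
#' subsets of the union with small coordinate jitter, so the union-merge
#' stage has real work to do), per-RNA-sample fragment BED6 files, the gene
#' expression, metadata and survival TSVs, and `truth.json`.
#'
#' @param cfg a [simConfig()].
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return named list of file paths (with `fragmentBeds` and `peakBeds`
#'   vectors).
#' @export
writeSimulation <- function(cfg, study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- study$genome
  p <- function(f) file.path(dir, f)

  g <- genome$genes
  g$source <- "sim"
  g$type <- "gene"
  rtracklayer::export(g, p("genome.gtf"), format = "gtf")
  utils::write.table(data.frame(names(genome$chromSizes),
                                unname(genome$chromSizes)),
                     p("chrom.sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  set.seed(cfg$seed + 55L)
  peaks <- genome$peaks
  nP <- length(peaks)
  anchor <- sample(cfg$nAtacSamples, nP, replace = TRUE)
  peakBeds <- character(cfg$nAtacSamples)
  for (a in seq_len(cfg$nAtacSamples)) {
    keep <- anchor == a | stats::runif(nP) < 0.5
    sub <- peaks[keep]
    jit <- function(n) sample(seq(-cfg$peakJitter, cfg$peakJitter), n, replace = TRUE)
    sub <- GRanges(seqnames(sub),
                   IRanges(start(sub) + jit(sum(keep)), end(sub) + jit(sum(keep))),
                   seqinfo = seqinfo(sub))
    names(sub) <- names(peaks)[keep]
    peakBeds[a] <- p(sprintf("atac_%02d.bed", a))
    writeBed(sub, peakBeds[a])
  }

  frags <- makeFragments(cfg, genome, study)
  fragmentBeds <- vapply(names(frags), function(s) {
    fr <- frags[[s]]
    fr$score <- 0L
    path <- p(sprintf("fragments_%s.bed", s))
    writeBed(fr, path)
    path
  }, character(1))

  utils::write.table(cbind(gene_id = rownames(study$geneExpr),
                           as.data.frame(study$geneExpr)),
                     p("gene_expr.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$meta, p("meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$surv, p("survival.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  list(gtf = p("genome.gtf"), chromSizes = p("chrom.sizes"),
       peakBeds = peakBeds, fragmentBeds = fragmentBeds,
       geneExpr = p("gene_expr.tsv"), meta = p("meta.tsv"),
       survival = p("survival.tsv"), truth = p("truth.json"))
}
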