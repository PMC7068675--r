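# Synthetic-data generation: random tripartite interaction networks, matched
# case/control expression bundles with planted dysregulated loops, and the
# companion gene-set / ceRNA / drug fixtures.  This is the test harness that
# stands in for a deposited whole-blood RNA-seq cohort (8 cases + 8 controls)
# plus the external interaction/annotation/drug databases.

#' Generate a random tripartite interaction network
#'
#' Draws each possible gene->miRNA, gene->lncRNA and miRNA->lncRNA edge
#' independently with its layer's probability, then enumerates the
#' resulting feedforward loops.
#'
#' @param nGenes,nMirnas,nLncrnas node counts per type.
#' @param edgeProb scalar or length-3 vector of per-layer edge
#'   probabilities, order `gene-miRNA`, `gene-lncRNA`, `miRNA-lncRNA`.
#' @param seed integer RNG seed.
#' @return list with `edges` (data.frame) and `network`
#'   ([FFLNetwork-class]).
#' @export
generateNetwork <- function(nGenes, nMirnas, nLncrnas, edgeProb, seed = 1L) {
  if (length(edgeProb) == 1L) edgeProb <- rep(edgeProb, 3)
  stopifnot(length(edgeProb) == 3, all(edgeProb >= 0), all(edgeProb <= 1),
            nGenes >= 1, nMirnas >= 1, nLncrnas >= 1)
  set.seed(as.integer(seed))
  genes <- sprintf("G%03d", seq_len(nGenes))
  mirs <- sprintf("MIR%03d", seq_len(nMirnas))
  lncs <- sprintf("LNC%03d", seq_len(nLncrnas))
  layerEdges <- function(src, tgt, p, layer) {
    grid <- expand.grid(source = src, target = tgt,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < p
    if (!any(keep)) return(NULL)
    cbind(grid[keep, , drop = FALSE],
          layer = layer, evidence = "simulated")
  }
  edges <- rbind(layerEdges(genes, mirs, edgeProb[1], "gene-miRNA"),
                 layerEdges(genes, lncs, edgeProb[2], "gene-lncRNA"),
                 layerEdges(mirs, lncs, edgeProb[3], "miRNA-lncRNA"))
  if (is.null(edges)) edges <- .emptyEdgeFrame()
  rownames(edges) <- NULL
  list(edges = edges, network = enumerateFFLs(edges))
}

# edge set of n node-disjoint triplets (one loop each)
.disjointTripletEdges <- function(n) {
  genes <- sprintf("G%03d", seq_len(n))
  mirs <- sprintf("MIR%03d", seq_len(n))
  lncs <- sprintf("LNC%03d", seq_len(n))
  rbind(data.frame(source = genes, target = mirs, layer = "gene-miRNA",
                   evidence = "simulated", stringsAsFactors = FALSE),
        data.frame(source = genes, target = lncs, layer = "gene-lncRNA",
                   evidence = "simulated", stringsAsFactors = FALSE),
        data.frame(source = mirs, target = lncs, layer = "miRNA-lncRNA",
                   evidence = "simulated", stringsAsFactors = FALSE))
}

#' Planted-effect table for dysregulated triplets
#'
#' Builds the per-loop effect specification consumed by
#' [syntheticTruth()].  Controls are equicorrelated at `rhoCtrl`; in cases
#' the coupling of one molecule (default the lncRNA) flips sign, so the two
#' edges involving it rewire from `rhoCtrl` to `-rhoCtrl` (a full
#' positive-to-negative transition) while the third edge keeps its control
#' correlation.  A three-edge simultaneous flip is not representable -- no
#' valid correlation matrix has all three pairwise correlations at -0.8 --
#' so the single-molecule sign flip is the strongest feasible version of
#' that rewiring.  Mean shifts are expressed in within-group SD units and
#' applied to the case group.
#'
#' @param triplets data.frame with `gene`, `miRNA`, `lncRNA`.
#' @param meanShift scalar or length-3 vector (gene, miRNA, lncRNA) of
#'   case-group mean shifts in SD units; default 2.
#' @param rhoCtrl control-group equicorrelation, default 0.8.
#' @param flip which molecule's coupling flips in cases: `"lncRNA"`
#'   (default), `"miRNA"`, `"gene"` or `"none"`.
#' @return data.frame suitable for the `planted` slot of
#'   [SyntheticTruth-class].
#' @export
plantedEffects <- function(triplets, meanShift = 2, rhoCtrl = 0.8,
                           flip = c("lncRNA", "miRNA", "gene", "none")) {
  flip <- match.arg(flip)
  if (length(meanShift) == 1L) meanShift <- rep(meanShift, 3)
  if (nrow(triplets) == 0L) {
    out <- .emptyFFLFrame()
    for (nm in c("shift_gene", "shift_miRNA", "shift_lncRNA",
                 "rho_ctrl_lnc_mir", "rho_ctrl_lnc_gene",
                 "rho_ctrl_mir_gene", "rho_case_lnc_mir",
                 "rho_case_lnc_gene", "rho_case_mir_gene"))
      out[[nm]] <- numeric()
    return(out)
  }
  s <- c(lnc_mir = 1, lnc_gene = 1, mir_gene = 1)
  if (flip == "lncRNA") s[c("lnc_mir", "lnc_gene")] <- -1
  if (flip == "miRNA") s[c("lnc_mir", "mir_gene")] <- -1
  if (flip == "gene") s[c("lnc_gene", "mir_gene")] <- -1
  data.frame(triplets[, c("gene", "miRNA", "lncRNA"), drop = FALSE],
             shift_gene = meanShift[1], shift_miRNA = meanShift[2],
             shift_lncRNA = meanShift[3],
             rho_ctrl_lnc_mir = rhoCtrl, rho_ctrl_lnc_gene = rhoCtrl,
             rho_ctrl_mir_gene = rhoCtrl,
             rho_case_lnc_mir = s[["lnc_mir"]] * rhoCtrl,
             rho_case_lnc_gene = s[["lnc_gene"]] * rhoCtrl,
             rho_case_mir_gene = s[["mir_gene"]] * rhoCtrl,
             stringsAsFactors = FALSE)
}

#' Construct a SyntheticTruth object
#'
#' @param planted data.frame from [plantedEffects()] (may have 0 rows for a
#'   global-null dataset).
#' @param rhoBackground within-triplet correlation of unplanted loops,
#'   identical in both groups; default 0.3.
#' @param nCase,nControl group sizes; default 8 + 8, the matched-cohort
#'   design the pipeline targets.
#' @param noiseSd overall expression scale (within-group SD); default 1.
#' @param seed integer seed recorded with the dataset.
#' @return a [SyntheticTruth-class].
#' @export
syntheticTruth <- function(planted = plantedEffects(.emptyFFLFrame()),
                           rhoBackground = 0.3, nCase = 8L, nControl = 8L,
                           noiseSd = 1, seed = 1L) {
  new("SyntheticTruth", planted = planted,
      rhoBackground = rhoBackground, nCase = as.integer(nCase),
      nControl = as.integer(nControl), noiseSd = noiseSd,
      seed = as.integer(seed))
}

# symmetric square root of a 3x3 correlation matrix; errors (naming the
# triplet) when the target is not positive semi-definite
.corSqrt <- function(R, label) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    .stopf("infeasible correlation targets for triplet %s (matrix not positive semi-definite)",
           label)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Generate a matched case/control expression bundle with planted signal
#'
#' Latent-factor Gaussian model.  Every molecule starts as independent
#' standard normal noise (times `noiseSd`).  Loops are then "claimed" in
#' order -- planted loops first, remaining loops lexicographically -- and a
#' claimed loop's three molecules are redrawn jointly from a trivariate
#' normal whose within-group correlation matrix matches the loop's target
#' correlations (background loops use the equicorrelated background rho in
#' both groups).  A loop only claims molecules not already claimed by an
#' earlier loop, so in networks with shared molecules the correlation
#' targets are guaranteed for a maximal node-disjoint subset (scenario
#' generators use fully disjoint loops, where every target is realised).
#' Planted case-group mean shifts are added last, in SD units.
#'
#' @param network an [FFLNetwork-class].
#' @param truth a [SyntheticTruth-class]; planted loops must be loops of
#'   `network`.
#' @return an [ExpressionBundle-class] with samples ordered case first,
#'   then control.
#' @export
generateBundle <- function(network, truth) {
  stopifnot(is(network, "FFLNetwork"), is(truth, "SyntheticTruth"))
  loopTab <- ffls(network)
  nk <- .fflKey(loopTab$gene, loopTab$miRNA, loopTab$lncRNA)
  pk <- .fflKey(truth@planted$gene, truth@planted$miRNA,
                truth@planted$lncRNA)
  if (!all(pk %in% nk))
    .stopf("planted FFL(s) not present in the network: %s",
           paste(utils::head(setdiff(pk, nk)), collapse = "; "))
  set.seed(truth@seed)
  n1 <- truth@nCase; n2 <- truth@nControl; n <- n1 + n2
  caseIdx <- seq_len(n1); ctrlIdx <- n1 + seq_len(n2)
  samples <- c(sprintf("case_%02d", seq_len(n1)),
               sprintf("control_%02d", seq_len(n2)))

  nodes <- fflNodes(network)
  mats <- list()
  for (ty in c("gene", "miRNA", "lncRNA")) {
    ids <- nodes$id[nodes$type == ty]
    m <- matrix(stats::rnorm(length(ids) * n, sd = truth@noiseSd),
                nrow = length(ids), dimnames = list(ids, samples))
    mats[[ty]] <- m
  }

  # claim order: planted loops first, then the rest lexicographically
  ordTab <- rbind(truth@planted[, c("gene", "miRNA", "lncRNA"), drop = FALSE],
                  loopTab[!nk %in% pk, , drop = FALSE])
  claimed <- character()
  rhoB <- truth@rhoBackground
  for (i in seq_len(nrow(ordTab))) {
    g <- ordTab$gene[i]; m <- ordTab$miRNA[i]; l <- ordTab$lncRNA[i]
    mk <- .normId(c(l, m, g))
    if (any(mk %in% claimed)) next
    claimed <- c(claimed, mk)
    planted <- i <= nrow(truth@planted)
    if (planted) {
      pr <- truth@planted[i, ]
      Rctrl <- matrix(c(1, pr$rho_ctrl_lnc_mir, pr$rho_ctrl_lnc_gene,
                        pr$rho_ctrl_lnc_mir, 1, pr$rho_ctrl_mir_gene,
                        pr$rho_ctrl_lnc_gene, pr$rho_ctrl_mir_gene, 1), 3)
      Rcase <- matrix(c(1, pr$rho_case_lnc_mir, pr$rho_case_lnc_gene,
                        pr$rho_case_lnc_mir, 1, pr$rho_case_mir_gene,
                        pr$rho_case_lnc_gene, pr$rho_case_mir_gene, 1), 3)
    } else {
      Rctrl <- Rcase <- matrix(rhoB, 3, 3); diag(Rctrl) <- diag(Rcase) <- 1
    }
    lab <- paste(g, m, l, sep = "/")
    vals <- cbind(.corSqrt(Rcase, lab) %*% matrix(stats::rnorm(3 * n1), 3),
                  .corSqrt(Rctrl, lab) %*% matrix(stats::rnorm(3 * n2), 3)) *
      truth@noiseSd
    if (planted) {
      pr <- truth@planted[i, ]
      vals[1, caseIdx] <- vals[1, caseIdx] + pr$shift_lncRNA * truth@noiseSd
      vals[2, caseIdx] <- vals[2, caseIdx] + pr$shift_miRNA * truth@noiseSd
      vals[3, caseIdx] <- vals[3, caseIdx] + pr$shift_gene * truth@noiseSd
    }
    mats$lncRNA[l, ] <- vals[1, ]
    mats$miRNA[m, ] <- vals[2, ]
    mats$gene[g, ] <- vals[3, ]
  }
  ExpressionBundle(mats$gene, mats$miRNA, mats$lncRNA,
                   rep(c("case", "control"), c(n1, n2)))
}

#' Simulate a complete analysis scenario
#'
#' Builds the network, truth ledger, expression bundle and companion
#' fixtures for one of three stated worlds:
#' \describe{
#'   \item{`null`}{`nFFLs` node-disjoint loops, no planted signal --
#'     both groups share the background correlation and means.  Used for
#'     permutation-calibration checks.}
#'   \item{`planted`}{as `null`, plus `nPlanted` loops planted dysregulated
#'     (case mean shift `meanShift` SD on all three molecules; control
#'     equicorrelation 0.8 rewired by an lncRNA sign flip to -0.8 on the
#'     two lncRNA edges).}
#'   \item{`paper_shaped`}{30 planted loops among `nFFLs`, with two
#'     overlapping gene sets built so that 11 planted loops are
#'     glycometabolism-annotated and 29 hormone-annotated with exactly 10
#'     in common; plus ceRNA triplets sharing gene+miRNA with the first
#'     planted loops, and a 29-drug association table (21 of them labelled
#'     hormonal or anti-inflammatory) targeting planted-loop molecules.}
#' }
#'
#' @param scenario `"null"`, `"planted"` or `"paper_shaped"`.
#' @param nFFLs number of loops (default 200).
#' @param nPlanted planted loops for the `planted` scenario (default 10).
#' @param meanShift case mean shift in SD units (default 2).
#' @param rhoCtrl planted control-group correlation (default 0.8).
#' @param rhoBackground background correlation (default 0.3).
#' @param nCase,nControl group sizes (default 8 + 8).
#' @param seed integer seed.
#' @return list with `edges`, `network`, `bundle`, `truth`, and (scenario
#'   dependent) `geneSets`, `cernas`, `drugs`.
#' @export
simulateScenario <- function(scenario = c("null", "planted", "paper_shaped"),
                             nFFLs = 200L, nPlanted = 10L, meanShift = 2,
                             rhoCtrl = 0.8, rhoBackground = 0.3,
                             nCase = 8L, nControl = 8L, seed = 1L) {
  scenario <- match.arg(scenario)
  seed <- as.integer(seed)
  edges <- .disjointTripletEdges(nFFLs)
  network <- enumerateFFLs(edges)
  loops <- ffls(network)
  set.seed(seed)
  out <- list(edges = edges, network = network)

  if (scenario == "null") {
    planted <- plantedEffects(.emptyFFLFrame())
  } else if (scenario == "planted") {
    stopifnot(nPlanted <= nFFLs)
    sel <- sort(sample.int(nFFLs, nPlanted))
    planted <- plantedEffects(loops[sel, ], meanShift = meanShift,
                              rhoCtrl = rhoCtrl)
  } else {
    nP <- 30L
    stopifnot(nFFLs >= nP)
    sel <- sort(sample.int(nFFLs, nP))
    planted <- plantedEffects(loops[sel, ], meanShift = meanShift,
                              rhoCtrl = rhoCtrl)
    # gene sets: 11 glyco / 29 hormone planted loops, overlap exactly 10
    pGenes <- planted$gene
    bgPool <- setdiff(loops$gene, pGenes)
    nBg <- min(40L, length(bgPool) %/% 2L)
    bg <- sample(bgPool, 2L * nBg)
    out$geneSets <- list(
      glycometabolism = sort(c(pGenes[1:11], bg[seq_len(nBg)])),
      hormone = sort(c(pGenes[2:30], bg[nBg + seq_len(nBg)])))
    # ceRNA triplets: share gene + miRNA with the first three planted loops
    out$cernas <- rbind(
      data.frame(gene = planted$gene[1:3], miRNA = planted$miRNA[1:3],
                 lncRNA = sprintf("LNCCE%02d", 1:3),
                 stringsAsFactors = FALSE),
      data.frame(gene = sprintf("GCE%02d", 1:2),
                 miRNA = sprintf("MIRCE%02d", 1:2),
                 lncRNA = sprintf("LNCCE%02d", 4:5),
                 stringsAsFactors = FALSE))
    # 29 drugs on planted-loop molecules; 21 hormonal/anti-inflammatory
    targets <- c(planted$gene[1:15], planted$miRNA[1:14])
    types <- rep(c("gene", "miRNA"), c(15, 14))
    out$drugs <- data.frame(
      drug = sprintf("drug%02d", 1:29), target = targets,
      target_type = types,
      category = c(rep("hormonal", 11), rep("anti-inflammatory", 10),
                   rep("other", 8)),
      stringsAsFactors = FALSE)
  }
  truth <- syntheticTruth(planted, rhoBackground = rhoBackground,
                          nCase = nCase, nControl = nControl, seed = seed)
  out$truth <- truth
  out$bundle <- generateBundle(network, truth)
  out
}

#' Write a complete simulated input set to disk
#'
#' Emits `edges.tsv`, the three expression matrices, `design.tsv`,
#' `genesets.gmt` (paper-shaped scenario), `cerna.tsv`, `drugs.tsv`,
#' `planted.tsv` (the truth ledger) and `manifest.json` recording every
#' generator parameter and the seed.  Output is byte-identical for a given
#' seed.
#'
#' @param outDir output directory (created if missing).
#' @param scenario passed to [simulateScenario()].
#' @param seed integer seed.
#' @param ... further arguments to [simulateScenario()].
#' @return invisibly, the scenario list (with `$dir` added).
#' @export
generateFixtures <- function(outDir, scenario = c("null", "planted",
                                                  "paper_shaped"),
                             seed = 1L, ...) {
  scenario <- match.arg(scenario)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  sim <- simulateScenario(scenario, seed = seed, ...)
  .writeTsv(sim$edges, file.path(outDir, "edges.tsv"))
  writeBundle(sim$bundle, outDir)
  .writeTsv(sim$truth@planted, file.path(outDir, "planted.tsv"))
  if (!is.null(sim$geneSets)) {
    gmt <- vapply(names(sim$geneSets), function(nm)
      paste(c(nm, "synthetic gene set", sim$geneSets[[nm]]),
            collapse = "\t"), character(1))
    writeLines(gmt, file.path(outDir, "genesets.gmt"))
  }
  if (!is.null(sim$cernas))
    .writeTsv(sim$cernas, file.path(outDir, "cerna.tsv"))
  if (!is.null(sim$drugs))
    .writeTsv(sim$drugs, file.path(outDir, "drugs.tsv"))
  manifest <- list(scenario = scenario, seed = sim$truth@seed,
                   n_ffls = nFFLs(sim$network),
                   n_planted = nrow(sim$truth@planted),
                   rho_background = sim$truth@rhoBackground,
                   n_case = sim$truth@nCase, n_control = sim$truth@nControl,
                   noise_sd = sim$truth@noiseSd)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  sim$dir <- outDir
  invisible(sim)
}
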