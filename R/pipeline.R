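#' Run the full dysregulated lnc-FFL pipeline
#'
#' Chains the stages end to end: read edges and expression -> enumerate the
#' loop network -> (optionally) restrict to gene-set subnetworks -> score
#' every loop with permutation significance -> extract key/core modules from
#' the dysregulated network -> (optionally) merge with ceRNA triplets and
#' overlay drug associations.  Every stage's tables are written into
#' `outDir` before the next stage starts, and a `manifest.json` records the
#' full configuration, seed, per-stage row counts and wall time.  Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config named list (or path to a JSON file holding one) with
#'   entries: `edges` (path or character vector), `gene`, `mirna`,
#'   `lncrna`, `design` (paths), optional `genesets` (GMT path),
#'   `cerna` (triplet TSV), `drugs` (association TSV), and parameters
#'   `B` (default 1000), `seed` (default 1), `alpha` (0.05), `tau` (0.3),
#'   `min_size` (4), `penalty` (2), `min_shared` (2), `log2p1` (FALSE),
#'   `group_aliases` (named vector), `categories_of_interest`.
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory stage results
#'   (`network`, `scores`, `dysregulated`, per-gene-set results, modules,
#'   `drugNetwork`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(B = 1000L, seed = 1L, alpha = 0.05, tau = 0.3,
                   min_size = 4L, penalty = 2, min_shared = 2L,
                   log2p1 = FALSE,
                   categories_of_interest = c("hormonal",
                                              "anti-inflammatory"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  required <- c("edges", "gene", "mirna", "lncrna", "design")
  miss <- required[!required %in% names(config)]
  if (length(miss))
    .stopf("config is missing required input path(s): %s",
           paste(miss, collapse = ", "))
  for (nm in c(required, "genesets", "cerna", "drugs")) {
    p <- config[[nm]]
    if (!is.null(p) && !all(file.exists(p)))
      .stopf("config: input file for '%s' not found: %s", nm,
             paste(p[!file.exists(p)], collapse = ", "))
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(config = config[order(names(config))],
                   stages = list())
  stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    .msgf("stage %-12s %s", name,
          paste(names(counts), unlist(counts), sep = "=", collapse = " "))
  }

  ## build
  edges <- readEdgeLists(config$edges)
  network <- enumerateFFLs(edges)
  writeNetworkTables(network, file.path(outDir, "network"))
  stage("build", list(edges = nrow(edges), ffls = nFFLs(network)))

  ## expression
  aliases <- config$group_aliases
  if (is.null(aliases))
    aliases <- c(case = "case", control = "control", case = "GDM",
                 control = "NGT")
  bundle <- readBundle(config$gene, config$mirna, config$lncrna,
                       config$design, groupAliases = aliases,
                       log2p1 = isTRUE(config$log2p1))
  stage("expression", list(samples = length(sampleIds(bundle))))

  ## subnetworks
  targets <- list(global = network)
  if (!is.null(config$genesets)) {
    gs <- readGeneSets(config$genesets)
    for (nm in names(gs)) targets[[nm]] <- extractSubnetwork(network, gs[[nm]])
    stage("subnet", lapply(targets[-1], nFFLs))
  }

  ## score each target network with its own derived seed
  results <- list()
  for (k in seq_along(targets)) {
    nm <- names(targets)[k]
    if (nFFLs(targets[[nm]]) < 2L) {
      .warnf("network '%s' has < 2 FFLs; skipping scoring", nm)
      next
    }
    sc <- scoreFFLs(bundle, targets[[nm]], B = config$B,
                    seed = as.integer(config$seed) + k - 1L,
                    alpha = config$alpha, tau = config$tau)
    writeScoreTable(sc, file.path(outDir, paste0("scores_", nm, ".tsv")))
    results[[nm]] <- sc
  }
  stage("score", lapply(results, nrow))

  ## set relations between dysregulated gene-set loop sets
  dysSets <- lapply(results, function(sc)
    sc[isTRUE(config$B > 0) & sc$dysregulated %in% TRUE, , drop = FALSE])
  if (length(dysSets) >= 3L) {
    nms <- setdiff(names(dysSets), "global")[1:2]
    rel <- fflSetRelations(dysSets[[nms[1]]], dysSets[[nms[2]]])
    .writeTsv(rel$common, file.path(outDir, "ffls_common.tsv"))
    .writeTsv(rel$only_a, file.path(outDir,
                                    paste0("ffls_only_", nms[1], ".tsv")))
    .writeTsv(rel$only_b, file.path(outDir,
                                    paste0("ffls_only_", nms[2], ".tsv")))
    stage("venn", list(common = nrow(rel$common),
                       only_a = nrow(rel$only_a),
                       only_b = nrow(rel$only_b)))
  }

  ## dysregulated network + modules
  dysGlobal <- dysSets$global
  out <- list(network = network, bundle = bundle, scores = results,
              dysregulated = dysGlobal)
  if (!is.null(dysGlobal) && nrow(dysGlobal) > 0L) {
    dysNet <- enumerateFFLs(.edgesOfTriplets(network, dysGlobal))
    writeNetworkTables(dysNet, file.path(outDir, "dysregulated_network"))
    km <- keyModule(dysNet)
    writeModuleTable(km, file.path(outDir, "key_module.tsv"))
    cm <- coreModules(dysNet, minSize = config$min_size,
                      penalty = config$penalty)
    if (length(cm))
      writeModuleTable(cm, file.path(outDir, "core_modules.tsv"))
    out$keyModule <- km
    out$coreModules <- cm
    stage("modules", list(key_size = nrow(km$nodes), core = length(cm)))
    if (!is.null(config$cerna)) {
      cernas <- utils::read.table(config$cerna, header = TRUE, sep = "\t",
                                  colClasses = "character",
                                  stringsAsFactors = FALSE)
      cx <- mergeWithCernas(dysGlobal, cernas,
                            minShared = config$min_shared)
      if (length(cx))
        writeModuleTable(cx, file.path(outDir, "complex_modules.tsv"))
      out$complexModules <- cx
      stage("cerna", list(complex = length(cx)))
    }
    if (!is.null(config$drugs)) {
      assoc <- readDrugAssociations(config$drugs)
      dn <- buildDrugNetwork(dysGlobal, assoc)
      .writeTsv(dn$edges, file.path(outDir, "drug_edges.tsv"))
      frac <- if (dn$n_drugs > 0)
        categoryFraction(dn, config$categories_of_interest) else NA_real_
      jsonlite::write_json(
        list(n_drugs = dn$n_drugs, n_targets = dn$n_targets,
             fraction_of_interest = frac,
             categories_of_interest = config$categories_of_interest),
        file.path(outDir, "drug_summary.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
      out$drugNetwork <- dn
      stage("drugs", list(drugs = dn$n_drugs, targets = dn$n_targets))
    }
  }

  manifest$seed <- as.integer(config$seed)
  manifest$wall_time_sec <- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
  manifest$package_version <- as.character(utils::packageVersion("lncFFLnet"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}

# edges of `network` supporting the given triplets
.edgesOfTriplets <- function(network, triplets) {
  ek <- paste(.normId(network@edges$source), .normId(network@edges$target),
              network@edges$layer, sep = "\r")
  nk <- c(paste(.normId(triplets$gene), .normId(triplets$miRNA),
                "gene-miRNA", sep = "\r"),
          paste(.normId(triplets$gene), .normId(triplets$lncRNA),
                "gene-lncRNA", sep = "\r"),
          paste(.normId(triplets$miRNA), .normId(triplets$lncRNA),
                "miRNA-lncRNA", sep = "\r"))
  network@edges[ek %in% nk, , drop = FALSE]
}
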