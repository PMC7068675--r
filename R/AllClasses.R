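#' @import methods
NULL

#' FFLNetwork: a typed tripartite regulatory network with its feedforward loops
#'
#' An `FFLNetwork` holds the three typed interaction layers of an
#' lncRNA-mediated feedforward loop (lnc-FFL) network -- gene to miRNA, gene
#' to lncRNA and miRNA to lncRNA edges -- together with the enumerated loop
#' triplets and the node table.  A loop (gene g, miRNA m, lncRNA l) exists iff
#' all three directed edges g->m, g->l and m->l are present.  After
#' enumeration, nodes and edges are restricted to loop participants, so the
#' object is closed: re-enumerating its own edges reproduces the same loops.
#'
#' @slot edges data.frame with columns `source`, `target`, `layer`,
#'   `evidence`; `layer` is one of `"gene-miRNA"`, `"gene-lncRNA"`,
#'   `"miRNA-lncRNA"`.
#' @slot ffls data.frame with columns `gene`, `miRNA`, `lncRNA`, one row per
#'   loop, sorted lexicographically.
#' @slot nodes data.frame with columns `id`, `type`
#'   (`gene`/`miRNA`/`lncRNA`).
#'
#' @seealso [enumerateFFLs()], [readEdgeLists()], [extractSubnetwork()]
#' @exportClass FFLNetwork
setClass("FFLNetwork",
  representation(edges = "data.frame", ffls = "data.frame",
                 nodes = "data.frame"),
  prototype(edges = .emptyEdgeFrame(), ffls = .emptyFFLFrame(),
            nodes = .emptyNodeFrame())
)

setValidity("FFLNetwork", function(object) {
  msgs <- character()
  if (!all(c("source", "target", "layer") %in% names(object@edges)))
    msgs <- c(msgs, "edges must have columns source, target, layer")
  if (!all(c("gene", "miRNA", "lncRNA") %in% names(object@ffls)))
    msgs <- c(msgs, "ffls must have columns gene, miRNA, lncRNA")
  if (!all(c("id", "type") %in% names(object@nodes)))
    msgs <- c(msgs, "nodes must have columns id, type")
  if (nrow(object@edges) && !all(object@edges$layer %in% .LAYERS))
    msgs <- c(msgs, sprintf("edge layers must be one of: %s",
                            paste(.LAYERS, collapse = ", ")))
  if (nrow(object@nodes) &&
      !all(object@nodes$type %in% c("gene", "miRNA", "lncRNA")))
    msgs <- c(msgs, "node types must be gene/miRNA/lncRNA")
  if (anyDuplicated(.fflKey(object@ffls$gene, object@ffls$miRNA,
                            object@ffls$lncRNA)))
    msgs <- c(msgs, "duplicate FFL triplets")
  if (length(msgs)) msgs else TRUE
})

#' ExpressionBundle: matched gene/miRNA/lncRNA expression with group labels
#'
#' Three feature-by-sample expression matrices over the same ordered set of
#' samples, plus a two-level group factor (`case`/`control`).  The samples
#' are matched subjects, so any label permutation must be applied identically
#' to all three matrices; the bundle enforces the shared ordering at
#' construction.  Values are continuous, already-normalised expression;
#' the scoring statistics (Student t-test, Pearson correlation) are
#' scale-agnostic.
#'
#' @slot geneExpr,mirnaExpr,lncrnaExpr numeric matrices, features x samples,
#'   identical colnames in identical order.
#' @slot groups factor of length `ncol`, levels `c("case","control")`, with
#'   at least 3 samples per level.
#'
#' @seealso [readBundle()], [ExpressionBundle()], [scoreFFLs()]
#' @exportClass ExpressionBundle
setClass("ExpressionBundle",
  representation(geneExpr = "matrix", mirnaExpr = "matrix",
                 lncrnaExpr = "matrix", groups = "factor")
)

setValidity("ExpressionBundle", function(object) {
  msgs <- character()
  mats <- list(gene = object@geneExpr, miRNA = object@mirnaExpr,
               lncRNA = object@lncrnaExpr)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.numeric(m))
      msgs <- c(msgs, sprintf("%s matrix is not numeric", nm))
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msgs <- c(msgs, sprintf("%s matrix needs row and column names", nm))
    if (anyNA(m))
      msgs <- c(msgs, sprintf("%s matrix contains missing values", nm))
  }
  ids <- colnames(object@geneExpr)
  if (!identical(ids, colnames(object@mirnaExpr)) ||
      !identical(ids, colnames(object@lncrnaExpr)))
    msgs <- c(msgs, "sample ids differ (or differ in order) across matrices")
  if (!identical(levels(object@groups), c("case", "control")))
    msgs <- c(msgs, "groups must be a factor with levels case, control")
  if (length(object@groups) != ncol(object@geneExpr))
    msgs <- c(msgs, "groups length must equal the number of samples")
  else if (any(table(object@groups) < 3))
    msgs <- c(msgs, "each group needs >= 3 samples")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticTruth: the planted-signal ledger of a simulated dataset
#'
#' Records exactly which loop triplets were planted as dysregulated and with
#' what effect (per-molecule mean shifts in within-group standard-deviation
#' units; per-edge target correlations in control and case), plus the global
#' generator settings.  This is the oracle against which recovery of planted
#' signal is judged.
#'
#' @slot planted data.frame: `gene`, `miRNA`, `lncRNA`, `shift_gene`,
#'   `shift_miRNA`, `shift_lncRNA`, and six target correlations
#'   `rho_ctrl_lnc_mir`, `rho_ctrl_lnc_gene`, `rho_ctrl_mir_gene`,
#'   `rho_case_lnc_mir`, `rho_case_lnc_gene`, `rho_case_mir_gene`.
#' @slot rhoBackground within-triplet correlation used for unplanted
#'   triplets, identical in both groups.
#' @slot nCase,nControl group sizes (defaults mirror an 8 vs 8 design).
#' @slot noiseSd overall expression scale.
#' @slot seed integer seed the dataset was generated from.
#'
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(planted = "data.frame", rhoBackground = "numeric",
                 nCase = "integer", nControl = "integer",
                 noiseSd = "numeric", seed = "integer")
)

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  rho <- unlist(object@planted[grep("^rho_", names(object@planted))])
  if (length(rho) && any(abs(rho) > 1))
    msgs <- c(msgs, "target correlations must lie in [-1, 1]")
  if (abs(object@rhoBackground) >= 1)
    msgs <- c(msgs, "background correlation must lie in (-1, 1)")
  if (object@nCase < 3L || object@nControl < 3L)
    msgs <- c(msgs, "each group needs >= 3 samples")
  if (object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "FFLNetwork", function(object) {
  tt <- table(factor(object@nodes$type, levels = c("gene", "miRNA", "lncRNA")))
  cat(sprintf(
    "FFLNetwork: %d FFLs | %d nodes (%d genes, %d miRNAs, %d lncRNAs) | %d edges\n",
    nrow(object@ffls), nrow(object@nodes), tt[["gene"]], tt[["miRNA"]],
    tt[["lncRNA"]], nrow(object@edges)))
  invisible(NULL)
})

setMethod("show", "ExpressionBundle", function(object) {
  tb <- table(object@groups)
  cat(sprintf(
    "ExpressionBundle: %d samples (%d case, %d control)\n  genes: %d  miRNAs: %d  lncRNAs: %d\n",
    length(object@groups), tb[["case"]], tb[["control"]],
    nrow(object@geneExpr), nrow(object@mirnaExpr), nrow(object@lncrnaExpr)))
  invisible(NULL)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d planted dysregulated FFLs | background rho %.2f | n = %d + %d | seed %d\n",
    nrow(object@planted), object@rhoBackground, object@nCase,
    object@nControl, object@seed))
  invisible(NULL)
})
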