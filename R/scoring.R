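# Core dysregulation statistic for lnc-FFLs.
#
# For each loop (gene g, miRNA m, lncRNA l) and a two-group design:
#   CS_dif  = P_lncRNA * P_miRNA * P_gene              (two-sided Student t)
#   CS_PCC  = |(r^case_lm - r^ctrl_lm) *
#              (r^case_lg - r^ctrl_lg) *
#              (r^case_mg - r^ctrl_mg)|                (within-group Pearson)
# CS_dif is ranked ascending (small p-products = strong differential
# expression), CS_PCC descending (large rewiring first); the final score is
# the mean of the two ranks, and significance comes from recomputing the
# whole cascade under random sample-label permutations shared across the
# three matrices.

# --- vectorised row statistics ---------------------------------------------

# two-sided t-test p-value per row of X, case vs control columns
.rowTtestP <- function(X, caseIdx, ctrlIdx, welch = FALSE) {
  n1 <- length(caseIdx); n2 <- length(ctrlIdx)
  x1 <- X[, caseIdx, drop = FALSE]; x2 <- X[, ctrlIdx, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, nrow(X))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  # zero pooled variance: no usable evidence of a difference -> p := 1
  p[se2 == 0 | !is.finite(tstat)] <- 1
  p
}

# rows standardised within a column subset so that rowSums(za * zb) = Pearson r
.rowStandardize <- function(X, idx) {
  x <- X[, idx, drop = FALSE]
  cx <- x - rowMeans(x)
  ss <- sqrt(rowSums(cx^2))
  z <- cx / ss
  z[ss == 0, ] <- NA_real_   # zero variance: correlation undefined
  z
}

# all per-FFL statistics for one labelling; idx holds matched row indices
.fflStats <- function(mats, idx, caseIdx, ctrlIdx, welch = FALSE) {
  pg <- .rowTtestP(mats$gene, caseIdx, ctrlIdx, welch)[idx$gene]
  pm <- .rowTtestP(mats$miRNA, caseIdx, ctrlIdx, welch)[idx$miRNA]
  pl <- .rowTtestP(mats$lncRNA, caseIdx, ctrlIdx, welch)[idx$lncRNA]
  r <- list()
  for (grp in c("case", "ctrl")) {
    cols <- if (grp == "case") caseIdx else ctrlIdx
    zg <- .rowStandardize(mats$gene, cols)
    zm <- .rowStandardize(mats$miRNA, cols)
    zl <- .rowStandardize(mats$lncRNA, cols)
    r[[paste0(grp, "_lnc_mir")]] <-
      rowSums(zl[idx$lncRNA, , drop = FALSE] * zm[idx$miRNA, , drop = FALSE])
    r[[paste0(grp, "_lnc_gene")]] <-
      rowSums(zl[idx$lncRNA, , drop = FALSE] * zg[idx$gene, , drop = FALSE])
    r[[paste0(grp, "_mir_gene")]] <-
      rowSums(zm[idx$miRNA, , drop = FALSE] * zg[idx$gene, , drop = FALSE])
  }
  r <- lapply(r, function(v) pmin(1, pmax(-1, v)))  # guard float overshoot
  list(p_gene = pg, p_miRNA = pm, p_lncRNA = pl, corrs = r)
}

.resolveIdx <- function(bundle, fflTable) {
  idx <- list(
    gene = match(.normId(fflTable$gene),
                 .normId(rownames(exprMatrix(bundle, "gene")))),
    miRNA = match(.normId(fflTable$miRNA),
                  .normId(rownames(exprMatrix(bundle, "miRNA")))),
    lncRNA = match(.normId(fflTable$lncRNA),
                   .normId(rownames(exprMatrix(bundle, "lncRNA")))))
  miss <- is.na(idx$gene) | is.na(idx$miRNA) | is.na(idx$lncRNA)
  if (any(miss))
    .msgf("excluding %d FFL(s) with molecules absent from the expression matrices",
          sum(miss))
  list(idx = lapply(idx, function(v) v[!miss]), kept = which(!miss))
}

# --- exported building blocks ----------------------------------------------

#' Per-molecule differential-expression p-values of one FFL
#'
#' Two-sided Student (pooled-variance) t-test of case versus control for
#' each of the loop's three molecules.  Zero pooled variance yields p = 1
#' (a constant feature carries no evidence of a group difference).
#'
#' @param bundle an [ExpressionBundle-class].
#' @param ffl list or one-row data.frame with `gene`, `miRNA`, `lncRNA`.
#' @param welch use the unequal-variance (Welch) test instead of the
#'   classic Student test.
#' @return named numeric vector `c(p_gene=, p_miRNA=, p_lncRNA=)`.
#' @export
differentialPvalues <- function(bundle, ffl, welch = FALSE) {
  res <- .scoreCore(bundle, as.data.frame(ffl, stringsAsFactors = FALSE),
                    welch = welch)
  if (nrow(res) == 0L) .stopf("FFL molecules absent from the matrices")
  c(p_gene = res$p_gene, p_miRNA = res$p_miRNA, p_lncRNA = res$p_lncRNA)
}

#' Within-group edge correlations of one FFL
#'
#' Pearson correlation of lncRNA~miRNA, lncRNA~gene and miRNA~gene
#' expression, separately within the case and the control samples.  An
#' undefined correlation (a zero-variance molecule in that group) is mapped
#' to 0 with a warning.
#'
#' @inheritParams differentialPvalues
#' @return named numeric vector of six correlations
#'   (`r_case_lnc_mir`, ..., `r_ctrl_mir_gene`), each in `[-1, 1]`.
#' @export
edgeCorrelations <- function(bundle, ffl) {
  res <- .scoreCore(bundle, as.data.frame(ffl, stringsAsFactors = FALSE))
  if (nrow(res) == 0L) .stopf("FFL molecules absent from the matrices")
  unlist(res[1, c("r_case_lnc_mir", "r_case_lnc_gene", "r_case_mir_gene",
                  "r_ctrl_lnc_mir", "r_ctrl_lnc_gene", "r_ctrl_mir_gene")])
}

#' Composite dysregulation scores
#'
#' `cs_dif` is the product of the three differential-expression p-values
#' (smaller = stronger joint differential expression, range (0, 1]);
#' `cs_pcc` is the absolute product of the three case-minus-control
#' correlation differences (larger = stronger co-expression rewiring,
#' range [0, 8]).
#'
#' @param pvals numeric length-3 vector (gene, miRNA, lncRNA p-values).
#' @param corrs named numeric vector with the six correlations as returned
#'   by [edgeCorrelations()].
#' @return list with `cs_dif` and `cs_pcc`.
#' @examples
#' compositeScores(c(0.1, 0.2, 0.5),
#'                 c(r_case_lnc_mir = 1, r_ctrl_lnc_mir = -1,
#'                   r_case_lnc_gene = 1, r_ctrl_lnc_gene = -1,
#'                   r_case_mir_gene = 1, r_ctrl_mir_gene = -1))
#' @export
compositeScores <- function(pvals, corrs) {
  stopifnot(length(pvals) == 3)
  list(cs_dif = prod(pvals),
       cs_pcc = abs((corrs[["r_case_lnc_mir"]] - corrs[["r_ctrl_lnc_mir"]]) *
                    (corrs[["r_case_lnc_gene"]] - corrs[["r_ctrl_lnc_gene"]]) *
                    (corrs[["r_case_mir_gene"]] - corrs[["r_ctrl_mir_gene"]])))
}

#' Equal-weighted rank aggregation of the two composite scores
#'
#' `cs_dif` is ranked ascending and `cs_pcc` descending, so rank 1 is the
#' most dysregulated on either axis; ties get average (fractional) ranks,
#' which conserves the rank sum.  The final comprehensive score is the
#' arithmetic mean of the two ranks: lower = more dysregulated.
#'
#' @param csDif,csPcc numeric vectors of equal length (>= 2).
#' @return data.frame with `rank_dif`, `rank_pcc`, `final_score`.
#' @export
rankAndCombine <- function(csDif, csPcc) {
  if (length(csDif) < 2L)
    .stopf("rankAndCombine: ranking needs >= 2 FFLs")
  stopifnot(length(csDif) == length(csPcc))
  rd <- rank(csDif, ties.method = "average")
  rp <- rank(-csPcc, ties.method = "average")
  data.frame(rank_dif = rd, rank_pcc = rp, final_score = (rd + rp) / 2)
}

#' Correlation-transition pattern of each FFL edge
#'
#' Discretises a correlation into `negative` (r <= -tau), `none`
#' (|r| < tau) or `positive` (r >= tau) and labels each edge with its
#' control-to-case transition, e.g. `"positive->negative"` for a full sign
#' flip or `"negative->none"` for a lost negative coupling.
#'
#' @param rCtrl,rCase numeric vectors of control and case correlations.
#' @param tau threshold separating "no correlation" from signed
#'   correlation; default 0.3.
#' @return character vector of `state->state` labels.
#' @export
classifyPatterns <- function(rCtrl, rCase, tau = 0.3) {
  stopifnot(tau > 0, tau < 1, length(rCtrl) == length(rCase))
  state <- function(r) ifelse(r <= -tau, "negative",
                       ifelse(r >= tau, "positive", "none"))
  paste0(state(rCtrl), "->", state(rCase))
}

# --- full scorer ------------------------------------------------------------

# observed (or permuted) per-FFL table without ranks/permutation columns
.scoreCore <- function(bundle, fflTable, caseIdx = NULL, ctrlIdx = NULL,
                       welch = FALSE, warnUndefined = TRUE) {
  grp <- sampleGroups(bundle)
  if (is.null(caseIdx)) caseIdx <- which(grp == "case")
  if (is.null(ctrlIdx)) ctrlIdx <- which(grp == "control")
  mats <- list(gene = exprMatrix(bundle, "gene"),
               miRNA = exprMatrix(bundle, "miRNA"),
               lncRNA = exprMatrix(bundle, "lncRNA"))
  rs <- .resolveIdx(bundle, fflTable)
  out <- fflTable[rs$kept, c("gene", "miRNA", "lncRNA"), drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) return(out)
  st <- .fflStats(mats, rs$idx, caseIdx, ctrlIdx, welch)
  out$p_gene <- st$p_gene
  out$p_miRNA <- st$p_miRNA
  out$p_lncRNA <- st$p_lncRNA
  cr <- st$corrs
  und <- FALSE
  for (nm in names(cr)) {
    if (anyNA(cr[[nm]])) { und <- TRUE; cr[[nm]][is.na(cr[[nm]])] <- 0 }
  }
  if (und && warnUndefined)
    .warnf("undefined correlation(s) from zero-variance features mapped to 0")
  out$cs_dif <- out$p_gene * out$p_miRNA * out$p_lncRNA
  out$r_case_lnc_mir <- cr$case_lnc_mir
  out$r_ctrl_lnc_mir <- cr$ctrl_lnc_mir
  out$r_case_lnc_gene <- cr$case_lnc_gene
  out$r_ctrl_lnc_gene <- cr$ctrl_lnc_gene
  out$r_case_mir_gene <- cr$case_mir_gene
  out$r_ctrl_mir_gene <- cr$ctrl_mir_gene
  out$cs_pcc <- abs((cr$case_lnc_mir - cr$ctrl_lnc_mir) *
                    (cr$case_lnc_gene - cr$ctrl_lnc_gene) *
                    (cr$case_mir_gene - cr$ctrl_mir_gene))
  out
}

#' Score all FFLs of a network for dysregulation
#'
#' Runs the full cascade on every loop of `network`: per-molecule Student
#' t-tests, within-group edge correlations, the two composite scores
#' (`cs_dif`, `cs_pcc`), equal-weighted rank aggregation into a final
#' comprehensive score, and (optionally) an empirical permutation p-value.
#'
#' Each permutation draws ONE random shuffle of the sample labels and
#' applies it identically to the gene, miRNA and lncRNA matrices -- the
#' samples are matched subjects, and permuting the layers independently
#' would destroy exactly the cross-layer structure the statistic measures.
#' The whole cascade (t-tests, correlations, composite scores, ranking) is
#' recomputed per permutation, and for loop i
#' \deqn{p_i = (1 + \#\{b: final_b(i) \le final_{obs}(i)\}) / (B + 1),}
#' the add-one estimator, so p = 0 is impossible and the smallest
#' attainable p is 1/(B+1).  Loops with `perm_p < alpha` are flagged
#' dysregulated.
#'
#' @param bundle an [ExpressionBundle-class].
#' @param network an [FFLNetwork-class] (or a data.frame of triplets with
#'   columns `gene`, `miRNA`, `lncRNA`).
#' @param B number of label permutations (>= 100; default 1000).  `B = 0`
#'   skips the permutation test (ranks and final scores only).
#' @param seed integer seed for the permutation RNG.
#' @param alpha significance threshold on the raw permutation p-value
#'   (default 0.05; no multiple-testing correction by default, see `bh`).
#' @param tau correlation threshold for [classifyPatterns()].
#' @param welch use Welch instead of Student t-tests.
#' @param bh if TRUE, additionally report Benjamini-Hochberg adjusted
#'   permutation p-values in `perm_p_bh` (flagging still uses the raw p).
#' @return data.frame with one row per scored FFL and columns
#'   `gene, miRNA, lncRNA, p_gene, p_miRNA, p_lncRNA, cs_dif,
#'   r_case_lnc_mir, r_ctrl_lnc_mir, r_case_lnc_gene, r_ctrl_lnc_gene,
#'   r_case_mir_gene, r_ctrl_mir_gene, cs_pcc, rank_dif, rank_pcc,
#'   final_score, perm_p, dysregulated, pattern_lnc_mir, pattern_lnc_gene,
#'   pattern_mir_gene`.
#' @seealso [rankAndCombine()], [classifyPatterns()]
#' @export
scoreFFLs <- function(bundle, network, B = 1000, seed = NULL, alpha = 0.05,
                      tau = 0.3, welch = FALSE, bh = FALSE) {
  stopifnot(is(bundle, "ExpressionBundle"))
  fflTable <- if (is(network, "FFLNetwork")) ffls(network) else
    as.data.frame(network, stringsAsFactors = FALSE)
  if (!all(c("gene", "miRNA", "lncRNA") %in% names(fflTable)))
    .stopf("network must provide gene/miRNA/lncRNA triplets")
  if (B != 0 && B < 100)
    .stopf("B must be 0 (skip) or >= 100 (resolution too coarse below that)")

  obs <- .scoreCore(bundle, fflTable, welch = welch)
  if (nrow(obs) < 2L)
    .stopf("scoring needs >= 2 FFLs present in the matrices")
  rk <- rankAndCombine(obs$cs_dif, obs$cs_pcc)
  obs$rank_dif <- rk$rank_dif
  obs$rank_pcc <- rk$rank_pcc
  obs$final_score <- rk$final_score

  if (B > 0) {
    grp <- sampleGroups(bundle)
    n <- length(grp)
    caseN <- sum(grp == "case")
    if (!is.null(seed)) set.seed(seed)
    exceed <- integer(nrow(obs))
    mats <- list(gene = exprMatrix(bundle, "gene"),
                 miRNA = exprMatrix(bundle, "miRNA"),
                 lncRNA = exprMatrix(bundle, "lncRNA"))
    rs <- .resolveIdx(bundle, obs)
    for (b in seq_len(B)) {
      ord <- sample.int(n)
      permCase <- ord[seq_len(caseN)]
      permCtrl <- ord[(caseN + 1L):n]
      st <- .fflStats(mats, rs$idx, permCase, permCtrl, welch)
      cr <- st$corrs
      for (nm in names(cr)) cr[[nm]][is.na(cr[[nm]])] <- 0
      csDif <- st$p_gene * st$p_miRNA * st$p_lncRNA
      csPcc <- abs((cr$case_lnc_mir - cr$ctrl_lnc_mir) *
                   (cr$case_lnc_gene - cr$ctrl_lnc_gene) *
                   (cr$case_mir_gene - cr$ctrl_mir_gene))
      fin <- (rank(csDif, ties.method = "average") +
              rank(-csPcc, ties.method = "average")) / 2
      exceed <- exceed + (fin <= obs$final_score)
    }
    obs$perm_p <- (1 + exceed) / (B + 1)
    obs$dysregulated <- obs$perm_p < alpha
    if (bh) obs$perm_p_bh <- stats::p.adjust(obs$perm_p, method = "BH")
  } else {
    obs$perm_p <- NA_real_
    obs$dysregulated <- NA
  }
  obs$pattern_lnc_mir <- classifyPatterns(obs$r_ctrl_lnc_mir,
                                          obs$r_case_lnc_mir, tau)
  obs$pattern_lnc_gene <- classifyPatterns(obs$r_ctrl_lnc_gene,
                                           obs$r_case_lnc_gene, tau)
  obs$pattern_mir_gene <- classifyPatterns(obs$r_ctrl_mir_gene,
                                           obs$r_case_mir_gene, tau)
  obs
}

#' Write a per-FFL score table
#'
#' @param scores data.frame from [scoreFFLs()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeScoreTable <- function(scores, path) {
  .writeTsv(scores, path)
}
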