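#' Construct an ExpressionBundle
#'
#' @param geneExpr,mirnaExpr,lncrnaExpr numeric matrices (features x
#'   samples) with identical column names in identical order.
#' @param groups factor or character of per-sample labels; coerced to a
#'   factor with levels `c("case", "control")`.
#' @return an [ExpressionBundle-class].
#' @export
ExpressionBundle <- function(geneExpr, mirnaExpr, lncrnaExpr, groups) {
  groups <- factor(as.character(groups), levels = c("case", "control"))
  if (anyNA(groups))
    .stopf("group labels must be 'case' or 'control'")
  new("ExpressionBundle", geneExpr = as.matrix(geneExpr),
      mirnaExpr = as.matrix(mirnaExpr), lncrnaExpr = as.matrix(lncrnaExpr),
      groups = groups)
}

.readMatrixTsv <- function(path, naPolicy = c("error", "drop-feature")) {
  naPolicy <- match.arg(naPolicy)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .stopf("matrix file %s needs a feature-id column plus sample columns",
           basename(path))
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids))
    .stopf("matrix file %s: duplicate feature id(s): %s", basename(path),
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]) &
                   trimws(vals[[j]]) != "NA" & trimws(vals[[j]]) != "")
      if (length(bad))
        .stopf("matrix file %s: non-numeric value '%s' at feature '%s', sample '%s'",
               basename(path), vals[bad[1], j], ids[bad[1]], names(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (anyNA(m)) {
    if (naPolicy == "error")
      .stopf("matrix file %s contains missing values (use naPolicy = 'drop-feature' to remove those features)",
             basename(path))
    drop <- rowSums(is.na(m)) > 0
    .msgf("%s: dropping %d feature(s) with missing values", basename(path),
          sum(drop))
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' Read the three expression matrices and the sample design
#'
#' Matrices are TSV with a feature-id first column and one column per
#' sample.  The design file has columns `sample_id` and `group`; groups are
#' mapped to `case`/`control` through `groupAliases` (so e.g. GDM/NGT files
#' work unchanged).  All three matrices must contain exactly the design's
#' samples; columns are reordered to the design order, which makes
#' downstream statistics invariant to the column order of the input files.
#'
#' @param genePath,mirnaPath,lncrnaPath paths to the three matrices.
#' @param designPath path to the design TSV.
#' @param groupAliases named character vector mapping design labels to
#'   `case`/`control`; default accepts `case`/`control`, `GDM`/`NGT`.
#' @param naPolicy `"error"` (default) or `"drop-feature"`.
#' @param log2p1 if TRUE, matrices are transformed to `log2(x + 1)` after
#'   reading (convenience for count-scale inputs; the pipeline itself is
#'   scale-agnostic).
#' @return an [ExpressionBundle-class].  Features with zero variance in
#'   both groups (which yield undefined correlations downstream) are
#'   reported with a message.
#' @export
readBundle <- function(genePath, mirnaPath, lncrnaPath, designPath,
                       groupAliases = c(case = "case", control = "control",
                                        case = "GDM", control = "NGT"),
                       naPolicy = c("error", "drop-feature"),
                       log2p1 = FALSE) {
  naPolicy <- match.arg(naPolicy)
  design <- utils::read.table(designPath, header = TRUE, sep = "\t",
                              quote = "", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(design)))
    .stopf("design file needs columns 'sample_id' and 'group'")
  design$sample_id <- trimws(design$sample_id)
  alias <- stats::setNames(names(groupAliases), groupAliases)
  grp <- alias[trimws(design$group)]
  if (anyNA(grp))
    .stopf("design file: unknown group label(s): %s",
           paste(unique(design$group[is.na(grp)]), collapse = ", "))
  mats <- list(gene = .readMatrixTsv(genePath, naPolicy),
               miRNA = .readMatrixTsv(mirnaPath, naPolicy),
               lncRNA = .readMatrixTsv(lncrnaPath, naPolicy))
  for (nm in names(mats)) {
    have <- colnames(mats[[nm]])
    missing <- setdiff(design$sample_id, have)
    extra <- setdiff(have, design$sample_id)
    if (length(missing) || length(extra))
      .stopf("%s matrix and design disagree on samples: missing from matrix {%s}, absent from design {%s}",
             nm, paste(missing, collapse = ", "),
             paste(extra, collapse = ", "))
    mats[[nm]] <- mats[[nm]][, design$sample_id, drop = FALSE]
    if (log2p1) mats[[nm]] <- log2(mats[[nm]] + 1)
  }
  if (any(table(factor(grp, levels = c("case", "control"))) < 3))
    .stopf("each group needs >= 3 samples")
  bundle <- ExpressionBundle(mats$gene, mats$miRNA, mats$lncRNA, grp)
  flat <- zeroVarianceFeatures(bundle)
  if (length(flat))
    .msgf("%d feature(s) with zero variance in both groups: %s",
          length(flat), paste(utils::head(flat, 5), collapse = ", "))
  bundle
}

#' Features with zero variance in both groups
#'
#' These features carry no information for the t-test or correlation
#' statistics (their p-value is defined as 1 and their correlations as 0).
#'
#' @param bundle an [ExpressionBundle-class].
#' @return character vector of feature ids (layer-prefixed).
#' @export
zeroVarianceFeatures <- function(bundle) {
  stopifnot(is(bundle, "ExpressionBundle"))
  grp <- bundle@groups
  out <- character()
  for (layer in c("gene", "miRNA", "lncRNA")) {
    m <- exprMatrix(bundle, layer)
    v1 <- apply(m[, grp == "case", drop = FALSE], 1, stats::var)
    v2 <- apply(m[, grp == "control", drop = FALSE], 1, stats::var)
    flat <- rownames(m)[v1 == 0 & v2 == 0]
    if (length(flat)) out <- c(out, paste0(layer, ":", flat))
  }
  out
}

#' Write an ExpressionBundle to TSV files
#'
#' Inverse of [readBundle()]: emits `gene.tsv`, `mirna.tsv`, `lncrna.tsv`
#' and `design.tsv` into `dir`.  Values are written with 10 significant
#' digits, so write-then-read round-trips losslessly at that precision and
#' reruns are byte-identical.
#'
#' @param bundle an [ExpressionBundle-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
writeBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "ExpressionBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("gene.tsv", "mirna.tsv", "lncrna.tsv",
                            "design.tsv"))
  mats <- list(exprMatrix(bundle, "gene"), exprMatrix(bundle, "miRNA"),
               exprMatrix(bundle, "lncRNA"))
  for (i in 1:3) {
    df <- data.frame(feature_id = rownames(mats[[i]]),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(mats[[i]], check.names = FALSE))
    .writeTsv(df, paths[i])
  }
  .writeTsv(data.frame(sample_id = sampleIds(bundle),
                       group = as.character(sampleGroups(bundle)),
                       stringsAsFactors = FALSE), paths[4])
  invisible(paths)
}
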