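#' Read typed interaction edge lists
#'
#' Reads one or more delimited files of regulatory interactions into a
#' validated edge table.  Each file must have a header and at least `source`
#' and `target` columns; the layer is either a `layer` column in the file or
#' supplied per file through `layers`.  Layers are spelled `gene-miRNA`,
#' `gene-lncRNA` and `miRNA-lncRNA`, and determine the molecule types of the
#' two endpoints.  Duplicate rows (same source, target and layer after
#' identifier trimming, matched case-insensitively) collapse to a single
#' edge; original casing of the first occurrence is kept.  Self edges and
#' nodes used with contradictory types across layers are input errors.
#'
#' @param paths character vector of file paths (TSV by default; `.csv`
#'   files are read comma-separated).
#' @param layers optional character vector, one layer per file, for files
#'   without a `layer` column.
#' @param nodeTypeMap optional data.frame with columns `id`, `type`
#'   declaring molecule types up front; edges contradicting it are rejected.
#' @return data.frame with columns `source`, `target`, `layer`, `evidence`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("source\ttarget\tlayer",
#'              "G1\tM1\tgene-miRNA",
#'              "G1\tL1\tgene-lncRNA",
#'              "M1\tL1\tmiRNA-lncRNA"), f)
#' readEdgeLists(f)
#' @export
readEdgeLists <- function(paths, layers = NULL, nodeTypeMap = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1)
  if (!is.null(layers) && length(layers) != length(paths))
    .stopf("layers must have one entry per file (%d files, %d layers)",
           length(paths), length(layers))
  pieces <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) .stopf("edge-list file not found: %s", p)
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(p, header = TRUE, sep = sep, quote = "",
                            colClasses = "character",
                            comment.char = "", stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      .warnf("edge-list file %s is empty", basename(p))
      next
    }
    if (!all(c("source", "target") %in% names(df)))
      .stopf("file %s: needs 'source' and 'target' columns", basename(p))
    if (!"layer" %in% names(df)) {
      if (is.null(layers))
        .stopf("file %s: no 'layer' column and no per-file layer given",
               basename(p))
      df$layer <- layers[i]
    }
    if (!"evidence" %in% names(df)) df$evidence <- ""
    df$source <- trimws(df$source)
    df$target <- trimws(df$target)
    df$layer <- trimws(df$layer)
    bad <- which(is.na(df$source) | is.na(df$target) | df$source == "" |
                 df$target == "" | is.na(df$layer) | df$layer == "")
    if (length(bad))
      .stopf("file %s: malformed row(s) at line(s) %s (missing source/target/layer)",
             basename(p), paste(bad + 1L, collapse = ", "))
    unknown <- setdiff(unique(df$layer), .LAYERS)
    if (length(unknown))
      .stopf("file %s: unknown layer(s): %s (expected %s)", basename(p),
             paste(unknown, collapse = ", "), paste(.LAYERS, collapse = ", "))
    pieces[[i]] <- df[, c("source", "target", "layer", "evidence")]
  }
  edges <- do.call(rbind, pieces)
  if (is.null(edges) || nrow(edges) == 0L) return(.emptyEdgeFrame())
  self <- .normId(edges$source) == .normId(edges$target)
  if (any(self))
    .stopf("self-edges are not allowed: %s",
           paste(unique(edges$source[self]), collapse = ", "))
  key <- paste(.normId(edges$source), .normId(edges$target), edges$layer,
               sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  .checkNodeTypes(edges, nodeTypeMap)
  rownames(edges) <- NULL
  edges
}

# node types implied by edge layers must be consistent; contradiction is an
# input error, never silently resolved
.checkNodeTypes <- function(edges, nodeTypeMap = NULL) {
  src <- vapply(edges$layer, function(l) .LAYER_TYPES[[l]][1], character(1))
  tgt <- vapply(edges$layer, function(l) .LAYER_TYPES[[l]][2], character(1))
  ids <- c(.normId(edges$source), .normId(edges$target))
  typ <- c(src, tgt)
  if (!is.null(nodeTypeMap)) {
    ids <- c(ids, .normId(nodeTypeMap$id))
    typ <- c(typ, as.character(nodeTypeMap$type))
  }
  tab <- unique(data.frame(id = ids, type = typ, stringsAsFactors = FALSE))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup))
    .stopf("node(s) used with contradictory molecule types: %s",
           paste(unique(dup), collapse = ", "))
  invisible(tab)
}

#' Enumerate lncRNA-mediated feedforward loops
#'
#' A loop (gene g, miRNA m, lncRNA l) is reported iff the edge set contains
#' all three of g->m (`gene-miRNA`), g->l (`gene-lncRNA`) and m->l
#' (`miRNA-lncRNA`).  Nodes and edges of the returned network are restricted
#' to loop participants, so enumeration is idempotent, and loops are sorted
#' lexicographically by (gene, miRNA, lncRNA) so output is reproducible.
#'
#' @param edges data.frame as returned by [readEdgeLists()] (columns
#'   `source`, `target`, `layer`, optional `evidence`).
#' @return an [FFLNetwork-class].
#' @examples
#' edges <- data.frame(source = c("G1", "G1", "M1"),
#'                     target = c("M1", "L1", "L1"),
#'                     layer = c("gene-miRNA", "gene-lncRNA", "miRNA-lncRNA"))
#' nFFLs(enumerateFFLs(edges))
#' @export
enumerateFFLs <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(new("FFLNetwork"))
  if (!"evidence" %in% names(edges)) edges$evidence <- ""
  .checkNodeTypes(edges)
  key <- paste(.normId(edges$source), .normId(edges$target), edges$layer,
               sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]

  gm <- edges[edges$layer == "gene-miRNA", , drop = FALSE]
  gl <- edges[edges$layer == "gene-lncRNA", , drop = FALSE]
  ml <- edges[edges$layer == "miRNA-lncRNA", , drop = FALSE]
  if (nrow(gm) == 0L || nrow(gl) == 0L || nrow(ml) == 0L) {
    net <- new("FFLNetwork")
    return(net)
  }
  gmk <- data.frame(gk = .normId(gm$source), gene = gm$source,
                    mk = .normId(gm$target), miRNA = gm$target,
                    stringsAsFactors = FALSE)
  glk <- data.frame(gk = .normId(gl$source),
                    lk = .normId(gl$target), lncRNA = gl$target,
                    stringsAsFactors = FALSE)
  cand <- merge(gmk, glk, by = "gk")
  if (nrow(cand) == 0L) return(new("FFLNetwork"))
  mlKey <- paste(.normId(ml$source), .normId(ml$target), sep = "\r")
  keep <- paste(cand$mk, cand$lk, sep = "\r") %in% mlKey
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(new("FFLNetwork"))

  ffls <- unique(data.frame(gene = cand$gene, miRNA = cand$miRNA,
                            lncRNA = cand$lncRNA, stringsAsFactors = FALSE))
  ord <- order(.normId(ffls$gene), .normId(ffls$miRNA), .normId(ffls$lncRNA))
  ffls <- ffls[ord, , drop = FALSE]
  rownames(ffls) <- NULL

  # keep only edges supporting at least one loop
  need <- unique(rbind(
    data.frame(s = .normId(ffls$gene), t = .normId(ffls$miRNA),
               layer = "gene-miRNA", stringsAsFactors = FALSE),
    data.frame(s = .normId(ffls$gene), t = .normId(ffls$lncRNA),
               layer = "gene-lncRNA", stringsAsFactors = FALSE),
    data.frame(s = .normId(ffls$miRNA), t = .normId(ffls$lncRNA),
               layer = "miRNA-lncRNA", stringsAsFactors = FALSE)))
  ek <- paste(.normId(edges$source), .normId(edges$target), edges$layer,
              sep = "\r")
  nk <- paste(need$s, need$t, need$layer, sep = "\r")
  sub <- edges[ek %in% nk, c("source", "target", "layer", "evidence"),
               drop = FALSE]
  sub <- sub[order(sub$layer, .normId(sub$source), .normId(sub$target)), ,
             drop = FALSE]
  rownames(sub) <- NULL

  nodes <- unique(rbind(
    data.frame(id = ffls$gene, type = "gene", stringsAsFactors = FALSE),
    data.frame(id = ffls$miRNA, type = "miRNA", stringsAsFactors = FALSE),
    data.frame(id = ffls$lncRNA, type = "lncRNA", stringsAsFactors = FALSE)))
  nodes <- nodes[!duplicated(.normId(nodes$id)), , drop = FALSE]
  nodes <- nodes[order(nodes$type, .normId(nodes$id)), , drop = FALSE]
  rownames(nodes) <- NULL

  new("FFLNetwork", edges = sub, ffls = ffls, nodes = nodes)
}

# undirected simple igraph over the network's edge set (multi-edges collapsed)
.asUndirectedGraph <- function(network) {
  ed <- network@edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network@nodes$id,
                          type = network@nodes$type,
                          stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Degree distribution of a network
#'
#' Node degrees are computed on the undirected simple projection of the edge
#' set (direction and duplicate edges dropped), and tabulated as (degree k,
#' number of nodes with that degree).
#'
#' @param x an [FFLNetwork-class] or an `igraph` graph.
#' @return data.frame with columns `degree` and `n_nodes`; the `n_nodes`
#'   column sums to the node count.
#' @rdname degreeDistribution
#' @export
setMethod("degreeDistribution", "FFLNetwork", function(x) {
  if (nrow(x@nodes) == 0L) .stopf("degreeDistribution: empty network")
  degreeDistribution(.asUndirectedGraph(x))
})

#' @rdname degreeDistribution
setMethod("degreeDistribution", "ANY", function(x) {
  if (!igraph::is_igraph(x))
    .stopf("degreeDistribution: expected an FFLNetwork or igraph object")
  if (igraph::vcount(x) == 0L) .stopf("degreeDistribution: empty network")
  deg <- igraph::degree(igraph::simplify(igraph::as_undirected(x)))
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
})

#' Log-log power-law fit of a degree distribution
#'
#' Ordinary least squares of `log10(n_nodes)` on `log10(degree)`.  A network
#' whose degree distribution follows a power law gives a straight line on
#' this scale; the returned R-squared summarises how closely the network
#' approximates scale-free topology.  When the log counts have zero
#' variance the fit carries no information and R-squared is reported as 0.
#'
#' @param dist data.frame as returned by [degreeDistribution()]; rows with
#'   `n_nodes == 0` or `degree == 0` are dropped before fitting.
#' @return list with `slope`, `intercept` and `r_squared` (in `[0, 1]`).
#' @export
scaleFreeFit <- function(dist) {
  stopifnot(is.data.frame(dist), all(c("degree", "n_nodes") %in% names(dist)))
  dist <- dist[dist$n_nodes > 0 & dist$degree > 0, , drop = FALSE]
  if (length(unique(dist$degree)) < 3L)
    .stopf("scaleFreeFit: need >= 3 distinct degrees with positive counts")
  x <- log10(dist$degree)
  y <- log10(dist$n_nodes)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0))
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Write the node/edge/FFL tables of a network
#'
#' Exports three TSVs: `nodes.tsv` (`id`, `type`, `degree`, `n_ffls`),
#' `edges.tsv` (`source`, `target`, `layer`, `evidence`) and `ffls.tsv`
#' (`gene`, `miRNA`, `lncRNA`).
#'
#' @param network an [FFLNetwork-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeNetworkTables <- function(network, dir) {
  stopifnot(is(network, "FFLNetwork"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- network@nodes
  if (nrow(nodes)) {
    g <- .asUndirectedGraph(network)
    deg <- igraph::degree(g)
    nodes$degree <- as.integer(deg[nodes$id])
    memb <- c(table(.normId(c(network@ffls$gene, network@ffls$miRNA,
                              network@ffls$lncRNA))))
    nodes$n_ffls <- as.integer(memb[.normId(nodes$id)])
  } else {
    nodes$degree <- integer()
    nodes$n_ffls <- integer()
  }
  paths <- file.path(dir, c("nodes.tsv", "edges.tsv", "ffls.tsv"))
  .writeTsv(nodes, paths[1])
  .writeTsv(network@edges, paths[2])
  .writeTsv(network@ffls, paths[3])
  invisible(paths)
}
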