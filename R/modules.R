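# Module extraction: key (hub) modules, ClusterONE-style core modules, and
# FFL/ceRNA complex modules.

#' Key module: the highest-degree node and its neighborhood
#'
#' Degrees are taken on the undirected simple projection.  Ties are broken
#' by the lexicographically smallest identifier; all tied hubs are reported
#' via a message.  The module is the hub, its full neighbor set, and the
#' induced edges.
#'
#' @param x an [FFLNetwork-class] or an `igraph` graph.
#' @return list with `hub`, `nodes` (data.frame `id`, `type`, `kind`),
#'   `edges` (data.frame `from`, `to`) and `kind = "key"`.
#' @rdname keyModule
#' @export
setMethod("keyModule", "FFLNetwork", function(x) {
  if (nrow(x@nodes) == 0L) .stopf("keyModule: empty network")
  keyModule(.asUndirectedGraph(x))
})

#' @rdname keyModule
setMethod("keyModule", "ANY", function(x) {
  if (!igraph::is_igraph(x))
    .stopf("keyModule: expected an FFLNetwork or igraph object")
  if (igraph::vcount(x) == 0L) .stopf("keyModule: empty network")
  g <- igraph::simplify(igraph::as_undirected(x))
  deg <- igraph::degree(g)
  top <- names(deg)[deg == max(deg)]
  if (length(top) > 1L)
    .msgf("hub tie between: %s (lexicographically smallest chosen)",
          paste(sort(top), collapse = ", "))
  hub <- sort(top)[1]
  members <- sort(unique(c(hub, names(igraph::neighbors(g, hub)))))
  sub <- igraph::induced_subgraph(g, members)
  ed <- igraph::as_data_frame(sub, what = "edges")
  typ <- igraph::vertex_attr(g, "type")
  nodes <- data.frame(id = members,
                      type = if (is.null(typ)) NA_character_ else
                        typ[match(members, igraph::V(g)$name)],
                      kind = "key", stringsAsFactors = FALSE)
  list(hub = hub, nodes = nodes,
       edges = data.frame(from = ed$from, to = ed$to,
                          stringsAsFactors = FALSE),
       kind = "key")
})

# cohesiveness of a node set S: w_in / (w_in + w_bound + penalty * |S|)
# (unweighted edges; `penalty` plays the role of the per-node penalty of
# the original cohesiveness-based clustering tool)
.growCluster <- function(A, deg, seed, penalty) {
  n <- nrow(A)
  inS <- logical(n)
  inS[seed] <- TRUE
  dS <- A[, seed]            # edges from each node into S
  win <- 0
  wbound <- deg[seed]
  size <- 1L
  f <- function(w_in, w_b, s) if (w_in + w_b + penalty * s == 0) 0 else
    w_in / (w_in + w_b + penalty * s)
  repeat {
    fCur <- f(win, wbound, size)
    # additions: external nodes with >= 1 edge into S
    addCand <- which(!inS & dS > 0)
    bestGain <- 0; bestNode <- NA_integer_; bestIsAdd <- TRUE
    if (length(addCand)) {
      winA <- win + dS[addCand]
      wbA <- wbound - dS[addCand] + (deg[addCand] - dS[addCand])
      fA <- winA / pmax(winA + wbA + penalty * (size + 1L), .Machine$double.eps)
      i <- which.max(fA)
      if (fA[i] > fCur + 1e-12) {
        bestGain <- fA[i] - fCur; bestNode <- addCand[i]; bestIsAdd <- TRUE
      }
    }
    if (size > 1L) {
      remCand <- which(inS)
      winR <- win - dS[remCand]
      wbR <- wbound + dS[remCand] - (deg[remCand] - dS[remCand])
      fR <- ifelse(winR + wbR + penalty * (size - 1L) == 0, 0,
                   winR / (winR + wbR + penalty * (size - 1L)))
      i <- which.max(fR)
      if (fR[i] > fCur + 1e-12 && fR[i] - fCur > bestGain) {
        bestGain <- fR[i] - fCur; bestNode <- remCand[i]; bestIsAdd <- FALSE
      }
    }
    if (is.na(bestNode)) break
    if (bestIsAdd) {
      inS[bestNode] <- TRUE
      win <- win + dS[bestNode]
      wbound <- wbound - dS[bestNode] + (deg[bestNode] - dS[bestNode])
      dS <- dS + A[, bestNode]
      size <- size + 1L
    } else {
      inS[bestNode] <- FALSE
      win <- win - dS[bestNode]
      wbound <- wbound + dS[bestNode] - (deg[bestNode] - dS[bestNode])
      dS <- dS - A[, bestNode]
      size <- size - 1L
    }
  }
  list(members = which(inS), cohesiveness = f(win, wbound, size))
}

#' Core modules: greedy cohesiveness clustering (ClusterONE-style)
#'
#' Re-implementation of greedy cohesiveness maximisation for dense-region
#' discovery: each unvisited node (taken in lexicographic order) seeds a
#' cluster that greedily adds boundary nodes or removes members while the
#' cohesiveness \eqn{f(S) = w_{in} / (w_{in} + w_{bound} + p|S|)} improves;
#' grown clusters overlapping with Jaccard >= `mergeThreshold` are merged,
#' and clusters below `minSize` dropped.  Defaults (`penalty = 2`,
#' `minSize = 4`, merge threshold 0.8) mirror the published defaults of the
#' original tool; bit-identity with it is not claimed.
#'
#' @param x an [FFLNetwork-class] or `igraph` graph (edges taken
#'   undirected, simplified).
#' @param minSize smallest reported module (default 4).
#' @param penalty per-node boundary penalty in the cohesiveness
#'   denominator (default 2).
#' @param mergeThreshold Jaccard overlap at or above which grown clusters
#'   are merged (default 0.8).
#' @return list of modules, each a list with `nodes` (data.frame `id`,
#'   `type`, `kind`), `cohesiveness` and `kind = "core"`, ordered by
#'   decreasing cohesiveness.
#' @rdname coreModules
#' @export
setMethod("coreModules", "FFLNetwork",
  function(x, minSize = 4, penalty = 2, mergeThreshold = 0.8) {
    if (nrow(x@nodes) == 0L) .stopf("coreModules: empty network")
    coreModules(.asUndirectedGraph(x), minSize, penalty, mergeThreshold)
  })

#' @rdname coreModules
setMethod("coreModules", "ANY",
  function(x, minSize = 4, penalty = 2, mergeThreshold = 0.8) {
    if (!igraph::is_igraph(x))
      .stopf("coreModules: expected an FFLNetwork or igraph object")
    g <- igraph::simplify(igraph::as_undirected(x))
    n <- igraph::vcount(g)
    if (n == 0L) .stopf("coreModules: empty network")
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    A[A > 1] <- 1
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(n))
    deg <- rowSums(A)
    typ <- igraph::vertex_attr(g, "type")

    clusters <- list()
    visited <- logical(n)
    for (seed in order(nm)) {
      if (visited[seed]) next
      cl <- .growCluster(A, deg, seed, penalty)
      visited[cl$members] <- TRUE
      clusters[[length(clusters) + 1L]] <- cl$members
    }
    if (!length(clusters)) return(list())

    # merge clusters with high Jaccard overlap (connected components of the
    # overlap graph, then union of members)
    k <- length(clusters)
    if (k > 1L) {
      ov <- matrix(FALSE, k, k)
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        inter <- length(intersect(clusters[[i]], clusters[[j]]))
        uni <- length(union(clusters[[i]], clusters[[j]]))
        ov[i, j] <- ov[j, i] <- uni > 0 && inter / uni >= mergeThreshold
      }
      og <- igraph::graph_from_adjacency_matrix(ov, mode = "undirected")
      comp <- igraph::components(og)$membership
      clusters <- lapply(split(seq_len(k), comp), function(ix)
        sort(unique(unlist(clusters[ix]))))
    }

    clusters <- Filter(function(m) length(m) >= minSize, clusters)
    out <- lapply(clusters, function(m) {
      sub <- A[m, m, drop = FALSE]
      win <- sum(sub) / 2
      wbound <- sum(A[m, -m, drop = FALSE])
      coh <- if (win + wbound + penalty * length(m) == 0) 0 else
        win / (win + wbound + penalty * length(m))
      ids <- sort(nm[m])
      list(nodes = data.frame(
             id = ids,
             type = if (is.null(typ)) NA_character_ else
               typ[match(ids, nm)],
             kind = "core", stringsAsFactors = FALSE),
           cohesiveness = coh, kind = "core")
    })
    out[order(-vapply(out, `[[`, numeric(1), "cohesiveness"))]
  })

#' Merge FFLs with ceRNA triplets into complex modules
#'
#' A loop and a competing-endogenous-RNA triplet merge when they share at
#' least `minShared` molecules (default 2, e.g. the same gene and miRNA).
#' Merging is transitive: complex modules are the connected components of
#' the bipartite FFL-ceRNA share graph, and each module is the union of its
#' member triplets' molecules.  Components without any FFL-ceRNA link are
#' not reported.
#'
#' @param ffls data.frame of loops (`gene`, `miRNA`, `lncRNA`).
#' @param cernas data.frame of ceRNA triplets (`gene`, `miRNA`, `lncRNA`).
#' @param minShared minimum shared molecules for a merge (>= 1; default 2).
#' @return list of modules, each with `nodes` (data.frame `id`, `type`,
#'   `kind`), `members` (data.frame `gene`, `miRNA`, `lncRNA`, `triplet`
#'   in `ffl`/`ceRNA`), and `kind = "complex"`.
#' @export
mergeWithCernas <- function(ffls, cernas, minShared = 2) {
  stopifnot(minShared >= 1)
  ffls <- as.data.frame(ffls, stringsAsFactors = FALSE)
  cernas <- as.data.frame(cernas, stringsAsFactors = FALSE)
  nf <- nrow(ffls); nc <- nrow(cernas)
  if (nf == 0L || nc == 0L) return(list())
  tripNodes <- function(df, i)
    c(.normId(df$gene[i]), .normId(df$miRNA[i]), .normId(df$lncRNA[i]))
  edges <- list()
  for (i in seq_len(nf)) for (j in seq_len(nc)) {
    if (length(intersect(tripNodes(ffls, i), tripNodes(cernas, j))) >=
        minShared)
      edges[[length(edges) + 1L]] <- c(i, nf + j)
  }
  if (!length(edges)) return(list())
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(cbind(em[, 1], em[, 2]),
                                   directed = FALSE)
  g <- igraph::simplify(g)
  memb <- igraph::components(g)$membership
  linked <- sort(unique(as.vector(em)))
  comps <- split(linked, memb[linked])
  lapply(unname(comps), function(ix) {
    isF <- ix <= nf
    mem <- rbind(
      if (any(isF)) cbind(ffls[ix[isF], c("gene", "miRNA", "lncRNA"),
                               drop = FALSE], triplet = "ffl"),
      if (any(!isF)) cbind(cernas[ix[!isF] - nf,
                                  c("gene", "miRNA", "lncRNA"),
                                  drop = FALSE], triplet = "ceRNA"))
    rownames(mem) <- NULL
    nodes <- unique(rbind(
      data.frame(id = mem$gene, type = "gene", stringsAsFactors = FALSE),
      data.frame(id = mem$miRNA, type = "miRNA", stringsAsFactors = FALSE),
      data.frame(id = mem$lncRNA, type = "lncRNA",
                 stringsAsFactors = FALSE)))
    nodes <- nodes[!duplicated(.normId(nodes$id)), , drop = FALSE]
    nodes <- nodes[order(nodes$type, .normId(nodes$id)), , drop = FALSE]
    nodes$kind <- "complex"
    rownames(nodes) <- NULL
    list(nodes = nodes, members = mem, kind = "complex")
  })
}

#' Write a list of modules as one TSV
#'
#' One row per (module, node): `module_id`, `node`, `type`, `kind`,
#' `cohesiveness` (empty for non-core modules).
#'
#' @param modules list of modules from [keyModule()], [coreModules()] or
#'   [mergeWithCernas()] (a single key module may be passed directly).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeModuleTable <- function(modules, path) {
  if (!is.null(modules$nodes)) modules <- list(modules)
  rows <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module_id = i, node = m$nodes$id, type = m$nodes$type,
               kind = m$kind,
               cohesiveness = if (is.null(m$cohesiveness)) NA_real_ else
                 m$cohesiveness,
               stringsAsFactors = FALSE)
  })
  .writeTsv(do.call(rbind, rows), path)
}
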