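# Independent oracles and small fixture builders used across the suite.

# Brute-force FFL enumeration: explicit triple loop over every
# (gene, miRNA, lncRNA) combination, checking the three edges by set
# membership.  Deliberately independent of the package's join-based code.
bruteForceFFLs <- function(edges) {
  norm <- function(x) toupper(trimws(x))
  gm <- edges[edges$layer == "gene-miRNA", , drop = FALSE]
  gl <- edges[edges$layer == "gene-lncRNA", , drop = FALSE]
  ml <- edges[edges$layer == "miRNA-lncRNA", , drop = FALSE]
  gmSet <- paste(norm(gm$source), norm(gm$target))
  glSet <- paste(norm(gl$source), norm(gl$target))
  mlSet <- paste(norm(ml$source), norm(ml$target))
  genes <- sort(unique(norm(c(gm$source, gl$source))))
  mirs <- sort(unique(norm(c(gm$target, ml$source))))
  lncs <- sort(unique(norm(c(gl$target, ml$target))))
  out <- list()
  for (g in genes) for (m in mirs) for (l in lncs) {
    if (paste(g, m) %in% gmSet && paste(g, l) %in% glSet &&
        paste(m, l) %in% mlSet)
      out[[length(out) + 1L]] <- c(gene = g, miRNA = m, lncRNA = l)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

fflKeys <- function(fflTable) {
  sort(paste(toupper(fflTable$gene), toupper(fflTable$miRNA),
             toupper(fflTable$lncRNA), sep = "|"))
}

# minimal one-loop edge set
minimalLoopEdges <- function() {
  data.frame(source = c("G1", "G1", "M1"), target = c("M1", "L1", "L1"),
             layer = c("gene-miRNA", "gene-lncRNA", "miRNA-lncRNA"),
             stringsAsFactors = FALSE)
}

# FFL network with a planted degree-10 hub: one gene regulating 7 miRNAs
# and 3 lncRNAs, with every miRNA also regulating every lncRNA
hubFixtureEdges <- function() {
  mirs <- sprintf("hub-mir-%d", 1:7)
  lncs <- sprintf("hub-lnc-%d", 1:3)
  rbind(
    data.frame(source = "HUBG", target = mirs, layer = "gene-miRNA",
               stringsAsFactors = FALSE),
    data.frame(source = "HUBG", target = lncs, layer = "gene-lncRNA",
               stringsAsFactors = FALSE),
    expand.grid(source = mirs, target = lncs, stringsAsFactors = FALSE) |>
      transform(layer = "miRNA-lncRNA"))
}

# undirected random graph with three planted dense blocks
plantedBlockGraph <- function(blockSize = 10, nBlocks = 3, pIn = 0.8,
                              pOut = 0.05, seed = 1) {
  set.seed(seed)
  n <- blockSize * nBlocks
  block <- rep(seq_len(nBlocks), each = blockSize)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) pIn else pOut
    A[i, j] <- A[j, i] <- as.integer(stats::runif(1) < p)
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  list(graph = g, block = block,
       members = split(sprintf("n%02d", seq_len(n)), block))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# average fractional rank computed from first principles
naiveAvgRank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}
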