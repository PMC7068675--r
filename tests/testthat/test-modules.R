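test_that("key module is the hub plus its full neighborhood", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- sprintf("v%d", 1:6)
  km <- keyModule(star)
  expect_equal(km$hub, "v1")
  expect_equal(nrow(km$nodes), 6L)

  # two disconnected triangles; one vertex of the second carries a pendant
  # node, making it the unique degree-3 hub
  g <- igraph::graph_from_literal(a - b, b - c, c - a,
                                  x - y, y - z, z - x, x - w)
  km2 <- keyModule(g)
  expect_equal(km2$hub, "x")
  expect_setequal(km2$nodes$id, c("w", "x", "y", "z"))

  # planted degree-10 hub: 7 miRNA + 3 lncRNA neighbors -> 11-node module
  net <- enumerateFFLs(hubFixtureEdges())
  km3 <- keyModule(net)
  expect_equal(km3$hub, "HUBG")
  expect_equal(nrow(km3$nodes), 11L)
  expect_equal(sum(km3$nodes$type == "miRNA"), 7L)
  expect_equal(sum(km3$nodes$type == "lncRNA"), 3L)
})

test_that("hub ties break lexicographically and hub degree is maximal", {
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- c("e", "d", "c", "b", "a")
  expect_message(km <- keyModule(ring), "tie")
  expect_equal(km$hub, "a")

  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(25, 0.2)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    km <- keyModule(g)
    deg <- igraph::degree(g)
    expect_equal(unname(deg[km$hub]), max(deg))
  }
  expect_error(keyModule(new("FFLNetwork")), "empty")
})

test_that("core modules split two cliques joined by one edge", {
  cl <- function(nodes) t(combn(nodes, 2))
  e <- rbind(cl(sprintf("a%d", 1:5)), cl(sprintf("b%d", 1:5)),
             c("a1", "b1"))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  mods <- coreModules(g, minSize = 4)
  expect_length(mods, 2L)
  ids <- lapply(mods, function(m) sort(m$nodes$id))
  expect_true(any(vapply(ids, identical, logical(1), sprintf("a%d", 1:5))))
  expect_true(any(vapply(ids, identical, logical(1), sprintf("b%d", 1:5))))
})

test_that("a single clique is one module with cohesiveness -> 1 as penalty -> 0", {
  cl <- t(combn(sprintf("c%d", 1:6), 2))
  g <- igraph::graph_from_edgelist(cl, directed = FALSE)
  mods <- coreModules(g, minSize = 4, penalty = 0)
  expect_length(mods, 1L)
  expect_setequal(mods[[1]]$nodes$id, sprintf("c%d", 1:6))
  expect_equal(mods[[1]]$cohesiveness, 1)
  modsP <- coreModules(g, minSize = 4, penalty = 2)
  expect_lt(modsP[[1]]$cohesiveness, 1)
})

test_that("core modules recover planted dense blocks", {
  pb <- plantedBlockGraph(blockSize = 10, nBlocks = 3, pIn = 0.8,
                          pOut = 0.05, seed = 5)
  mods <- coreModules(pb$graph, minSize = 4)
  for (blk in pb$members) {
    best <- max(vapply(mods, function(m) jaccard(m$nodes$id, blk),
                       numeric(1)))
    expect_gte(best, 0.8)
  }
  # sanity: module internal density >= global density
  A <- igraph::as_adjacency_matrix(pb$graph, sparse = FALSE)
  globalDensity <- igraph::edge_density(pb$graph)
  for (m in mods) {
    ix <- match(m$nodes$id, igraph::V(pb$graph)$name)
    k <- length(ix)
    dens <- sum(A[ix, ix]) / (k * (k - 1))
    expect_gte(dens, globalDensity)
  }
})

test_that("FFL-ceRNA merging follows the shared-molecule rule", {
  ffl <- data.frame(gene = "EP300", miRNA = "miR-150-5p", lncRNA = "ZFAS1")
  cer <- data.frame(gene = "EP300", miRNA = "miR-150-5p", lncRNA = "HCG27")
  mods <- mergeWithCernas(ffl, cer, minShared = 2)
  expect_length(mods, 1L)
  expect_equal(nrow(mods[[1]]$nodes), 4L)   # shared gene + miRNA, 2 lncRNAs
  expect_setequal(mods[[1]]$nodes$id,
                  c("EP300", "miR-150-5p", "ZFAS1", "HCG27"))

  # a single shared molecule is not enough at minShared = 2
  cer1 <- data.frame(gene = "OTHER", miRNA = "miR-150-5p", lncRNA = "HCG27")
  expect_length(mergeWithCernas(ffl, cer1, minShared = 2), 0L)

  # triplets have 3 molecules, so minShared = 4 can never merge
  expect_length(mergeWithCernas(ffl, cer, minShared = 4), 0L)
})

test_that("merging is transitive through chains of shares", {
  # A(ffl) - B(ceRNA) share 2; B - C(ffl) share 2; A and C share nothing
  ffl <- data.frame(gene = c("GA", "GC"), miRNA = c("M1", "M2"),
                    lncRNA = c("LA", "LC"))
  cer <- data.frame(gene = "GA", miRNA = "M2", lncRNA = "LC")
  # shares: ffl1-cer = {GA} (1), insufficient; adjust to share 2
  cer2 <- data.frame(gene = c("GA", "GC"), miRNA = c("M1", "M2"),
                     lncRNA = c("LB", "LB"))
  mods <- mergeWithCernas(ffl, cer2, minShared = 2)
  # ffl1 ~ cer2[1] via {GA, M1}; ffl2 ~ cer2[2] via {GC, M2};
  # cer2[1] ~ cer2[2] share LB but ceRNA-ceRNA links are not part of the
  # bipartite share graph -> two separate modules
  expect_length(mods, 2L)
  expect_equal(vapply(mods, function(m) nrow(m$members), integer(1)),
               c(2L, 2L))

  # a true chain: one ceRNA bridging two loops
  fflPair <- data.frame(gene = c("G1", "G1"), miRNA = c("M1", "M3"),
                        lncRNA = c("L1", "L3"))
  bridge <- data.frame(gene = "G1", miRNA = "M1", lncRNA = "L3")
  mods2 <- mergeWithCernas(fflPair, bridge, minShared = 2)
  expect_length(mods2, 1L)
  expect_equal(nrow(mods2[[1]]$members), 3L)
})

test_that("module tables are written in long format", {
  net <- enumerateFFLs(hubFixtureEdges())
  dir <- withr::local_tempdir()
  writeModuleTable(keyModule(net), file.path(dir, "key.tsv"))
  tab <- read.delim(file.path(dir, "key.tsv"))
  expect_equal(nrow(tab), 11L)
  expect_setequal(unique(tab$kind), "key")
})
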