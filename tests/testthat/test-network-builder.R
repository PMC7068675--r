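test_that("edge lists are read, trimmed and de-duplicated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tlayer",
               "G1\tM1\tgene-miRNA",
               "G1 \t M1\tgene-miRNA",   # duplicate up to whitespace
               "g1\tm2\tgene-miRNA"),    # case-insensitive ids, new edge
             f)
  edges <- readEdgeLists(f)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$source[1], "G1")   # original casing preserved

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("source\ttarget\tlayer", empty)
  expect_warning(e0 <- readEdgeLists(empty), "empty")
  expect_equal(nrow(e0), 0L)
})

test_that("the shipped demo fixture has 12 edges with correct layers", {
  f <- system.file("extdata", "edges_demo.tsv", package = "lncFFLnet")
  edges <- readEdgeLists(f)
  expect_equal(nrow(edges), 12L)
  expect_equal(as.vector(table(edges$layer)[c("gene-miRNA", "gene-lncRNA",
                                              "miRNA-lncRNA")]),
               c(5L, 3L, 4L))
  # hand count of the loop closure in the fixture
  expect_equal(nFFLs(enumerateFFLs(edges)), 4L)
})

test_that("malformed input is rejected with a useful error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tlayer", "G1\t\tgene-miRNA"), f)
  expect_error(readEdgeLists(f), "malformed row")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tlayer", "G1\tX1\tgene-miRNA",
               "X1\tL1\tgene-lncRNA"), f2)  # X1 used as miRNA and as gene
  expect_error(readEdgeLists(f2), "contradictory")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tlayer", "A1\ta1\tgene-miRNA"), f3)
  expect_error(readEdgeLists(f3), "self-edge")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tlayer", "G1\tM1\tgene-mirna"), f4)
  expect_error(readEdgeLists(f4), "unknown layer")
})

test_that("minimal motifs enumerate exactly", {
  expect_equal(nFFLs(enumerateFFLs(minimalLoopEdges())), 1L)
  expect_equal(ffls(enumerateFFLs(minimalLoopEdges()))$lncRNA, "L1")
  # incomplete motif: no miRNA->lncRNA closure
  expect_equal(nFFLs(enumerateFFLs(minimalLoopEdges()[1:2, ])), 0L)
  expect_equal(nFFLs(enumerateFFLs(NULL)), 0L)
})

test_that("enumeration matches the brute-force oracle on random graphs", {
  for (s in 1:8) {
    g <- generateNetwork(15, 15, 15, 0.15, seed = s)
    expect_identical(fflKeys(ffls(g$network)), bruteForceFFLs(g$edges),
                     info = paste("seed", s))
  }
})

test_that("enumeration is idempotent and monotone under edge addition", {
  g <- generateNetwork(12, 12, 12, 0.2, seed = 99)
  net <- g$network
  again <- enumerateFFLs(fflEdges(net))
  expect_identical(fflKeys(ffls(again)), fflKeys(ffls(net)))
  # adding edges can only add loops
  extra <- rbind(g$edges,
                 data.frame(source = "G001", target = "MIRX",
                            layer = "gene-miRNA", evidence = "",
                            stringsAsFactors = FALSE))
  expect_true(all(fflKeys(ffls(net)) %in%
                  fflKeys(ffls(enumerateFFLs(extra)))))
})

test_that("degree distribution is computed on the undirected projection", {
  expect_equal(degreeDistribution(igraph::make_star(6, mode = "undirected")),
               data.frame(degree = c(1L, 5L), n_nodes = c(5L, 1L)))
  one <- enumerateFFLs(minimalLoopEdges())
  expect_equal(degreeDistribution(one),
               data.frame(degree = 2L, n_nodes = 3L))
  # independent per-node count on a preferential-attachment graph
  set.seed(4)
  ba <- igraph::sample_pa(300, directed = FALSE)
  dd <- degreeDistribution(ba)
  expect_equal(sum(dd$n_nodes), 300L)
  deg <- igraph::degree(ba)
  expect_equal(dd$n_nodes,
               as.integer(table(deg)[as.character(dd$degree)]))
  expect_error(degreeDistribution(new("FFLNetwork")), "empty")
})

test_that("scale-free fit recovers exact power laws and degenerate cases", {
  k <- 1:10
  fit <- scaleFreeFit(data.frame(degree = k, n_nodes = 1000 * k^-2))
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(fit$slope, -2, tolerance = 1e-10)

  flat <- scaleFreeFit(data.frame(degree = 1:5, n_nodes = 7))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(scaleFreeFit(data.frame(degree = 1:2, n_nodes = c(3, 1))),
               ">= 3 distinct degrees")

  # a preferential-attachment network approximates a power law
  set.seed(11)
  ba <- igraph::sample_pa(500, directed = FALSE)
  expect_gt(scaleFreeFit(degreeDistribution(ba))$r_squared, 0.6)
})

test_that("network export writes consistent node/edge/FFL tables", {
  net <- enumerateFFLs(readEdgeLists(
    system.file("extdata", "edges_demo.tsv", package = "lncFFLnet")))
  dir <- withr::local_tempdir()
  paths <- writeNetworkTables(net, dir)
  nodes <- read.delim(file.path(dir, "nodes.tsv"))
  expect_equal(nrow(nodes), nrow(fflNodes(net)))
  expect_equal(sum(nodes$n_ffls), 3L * nFFLs(net))
  expect_equal(nrow(read.delim(file.path(dir, "ffls.tsv"))), nFFLs(net))
})
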