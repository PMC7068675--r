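# toy bundle with explicit values for the three molecules of one loop
toyBundle <- function(geneVals, mirVals, lncVals, n1 = 4, n2 = 4) {
  n <- n1 + n2
  ids <- sprintf("S%02d", seq_len(n))
  mk <- function(v, nm) matrix(v, nrow = 1, dimnames = list(nm, ids))
  ExpressionBundle(mk(geneVals, "G1"), mk(mirVals, "M1"), mk(lncVals, "L1"),
                   rep(c("case", "control"), c(n1, n2)))
}

oneLoop <- data.frame(gene = "G1", miRNA = "M1", lncRNA = "L1")

test_that("differential p-values equal the Student t-test", {
  # case values equal to control values sample-for-sample -> t = 0, p = 1
  b <- toyBundle(rep(1:4, 2), rep(c(2, 4, 6, 8), 2), rep(c(1, 3, 2, 5), 2))
  p <- differentialPvalues(b, oneLoop)
  expect_equal(unname(p), c(1, 1, 1))

  # strong shift: matches stats::t.test with pooled variance exactly
  b2 <- toyBundle(c(10, 11, 12, 13, 1, 2, 3, 4),
                  c(5, 6, 4, 7, 5.5, 6.1, 4.2, 7.3),
                  c(0, 1, 0, 1, 2, 3, 2, 3))
  p2 <- differentialPvalues(b2, oneLoop)
  oracle <- function(x) t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value
  expect_equal(unname(p2["p_gene"]), oracle(c(10:13, 1:4)), tolerance = 1e-12)
  expect_equal(unname(p2["p_lncRNA"]), oracle(c(0, 1, 0, 1, 2, 3, 2, 3)),
               tolerance = 1e-12)

  # one group constant, the other varying: pooled-variance formula applies
  # (the flat case-group correlations are undefined -> warning expected)
  x <- c(5, 5, 5, 5, 1, 2, 3, 4)
  b3 <- toyBundle(x, x + 1, x - 1)
  expect_warning(p3 <- differentialPvalues(b3, oneLoop), "zero-variance")
  expect_equal(unname(p3["p_gene"]),
               t.test(x[1:4], x[5:8], var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("edge correlations are within-group Pearson correlations", {
  v <- c(1, 4, 2, 6)
  b <- toyBundle(c(v, 9, 3, 5, 2), c(v, 8, 1, 4, 4), c(-v, 2, 2.5, 1, 7))
  r <- edgeCorrelations(b, oneLoop)
  expect_equal(unname(r["r_case_lnc_mir"]), -1)   # lncRNA = -miRNA in cases
  expect_equal(unname(r["r_case_mir_gene"]), 1)   # identical vectors
  expect_equal(unname(r["r_ctrl_mir_gene"]),
               cor(c(8, 1, 4, 4), c(9, 3, 5, 2)), tolerance = 1e-12)
  set.seed(8)
  x <- rnorm(8); y <- rnorm(8); z <- rnorm(8)
  b2 <- toyBundle(x, y, z)
  r2 <- edgeCorrelations(b2, oneLoop)
  manual <- function(a, b_) {
    ca <- a - mean(a); cb <- b_ - mean(b_)
    sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  expect_equal(unname(r2["r_case_lnc_gene"]), manual(z[1:4], x[1:4]),
               tolerance = 1e-12)
  expect_equal(unname(r2["r_ctrl_lnc_mir"]), manual(z[5:8], y[5:8]),
               tolerance = 1e-12)
})

test_that("composite scores follow their defining products", {
  corrsEq <- c(r_case_lnc_mir = .5, r_ctrl_lnc_mir = .5,
               r_case_lnc_gene = -.2, r_ctrl_lnc_gene = -.2,
               r_case_mir_gene = .9, r_ctrl_mir_gene = .9)
  cs <- compositeScores(c(0.1, 0.2, 0.5), corrsEq)
  expect_equal(cs$cs_dif, 0.01, tolerance = 1e-15)
  expect_equal(cs$cs_pcc, 0)
  corrsMax <- c(r_case_lnc_mir = 1, r_ctrl_lnc_mir = -1,
                r_case_lnc_gene = 1, r_ctrl_lnc_gene = -1,
                r_case_mir_gene = 1, r_ctrl_mir_gene = -1)
  expect_equal(compositeScores(c(1, 1, 1), corrsMax)$cs_pcc, 8)
})

test_that("rank aggregation is equal-weighted with average ranks", {
  rk <- rankAndCombine(c(0.001, 0.5), c(4, 0.1))
  expect_equal(rk$final_score, c(1, 2))

  # ties conserve the rank sum: final scores sum to n(n+1)/2
  rk2 <- rankAndCombine(c(0.2, 0.2, 0.2), c(1, 2, 3))
  expect_equal(rk2$rank_dif, rep(2, 3))
  expect_equal(sum(rk2$final_score), 3 * 4 / 2)

  set.seed(31)
  a <- sample(round(runif(100), 2)); b <- sample(round(runif(100), 2))
  rk3 <- rankAndCombine(a, b)
  expect_equal(rk3$rank_dif, naiveAvgRank(a))
  expect_equal(rk3$rank_pcc, naiveAvgRank(-b))
  expect_equal(rk3$final_score, (naiveAvgRank(a) + naiveAvgRank(-b)) / 2)

  expect_error(rankAndCombine(0.5, 1), ">= 2 FFLs")
})

test_that("improving one component never worsens its rank", {
  set.seed(12)
  csDif <- runif(50); csPcc <- runif(50) * 4
  base <- rankAndCombine(csDif, csPcc)
  for (i in c(3, 17, 42)) {
    better <- csDif; better[i] <- better[i] / 10
    expect_lte(rankAndCombine(better, csPcc)$rank_dif[i], base$rank_dif[i])
    bigger <- csPcc; bigger[i] <- bigger[i] * 3
    expect_lte(rankAndCombine(csDif, bigger)$rank_pcc[i], base$rank_pcc[i])
  }
})

test_that("correlation transitions are classified on the tau grid", {
  expect_equal(classifyPatterns(0.8, -0.7, tau = 0.3), "positive->negative")
  expect_equal(classifyPatterns(0.1, 0.2, tau = 0.3), "none->none")
  # a lost negative coupling: negative in controls, none in cases
  expect_equal(classifyPatterns(-0.5, 0.0, tau = 0.3), "negative->none")
  expect_equal(classifyPatterns(c(-1, 1), c(1, -1), tau = 0.5),
               c("negative->positive", "positive->negative"))
})

test_that("swapping the two group labels wholesale leaves scores unchanged", {
  sim <- simulateScenario("planted", nFFLs = 20, nPlanted = 3, seed = 13)
  flipped <- ExpressionBundle(
    exprMatrix(sim$bundle, "gene"), exprMatrix(sim$bundle, "miRNA"),
    exprMatrix(sim$bundle, "lncRNA"),
    ifelse(sampleGroups(sim$bundle) == "case", "control", "case"))
  a <- scoreFFLs(sim$bundle, sim$network, B = 0)
  b <- scoreFFLs(flipped, sim$network, B = 0)
  expect_equal(a$cs_dif, b$cs_dif, tolerance = 1e-12)
  expect_equal(a$cs_pcc, b$cs_pcc, tolerance = 1e-12)
  expect_equal(a$final_score, b$final_score)
})

test_that("permutation p-values respect the add-one bound", {
  # constant matrices: every permutation reproduces the observed scores,
  # so perm_p must be exactly 1 for every loop
  n <- 8
  ids <- sprintf("S%02d", 1:n)
  mk <- function(k) matrix(rep(seq_len(k), n), nrow = k,
                           dimnames = list(sprintf("F%d", 1:k), ids))
  b <- ExpressionBundle(mk(2), mk(2), mk(2),
                        rep(c("case", "control"), each = 4))
  loops <- data.frame(gene = c("F1", "F2"), miRNA = c("F1", "F2"),
                      lncRNA = c("F1", "F2"))
  sc <- suppressWarnings(scoreFFLs(b, loops, B = 100, seed = 1))
  expect_equal(sc$perm_p, c(1, 1))
  expect_equal(sc$p_gene, c(1, 1))   # zero pooled variance -> p := 1

  sim <- simulateScenario("planted", nFFLs = 15, nPlanted = 2, seed = 21)
  sc2 <- scoreFFLs(sim$bundle, sim$network, B = 100, seed = 2)
  expect_true(all(sc2$perm_p >= 1 / 101))
  expect_true(all(sc2$perm_p <= 1))
  expect_error(scoreFFLs(sim$bundle, sim$network, B = 50), ">= 100")
})

test_that("loops with molecules absent from the matrices are excluded", {
  sim <- simulateScenario("null", nFFLs = 6, seed = 3)
  loops <- rbind(ffls(sim$network),
                 data.frame(gene = "GHOST", miRNA = "MIR001",
                            lncRNA = "LNC001"))
  expect_message(sc <- scoreFFLs(sim$bundle, loops, B = 0), "excluding 1")
  expect_equal(nrow(sc), 6L)
})
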