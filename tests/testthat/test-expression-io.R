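makeBundleFiles <- function(dir, permuteCols = FALSE) {
  sim <- simulateScenario("null", nFFLs = 5, seed = 7)
  writeBundle(sim$bundle, dir)
  if (permuteCols) {
    for (f in c("gene.tsv", "mirna.tsv", "lncrna.tsv")) {
      df <- read.delim(file.path(dir, f), check.names = FALSE)
      perm <- c(1, 1 + sample(ncol(df) - 1))
      write.table(df[, perm], file.path(dir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  sim$bundle
}

test_that("write -> read round-trips a bundle losslessly", {
  dir <- withr::local_tempdir()
  orig <- makeBundleFiles(dir)
  got <- readBundle(file.path(dir, "gene.tsv"), file.path(dir, "mirna.tsv"),
                    file.path(dir, "lncrna.tsv"), file.path(dir, "design.tsv"))
  expect_equal(exprMatrix(got, "gene"), exprMatrix(orig, "gene"),
               tolerance = 1e-8)
  expect_equal(exprMatrix(got, "lncRNA"), exprMatrix(orig, "lncRNA"),
               tolerance = 1e-8)
  expect_identical(sampleIds(got), sampleIds(orig))
  expect_identical(as.character(sampleGroups(got)),
                   as.character(sampleGroups(orig)))
})

test_that("column order of the matrix files is canonicalised by the design", {
  dir <- withr::local_tempdir()
  orig <- makeBundleFiles(dir)
  set.seed(42)
  dir2 <- withr::local_tempdir()
  writeBundle(orig, dir2)
  makeBundleFiles(dir2, permuteCols = TRUE)
  a <- readBundle(file.path(dir, "gene.tsv"), file.path(dir, "mirna.tsv"),
                  file.path(dir, "lncrna.tsv"), file.path(dir, "design.tsv"))
  b <- readBundle(file.path(dir2, "gene.tsv"), file.path(dir2, "mirna.tsv"),
                  file.path(dir2, "lncrna.tsv"), file.path(dir2, "design.tsv"))
  expect_equal(exprMatrix(a, "gene"), exprMatrix(b, "gene"),
               tolerance = 1e-8)
  expect_equal(exprMatrix(a, "miRNA"), exprMatrix(b, "miRNA"),
               tolerance = 1e-8)
})

test_that("sample mismatches, small groups and bad cells are rejected", {
  dir <- withr::local_tempdir()
  makeBundleFiles(dir)
  # drop one sample from the design
  des <- read.delim(file.path(dir, "design.tsv"))
  write.table(des[-1, ], file.path(dir, "design_short.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(
    readBundle(file.path(dir, "gene.tsv"), file.path(dir, "mirna.tsv"),
               file.path(dir, "lncrna.tsv"),
               file.path(dir, "design_short.tsv")),
    "case_01")
  # shrink one group below 3
  des2 <- des[c(1:2, 9:16), ]
  write.table(des2, file.path(dir, "design_small.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g2 <- read.delim(file.path(dir, "gene.tsv"), check.names = FALSE)
  keep <- c("feature_id", des2$sample_id)
  for (f in c("gene.tsv", "mirna.tsv", "lncrna.tsv")) {
    df <- read.delim(file.path(dir, f), check.names = FALSE)
    write.table(df[, keep], file.path(dir, paste0("s_", f)), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  expect_error(
    readBundle(file.path(dir, "s_gene.tsv"), file.path(dir, "s_mirna.tsv"),
               file.path(dir, "s_lncrna.tsv"),
               file.path(dir, "design_small.tsv")),
    ">= 3 samples")
  # poison one cell
  lines <- readLines(file.path(dir, "gene.tsv"))
  lines[2] <- sub("\t[-0-9.e+]+$", "\tnot_a_number", lines[2])
  writeLines(lines, file.path(dir, "bad_gene.tsv"))
  expect_error(
    readBundle(file.path(dir, "bad_gene.tsv"), file.path(dir, "mirna.tsv"),
               file.path(dir, "lncrna.tsv"), file.path(dir, "design.tsv")),
    "non-numeric value 'not_a_number'")
})

test_that("group aliases map study labels onto case/control", {
  dir <- withr::local_tempdir()
  makeBundleFiles(dir)
  des <- read.delim(file.path(dir, "design.tsv"))
  des$group <- ifelse(des$group == "case", "GDM", "NGT")
  write.table(des, file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  b <- readBundle(file.path(dir, "gene.tsv"), file.path(dir, "mirna.tsv"),
                  file.path(dir, "lncrna.tsv"), file.path(dir, "design.tsv"))
  expect_equal(as.vector(table(sampleGroups(b))), c(8L, 8L))
})

test_that("zero-variance features are flagged and NA policy is enforced", {
  sim <- simulateScenario("null", nFFLs = 4, seed = 5)
  m <- exprMatrix(sim$bundle, "gene")
  m["G001", ] <- 5
  flat <- ExpressionBundle(m, exprMatrix(sim$bundle, "miRNA"),
                           exprMatrix(sim$bundle, "lncRNA"),
                           sampleGroups(sim$bundle))
  expect_identical(zeroVarianceFeatures(flat), "gene:G001")

  dir <- withr::local_tempdir()
  writeBundle(flat, dir)
  lines <- readLines(file.path(dir, "gene.tsv"))
  lines[3] <- sub("\t[-0-9.e+]+$", "\tNA", lines[3])
  writeLines(lines, file.path(dir, "gene.tsv"))
  args <- list(file.path(dir, "gene.tsv"), file.path(dir, "mirna.tsv"),
               file.path(dir, "lncrna.tsv"), file.path(dir, "design.tsv"))
  expect_error(do.call(readBundle, args), "missing values")
  b <- suppressMessages(do.call(readBundle, c(args, naPolicy = "drop-feature")))
  expect_equal(nrow(exprMatrix(b, "gene")), nrow(m) - 1L)
})
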