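#' Read gene sets from GMT or one-column list files
#'
#' GMT: one set per line, tab-separated `name`, `description`, then member
#' identifiers.  List: a plain single-column file (optionally headered with
#' `gene`), read as one set named after the file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gmt"` or `"list"`.
#' @return named list of character vectors of gene identifiers.
#' @export
readGeneSets <- function(path, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "list"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(lines, function(ln) {
      parts <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
      if (length(parts) < 3L)
        .stopf("GMT line with fewer than 3 fields: '%s'",
               substr(ln, 1, 50))
      unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    })
    names(sets) <- vapply(lines, function(ln)
      trimws(strsplit(ln, "\t", fixed = TRUE)[[1]][1]), character(1))
    sets
  } else {
    members <- trimws(readLines(path, warn = FALSE))
    members <- members[nzchar(members)]
    if (length(members) && tolower(members[1]) == "gene")
      members <- members[-1]
    stats::setNames(list(unique(members)),
                    sub("\\.[^.]*$", "", basename(path)))
  }
}

#' Restrict an FFL network to loops whose gene belongs to a gene set
#'
#' Membership is decided on the gene vertex only -- the glycometabolism and
#' hormone annotation lists this supports are protein-coding gene lists, so
#' miRNA and lncRNA identifiers are never tested against them.  Matching is
#' case-insensitive after trimming, as everywhere else.
#'
#' @param network an [FFLNetwork-class].
#' @param geneSet character vector of gene identifiers.
#' @return an [FFLNetwork-class]; empty (with a warning) when no loop gene
#'   is in the set.
#' @export
extractSubnetwork <- function(network, geneSet) {
  stopifnot(is(network, "FFLNetwork"))
  keep <- .normId(ffls(network)$gene) %in% .normId(geneSet)
  if (!any(keep)) {
    .warnf("gene set shares no genes with the network; empty subnetwork")
    return(new("FFLNetwork"))
  }
  sub <- ffls(network)[keep, , drop = FALSE]
  # rebuild from the supporting edges so nodes/edges stay consistent
  ek <- paste(.normId(network@edges$source), .normId(network@edges$target),
              network@edges$layer, sep = "\r")
  nk <- c(paste(.normId(sub$gene), .normId(sub$miRNA), "gene-miRNA", sep = "\r"),
          paste(.normId(sub$gene), .normId(sub$lncRNA), "gene-lncRNA", sep = "\r"),
          paste(.normId(sub$miRNA), .normId(sub$lncRNA), "miRNA-lncRNA",
                sep = "\r"))
  enumerateFFLs(network@edges[ek %in% nk, , drop = FALSE])
}

#' Set relations between two FFL lists
#'
#' Partitions two loop lists (compared by the full gene/miRNA/lncRNA
#' triplet, case-insensitively) into the shared loops and the loops unique
#' to each list -- the Venn partition of two dysregulated-FFL sets.
#'
#' @param setA,setB data.frames with columns `gene`, `miRNA`, `lncRNA`.
#' @return list with data.frames `common`, `only_a`, `only_b`;
#'   `nrow(common) + nrow(only_a) + nrow(only_b)` equals the union size.
#' @export
fflSetRelations <- function(setA, setB) {
  ka <- .fflKey(setA$gene, setA$miRNA, setA$lncRNA)
  kb <- .fflKey(setB$gene, setB$miRNA, setB$lncRNA)
  setA <- setA[!duplicated(ka), , drop = FALSE]; ka <- unique(ka)
  setB <- setB[!duplicated(kb), , drop = FALSE]; kb <- unique(kb)
  list(common = setA[ka %in% kb, c("gene", "miRNA", "lncRNA"), drop = FALSE],
       only_a = setA[!ka %in% kb, c("gene", "miRNA", "lncRNA"), drop = FALSE],
       only_b = setB[!kb %in% ka, c("gene", "miRNA", "lncRNA"), drop = FALSE])
}
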