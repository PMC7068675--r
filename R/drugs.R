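#' Read drug-target association tables
#'
#' TSV with header `drug`, `target`, `target_type` and optionally
#' `category`.  `target_type` must be `gene` or `miRNA` -- lncRNAs are not
#' drug-joined.  Duplicate rows collapse.
#'
#' @param path file path.
#' @return data.frame `drug`, `target`, `target_type`, `category`.
#' @export
readDrugAssociations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", comment.char = "",
                          stringsAsFactors = FALSE)
  if (!all(c("drug", "target", "target_type") %in% names(df)))
    .stopf("association file needs columns drug, target, target_type")
  if (!"category" %in% names(df)) df$category <- ""
  df$drug <- trimws(df$drug); df$target <- trimws(df$target)
  df$target_type <- trimws(df$target_type)
  bad <- setdiff(unique(df$target_type), c("gene", "miRNA"))
  if (length(bad))
    .stopf("unknown target_type value(s): %s (only gene/miRNA are drug targets)",
           paste(bad, collapse = ", "))
  df <- df[!duplicated(paste(.normId(df$drug), .normId(df$target),
                             df$target_type, trimws(df$category),
                             sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Overlay drug associations on dysregulated FFLs
#'
#' A drug enters the network iff it targets at least one gene or miRNA that
#' appears in a dysregulated loop.  The result is a bipartite drug-molecule
#' edge set plus a per-hit table listing the loops each targeted molecule
#' belongs to.
#'
#' @param dysregulated data.frame of dysregulated loops (`gene`, `miRNA`,
#'   `lncRNA`).
#' @param assoc data.frame from [readDrugAssociations()].
#' @return list with `edges` (drug, target, target_type), `hits`
#'   (drug, target, target_type, gene, miRNA, lncRNA), `drugs` (drug,
#'   categories, n_targets) and counts `n_drugs`, `n_targets`.
#' @export
buildDrugNetwork <- function(dysregulated, assoc) {
  dys <- as.data.frame(dysregulated, stringsAsFactors = FALSE)
  mols <- rbind(
    data.frame(key = .normId(dys$gene), type = "gene",
               gene = dys$gene, miRNA = dys$miRNA, lncRNA = dys$lncRNA,
               stringsAsFactors = FALSE),
    data.frame(key = .normId(dys$miRNA), type = "miRNA",
               gene = dys$gene, miRNA = dys$miRNA, lncRNA = dys$lncRNA,
               stringsAsFactors = FALSE))
  hit <- merge(
    data.frame(drug = assoc$drug, target = assoc$target,
               target_type = assoc$target_type, category = assoc$category,
               key = .normId(assoc$target), type = assoc$target_type,
               stringsAsFactors = FALSE),
    mols, by = c("key", "type"))
  if (nrow(hit) == 0L) {
    .warnf("no drug targets any molecule of a dysregulated FFL")
    return(list(edges = data.frame(drug = character(), target = character(),
                                   target_type = character()),
                hits = data.frame(), drugs = data.frame(),
                n_drugs = 0L, n_targets = 0L))
  }
  hits <- hit[order(.normId(hit$drug), .normId(hit$target), .normId(hit$gene),
                    .normId(hit$miRNA), .normId(hit$lncRNA)),
              c("drug", "target", "target_type", "gene", "miRNA", "lncRNA"),
              drop = FALSE]
  rownames(hits) <- NULL
  edges <- unique(hits[, c("drug", "target", "target_type"), drop = FALSE])
  rownames(edges) <- NULL
  cat <- stats::aggregate(
    category ~ drugKey, FUN = function(v)
      paste(sort(unique(v[nzchar(v)])), collapse = ";"),
    data = data.frame(drugKey = .normId(hit$drug), category = hit$category,
                      stringsAsFactors = FALSE))
  drugs <- data.frame(drug = edges$drug[!duplicated(.normId(edges$drug))],
                      stringsAsFactors = FALSE)
  drugs$categories <- cat$category[match(.normId(drugs$drug), cat$drugKey)]
  drugs$n_targets <- as.integer(table(.normId(edges$drug))[.normId(drugs$drug)])
  drugs <- drugs[order(.normId(drugs$drug)), , drop = FALSE]
  rownames(drugs) <- NULL
  list(edges = edges, hits = hits, drugs = drugs,
       n_drugs = nrow(drugs), n_targets = length(unique(.normId(edges$target))))
}

#' Fraction of network drugs carrying a category of interest
#'
#' The share of drugs in a drug-FFL network with at least one category
#' label among `categories` -- e.g. the anti-inflammatory plus hormonal
#' fraction of a repurposing candidate network.  Duplicate association
#' rows do not change the value (drugs are counted once).
#'
#' @param drugNetwork list from [buildDrugNetwork()].
#' @param categories character vector of category labels of interest.
#' @return fraction in `[0, 1]`.
#' @export
categoryFraction <- function(drugNetwork, categories) {
  if (is.null(drugNetwork$drugs) || nrow(drugNetwork$drugs) == 0L)
    .stopf("categoryFraction: empty drug network (fraction undefined)")
  catList <- strsplit(drugNetwork$drugs$categories, ";", fixed = TRUE)
  hit <- vapply(catList, function(v)
    any(.normId(v) %in% .normId(categories)), logical(1))
  sum(hit) / nrow(drugNetwork$drugs)
}
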