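# internal helpers shared across modules

.LAYERS <- c("gene-miRNA", "gene-lncRNA", "miRNA-lncRNA")

# layer -> (source type, target type)
.LAYER_TYPES <- list(
  "gene-miRNA"   = c("gene", "miRNA"),
  "gene-lncRNA"  = c("gene", "lncRNA"),
  "miRNA-lncRNA" = c("miRNA", "lncRNA")
)

# Identifier normalisation: matching is case-insensitive after trimming,
# original casing is preserved wherever identifiers are reported.
.normId <- function(x) toupper(trimws(as.character(x)))

.fflKey <- function(gene, miRNA, lncRNA) {
  paste(.normId(gene), .normId(miRNA), .normId(lncRNA), sep = "\r")
}

.emptyEdgeFrame <- function() {
  data.frame(source = character(), target = character(),
             layer = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

.emptyFFLFrame <- function() {
  data.frame(gene = character(), miRNA = character(), lncRNA = character(),
             stringsAsFactors = FALSE)
}

.emptyNodeFrame <- function() {
  data.frame(id = character(), type = character(), stringsAsFactors = FALSE)
}

# deterministic numeric formatting used by all table writers so that reruns
# with the same seed are byte-identical
.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
.msgf <- function(...) message(sprintf(...))
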