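# Result writers: a one-row-per-subnetwork TSV, one SIF file per significant
# subnetwork (Cytoscape simple-interaction format), and a GMT gene-set file of
# the significant subnetworks so they can be fed to gene-set enrichment tools.

.sanitizeFilename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write a result to a directory
#'
#' Emits \code{results.tsv} (name, phenotype, pathway, size, t_stat, p_value,
#' significant, semicolon-joined gene list; one row per scored subnetwork),
#' one \code{<name>.sif} per significant subnetwork with lines
#' \code{gene_a<TAB>relation<TAB>gene_b}, and \code{subnetworks.gmt} holding
#' every significant subnetwork as a gene set (set name, description = source
#' pathway, then the genes) for downstream enrichment tools.
#'
#' @param result an \linkS4class{SNetResult}.
#' @param outDir output directory (created if absent).
#' @return Invisibly, the path of \code{results.tsv}.
#' @export
writeResults <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tab <- resultTable(result)
  resPath <- file.path(outDir, "results.tsv")
  write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
              resPath, sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- significantSubnetworks(result)
  gmt <- vapply(sig, function(s)
    paste(c(snName(s), snPathway(s), snGenes(s)), collapse = "\t"),
    character(1))
  writeLines(gmt, file.path(outDir, "subnetworks.gmt"))

  for (s in sig) {
    e <- snEdges(s)
    writeLines(paste(e$gene_a, e$relation, e$gene_b, sep = "\t"),
               file.path(outDir,
                         paste0(.sanitizeFilename(snName(s)), ".sif")))
  }
  invisible(resPath)
}

#' Read a results table back
#'
#' Parses a \code{results.tsv} written by \code{\link{writeResults}}. Gene
#' sets and pathway names are recovered exactly; the induced edge lists are
#' not stored in the table, so the subnetworks are returned as plain records
#' suitable for the overlap metrics (\code{\link{subnetworkOverlap}},
#' \code{\link{geneOverlap}}).
#'
#' @param path path to a \code{results.tsv}.
#' @param significantOnly keep only rows flagged significant (default TRUE).
#' @return List with \code{table} (the parsed data.frame) and
#'   \code{subnetworks} (list of \code{list(name, phenotype, pathway, genes)}).
#' @export
readResults <- function(path, significantOnly = TRUE) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "", comment.char = "")
  need <- c("name", "phenotype", "pathway", "size", "t_stat", "p_value",
            "significant", "genes")
  if (!all(need %in% colnames(tab)))
    stop("malformed results table: expected columns ",
         paste(need, collapse = ", "))
  tab$size <- as.integer(tab$size)
  tab$t_stat <- as.numeric(tab$t_stat)
  tab$p_value <- as.numeric(tab$p_value)
  tab$significant <- tab$significant %in% c("TRUE", "true", "1")
  sel <- if (significantOnly) which(tab$significant) else seq_len(nrow(tab))
  subnetworks <- lapply(sel, function(i)
    list(name = tab$name[i], phenotype = tab$phenotype[i],
         pathway = tab$pathway[i],
         genes = strsplit(tab$genes[i], ";", fixed = TRUE)[[1L]]))
  list(table = tab, subnetworks = subnetworks)
}
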