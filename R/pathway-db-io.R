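# Pathway database readers/writers. Two dialects:
#   JSON: [{"name": "...", "edges": [["geneA", "geneB", "activate"], ...]}, ...]
#   TSV:  header pathway, gene_a, gene_b, relation
# Relations are case-insensitive on input and canonical lowercase in memory
# and on output; anything outside {activate, inhibit} is rejected.

#' Read a pathway database
#'
#' @param path file path.
#' @param format \code{"json"}, \code{"tsv"}, or \code{"auto"} (by file
#'   extension, default).
#' @return A \linkS4class{PathwayDB}; duplicate edges (same unordered pair and
#'   relation) collapsed.
#' @export
readPathwayDB <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(doc) == 0L) stop("empty pathway set")
    pathways <- list()
    for (p in doc) {
      if (is.null(p$name) || is.null(p$edges))
        stop("each pathway object needs 'name' and 'edges'")
      edges <- do.call(rbind, lapply(p$edges, function(e) {
        if (length(e) != 3L)
          stop(sprintf("pathway '%s': edge needs [gene_a, gene_b, relation]",
                       p$name))
        data.frame(gene_a = as.character(e[[1L]]),
                   gene_b = as.character(e[[2L]]),
                   relation = as.character(e[[3L]]),
                   stringsAsFactors = FALSE)
      }))
      pathways[[as.character(p$name)]] <- edges
    }
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      colClasses = "character", quote = "",
                      comment.char = "")
    need <- c("pathway", "gene_a", "gene_b", "relation")
    if (!all(need %in% colnames(tab)))
      stop("malformed header: expected columns ",
           paste(need, collapse = ", "))
    if (nrow(tab) == 0L) stop("empty pathway set")
    pathways <- split(tab[, c("gene_a", "gene_b", "relation")],
                      factor(tab$pathway, levels = unique(tab$pathway)))
  }
  PathwayDB(pathways)
}

#' Write a pathway database
#'
#' @param db a \linkS4class{PathwayDB}.
#' @param path output file path.
#' @param format \code{"json"}, \code{"tsv"}, or \code{"auto"} (by extension).
#' @return Invisibly, \code{path}.
#' @export
writePathwayDB <- function(db, path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    doc <- lapply(pathwayNames(db), function(pw) {
      e <- pathwayEdges(db, pw)
      list(name = pw,
           edges = lapply(seq_len(nrow(e)), function(i)
             list(e$gene_a[i], e$gene_b[i], e$relation[i])))
    })
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
  } else {
    tab <- do.call(rbind, lapply(pathwayNames(db), function(pw) {
      e <- pathwayEdges(db, pw)
      data.frame(pathway = pw, e, stringsAsFactors = FALSE)
    }))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
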