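# Shared helpers: a brute-force reachability oracle for connected components,
# small random-graph and study builders.

# Connected components by iterated neighbourhood expansion -- independent of
# the package's union-find. Returns a canonical form: each component sorted,
# components ordered by their first vertex.
bruteComponents <- function(a, b) {
  verts <- unique(c(a, b))
  reach <- function(v) {
    comp <- v
    repeat {
      nb <- unique(c(b[a %in% comp], a[b %in% comp]))
      fresh <- setdiff(nb, comp)
      if (length(fresh) == 0L) break
      comp <- c(comp, fresh)
    }
    sort(comp)
  }
  comps <- unique(lapply(verts, reach))
  comps[order(vapply(comps, `[`, comps[[1]][1], 1))]
}

canonComponents <- function(comps) {
  if (length(comps) == 0L) return(list())
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, comps[[1]][1], 1))]
}

# random undirected edge list on nVerts vertices (possibly disconnected,
# no self-loops, no duplicate pairs)
randomEdgeList <- function(nVerts, edgeProb) {
  verts <- sprintf("v%02d", seq_len(nVerts))
  pairs <- t(combn(verts, 2))
  sel <- runif(nrow(pairs)) < edgeProb
  data.frame(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2],
             relation = sample(c("activate", "inhibit"), sum(sel),
                               replace = TRUE),
             stringsAsFactors = FALSE)
}

# small study with explicit values
makeStudy <- function(values, phenos) {
  ExpressionStudy(values, setNames(phenos, colnames(values)))
}
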