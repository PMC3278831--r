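# Connected components of an undirected edge list via union-find with path
# compression. This sits inside the permutation loop, where thousands of tiny
# per-pathway graphs are decomposed per run, so it avoids any per-graph
# construction overhead. Vertices with no edge never appear in the input and
# therefore never form components (solitary genes are dropped by design).

# a, b: parallel vectors of edge endpoints (any atomic type).
# Returns an unnamed list of vertex vectors, one per component, in order of
# first appearance; vertices within a component in order of first appearance.
.ufComponents <- function(a, b) {
  if (length(a) == 0L) return(list())
  verts <- unique(c(a, b))
  n <- length(verts)
  parent <- seq_len(n)
  ia <- match(a, verts)
  ib <- match(b, verts)
  find <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) {
      nxt <- parent[i]
      parent[i] <<- r
      i <- nxt
    }
    r
  }
  for (e in seq_along(ia)) {
    ra <- find(ia[e])
    rb <- find(ib[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(verts, factor(roots, levels = unique(roots))))
}

# Locale-independent ascending sort of character vectors (C collation), so
# lexicographic tie-breaks are identical across platforms.
.csort <- function(x) sort(x, method = "radix")
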