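# Small builders shared across tests. All fixtures are generated in code.

# hypernetwork from a list of node vectors (seed = first node)
toyHypernetwork <- function(edgeSets, nNodes = max(unlist(edgeSets)),
                            id = "toy") {
  edges <- lapply(edgeSets, function(ns)
    list(nodes = sort(as.integer(ns)), seed = as.integer(ns[1L]),
         lambda1 = 0.1))
  new("Hypernetwork", nNodes = as.integer(nNodes),
      nodeLabels = as.character(seq_len(nNodes)),
      hyperedges = edges, subjectId = id)
}

# random hypergraph: up to maxEdges hyperedges of size 2..maxSize
randomHypernetwork <- function(nNodes, maxEdges, maxSize = min(4L, nNodes)) {
  nE <- sample.int(maxEdges, 1L)
  sets <- unique(lapply(seq_len(nE), function(e) {
    sz <- sample(2:maxSize, 1L)
    sort(sample.int(nNodes, sz))
  }))
  toyHypernetwork(sets, nNodes)
}

# deterministic subject time series with given dims
toySeries <- function(T, N, seed = 1, id = "s1", group = "negative") {
  set.seed(seed)
  SubjectTimeSeries(id, group, matrix(rnorm(T * N), T, N))
}
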