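## Brute-force oracles, independent of the package implementations.

## All-pairs shortest paths by Floyd-Warshall over the adjacency matrix.
oracle_distances <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  if (nrow(graph$edges))
    d[cbind(match(graph$edges$from, ids),
            match(graph$edges$to, ids))] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

## Betweenness by explicit enumeration of all shortest paths (DFS over
## the shortest-path DAG).  Exponential in the worst case; fine for the
## small random graphs used in tests.
oracle_betweenness <- function(graph, normalized = TRUE) {
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(graph$edges)) {
    f <- match(graph$edges$from, ids)
    t <- match(graph$edges$to, ids)
    for (k in seq_along(f)) adj[[f[k]]] <- c(adj[[f[k]]], t[k])
  }
  d <- oracle_distances(graph)
  betw <- stats::setNames(rep(0, n), ids)
  all_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (w in adj[[s]])
      if (is.finite(d[w, t]) && d[s, t] == d[w, t] + 1)
        for (p in all_paths(w, t))
          out[[length(out) + 1L]] <- c(s, p)
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    paths <- all_paths(s, t)
    npath <- length(paths)
    for (p in paths) {
      interior <- p[-c(1L, length(p))]
      for (v in interior) betw[v] <- betw[v] + 1 / npath
    }
  }
  if (normalized && n > 2L) betw <- betw / ((n - 1) * (n - 2))
  betw
}

## A tiny deterministic two-compartment test model: a -> b -> c with one
## catalysed and one inhibited step.
tiny_model <- function() {
  fruit_model(
    "tiny",
    compartments = list(compartment("env", kind = "environment"),
                        compartment("cell", kind = "fungal_cell")),
    species = list(
      species("a", "simple_molecule", "cell", initial_amount = 1),
      species("b", "simple_molecule", "cell", initial_amount = 0),
      species("c", "phenotype", "cell", initial_amount = 0),
      species("e", "protein", "cell"),
      species("i", "protein", "cell")),
    reactions = list(
      reaction("re1", "a", "b"),
      reaction("re2", "b", "c",
               modifiers = c(e = "catalyst", i = "inhibitor"))))
}

## local reaction getter (keeps tests to the exported surface)
find_rxn <- function(model, id) {
  for (r in model$reactions) if (r$id == id) return(r)
  stop("no reaction ", id)
}
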