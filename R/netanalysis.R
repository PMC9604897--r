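## Directed bipartite species-reaction graphs and from-scratch topology
## metrics.  All shortest-path quantities use directed breadth-first
## search with unit edge weights; component, clustering, degree and
## neighborhood-connectivity statistics use the underlying undirected
## simple graph, matching the conventions of the NetworkAnalyzer tool the
## published summary table was produced with.

#' Create a directed graph object
#'
#' @param nodes `data.frame` with columns `id`, `kind` (`"species"` or
#'   `"reaction"` for bipartite reaction graphs; arbitrary labels are
#'   allowed for generic graphs) and `label`.
#' @param edges `data.frame` with columns `from`, `to`, `kind`.
#' @return A list of class `fn_graph`.
#' @export
directed_graph <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), all(c("id", "kind") %in% names(nodes)),
            is.data.frame(edges) || is.null(edges))
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), stringsAsFactors = FALSE)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  if (!"kind" %in% names(edges)) edges$kind <- rep("edge", nrow(edges))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (nrow(edges)) {
    if (!all(edges$from %in% nodes$id) || !all(edges$to %in% nodes$id))
      stop("edge endpoint references unknown node")
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges$from, edges$to)))
      stop("duplicate directed edges are not allowed")
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "fn_graph")
}

#' @export
print.fn_graph <- function(x, ...) {
  cat(sprintf("<fn_graph>: %d nodes, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a model to its directed species-reaction graph
#'
#' Builds the bipartite graph with one node per reaction and one node per
#' species that participates in at least one reaction (isolated species
#' are dropped, as network exports of process diagrams conventionally
#' omit unconnected elements).  Edges run reactant -> reaction,
#' reaction -> product and modifier -> reaction.  Node order follows
#' model order (species first, then reactions), so the conversion is
#' deterministic.
#'
#' @param model A valid [fruit_model()].
#' @return An [directed_graph()] of class `fn_graph`.
#' @export
to_reaction_graph <- function(model) {
  stop_if_invalid(model)
  part <- participation_table(model)
  sids <- vapply(model$species, `[[`, "", "id")
  snames <- vapply(model$species, `[[`, "", "name")
  keep <- sids %in% part$species
  rids <- vapply(model$reactions, `[[`, "", "id")
  rnames <- vapply(model$reactions, `[[`, "", "name")
  nodes <- data.frame(
    id = c(sids[keep], rids),
    kind = c(rep("species", sum(keep)), rep("reaction", length(rids))),
    label = c(snames[keep], rnames),
    stringsAsFactors = FALSE)
  if (nrow(part)) {
    from <- ifelse(part$part == "product", part$reaction, part$species)
    to <- ifelse(part$part == "product", part$species, part$reaction)
    edges <- data.frame(from = from, to = to, kind = part$part,
                        stringsAsFactors = FALSE)
    edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  } else {
    edges <- NULL
  }
  directed_graph(nodes, edges)
}

## ---- internal adjacency helpers -------------------------------------

graph_index <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  out <- vector("list", n); inn <- vector("list", n)
  for (i in seq_len(n)) { out[[i]] <- integer(); inn[[i]] <- integer() }
  if (nrow(graph$edges)) {
    f <- idx[graph$edges$from]; t <- idx[graph$edges$to]
    out <- split(unname(t), factor(f, levels = seq_len(n)))
    inn <- split(unname(f), factor(t, levels = seq_len(n)))
  }
  und <- lapply(seq_len(n), function(i) sort(unique(c(out[[i]], inn[[i]]))))
  list(ids = ids, n = n, out = out, inn = inn, und = und)
}

## BFS distances from source i over adjacency list adj; returns integer
## vector with NA for unreachable nodes (distance to self is 0).
bfs_dist <- function(adj, n, i) {
  dist <- rep(NA_integer_, n)
  dist[i] <- 0L
  queue <- integer(n); queue[1L] <- i; head <- 1L; tail <- 1L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (w in adj[[u]]) if (is.na(dist[w])) {
      dist[w] <- dist[u] + 1L
      tail <- tail + 1L; queue[tail] <- w
    }
  }
  dist
}

undirected_edge_count <- function(gi) {
  sum(lengths(gi$und)) / 2
}

#' Topology report
#'
#' Computes the summary topology statistics of a directed graph: node and
#' edge counts, weakly connected components, mean clustering coefficient,
#' directed diameter and radius, the count of ordered reachable node
#' pairs ("shortest paths"), characteristic path length, average number
#' of neighbors, density, degree heterogeneity, degree centralization and
#' self-loop count.
#'
#' Conventions: shortest-path quantities (diameter, radius,
#' characteristic path length, path count) are over directed paths;
#' radius is the minimum eccentricity over nodes that reach at least one
#' other node; components, clustering, neighbor counts, heterogeneity and
#' centralization use the underlying undirected simple graph; density
#' uses the directed formula `edges / (n * (n - 1))`.
#'
#' @param graph An [directed_graph()].
#' @return A list of class `fn_topology`.  Path metrics are `NA` when no
#'   node pair is connected.
#' @export
topology_report <- function(graph) {
  stopifnot(inherits(graph, "fn_graph"))
  gi <- graph_index(graph)
  n <- gi$n
  n_edges <- nrow(graph$edges)

  if (n == 0L) {
    return(structure(list(
      nodes = 0L, edges = 0L, connected_components = 0L,
      clustering_coefficient = NA_real_, diameter = NA_integer_,
      radius = NA_integer_, shortest_paths = 0L,
      characteristic_path_length = NA_real_,
      average_neighbors = NA_real_, density = NA_real_,
      heterogeneity = NA_real_, centralization = NA_real_,
      self_loops = 0L), class = "fn_topology"))
  }

  ## weak components over undirected adjacency
  comp <- rep(NA_integer_, n); ncomp <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    ncomp <- ncomp + 1L
    queue <- i; comp[i] <- ncomp
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- gi$und[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }

  ## local clustering over undirected graph; nodes with degree < 2
  ## contribute 0
  cc <- vapply(seq_len(n), function(i) {
    nb <- gi$und[[i]]
    k <- length(nb)
    if (k < 2L) return(0)
    links <- 0L
    for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k))
      if (nb[b] %in% gi$und[[nb[a]]]) links <- links + 1L
    2 * links / (k * (k - 1))
  }, 0)

  ## all-pairs directed BFS
  ecc <- rep(NA_integer_, n)
  pair_count <- 0
  dist_sum <- 0
  for (i in seq_len(n)) {
    d <- bfs_dist(gi$out, n, i)
    d[i] <- NA_integer_
    fin <- d[!is.na(d)]
    if (length(fin)) {
      ecc[i] <- max(fin)
      pair_count <- pair_count + length(fin)
      dist_sum <- dist_sum + sum(fin)
    }
  }
  any_path <- pair_count > 0

  deg <- lengths(gi$und)
  dens <- if (n > 1L) n_edges / (n * (n - 1)) else NA_real_
  mean_deg <- mean(deg)
  het <- if (mean_deg > 0)
    sqrt(mean(deg^2) - mean_deg^2) / mean_deg else NA_real_
  centr <- if (n > 2L)
    sum(max(deg) - deg) / ((n - 1) * (n - 2)) else NA_real_

  structure(list(
    nodes = n,
    edges = n_edges,
    connected_components = ncomp,
    clustering_coefficient = mean(cc),
    diameter = if (any_path) max(ecc, na.rm = TRUE) else NA_integer_,
    radius = if (any_path) min(ecc, na.rm = TRUE) else NA_integer_,
    shortest_paths = as.integer(pair_count),
    characteristic_path_length =
      if (any_path) dist_sum / pair_count else NA_real_,
    average_neighbors = 2 * undirected_edge_count(gi) / n,
    density = dens,
    heterogeneity = het,
    centralization = centr,
    self_loops = 0L
  ), class = "fn_topology")
}

#' @export
print.fn_topology <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA"
    else if (is.integer(v) || v == round(v)) format(v)
    else sprintf("%.2f", v)
  cat("Topology report\n")
  for (f in names(x)) cat(sprintf("  %-28s %s\n", f, fmt(x[[f]])))
  invisible(x)
}

#' Per-node metrics
#'
#' In- and out-degree, normalized directed betweenness centrality
#' (Brandes' algorithm over unit-weight directed shortest paths, divided
#' by `(n - 1) * (n - 2)`), neighborhood connectivity (mean undirected
#' degree of the node's undirected neighbors) and directed eccentricity
#' (maximum finite directed distance; `NA` when the node reaches no other
#' node).
#'
#' @param graph An [directed_graph()].
#' @return A `data.frame` with one row per node, in node order.
#' @export
node_metrics <- function(graph) {
  stopifnot(inherits(graph, "fn_graph"))
  gi <- graph_index(graph)
  n <- gi$n
  indeg <- lengths(gi$inn)
  outdeg <- lengths(gi$out)
  deg <- lengths(gi$und)

  betw <- rep(0, n)
  ecc <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    ## Brandes single-source shortest-path accumulation
    sigma <- rep(0, n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_stack <- integer(0)
    queue <- integer(n); queue[1L] <- s; head <- 1L; tail <- 1L
    while (head <= tail) {
      u <- queue[head]; head <- head + 1L
      order_stack[length(order_stack) + 1L] <- u
      for (w in gi$out[[u]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[u] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dist[u] + 1L) {
          sigma[w] <- sigma[w] + sigma[u]
          preds[[w]] <- c(preds[[w]], u)
        }
      }
    }
    fin <- dist[dist > 0L]
    if (length(fin)) ecc[s] <- max(fin)
    delta <- rep(0, n)
    for (w in rev(order_stack)) {
      for (u in preds[[w]])
        delta[u] <- delta[u] + sigma[u] / sigma[w] * (1 + delta[w])
      if (w != s) betw[w] <- betw[w] + delta[w]
    }
  }
  if (n > 2L) betw <- betw / ((n - 1) * (n - 2))

  nc <- vapply(seq_len(n), function(i) {
    nb <- gi$und[[i]]
    if (!length(nb)) return(NA_real_)
    mean(deg[nb])
  }, 0)

  data.frame(id = gi$ids, kind = graph$nodes$kind,
             in_degree = as.integer(indeg),
             out_degree = as.integer(outdeg),
             degree = as.integer(deg),
             betweenness = betw,
             neighborhood_connectivity = nc,
             eccentricity = ecc,
             stringsAsFactors = FALSE)
}

#' Neighborhood connectivity distribution
#'
#' For every observed undirected degree `k`, the mean neighborhood
#' connectivity of the nodes of degree `k`.  In the fruiting network this
#' distribution decreases in `k`: edges preferentially join low-degree
#' nodes to high-degree hubs.
#'
#' @param graph An [directed_graph()].
#' @return A `data.frame` with columns `k` (degree, increasing) and
#'   `mean_neighbor_connectivity`.  Isolated nodes (degree 0) are
#'   excluded.
#' @export
neighborhood_connectivity_distribution <- function(graph) {
  nm <- node_metrics(graph)
  nm <- nm[nm$degree > 0L, , drop = FALSE]
  if (!nrow(nm))
    return(data.frame(k = integer(),
                      mean_neighbor_connectivity = numeric()))
  agg <- tapply(nm$neighborhood_connectivity, nm$degree, mean)
  data.frame(k = as.integer(names(agg)),
             mean_neighbor_connectivity = unname(as.numeric(agg)))
}

#' Hub ranking
#'
#' Top-`k` nodes by a degree or betweenness metric, ties broken
#' lexicographically by node id so the ranking is deterministic.
#'
#' @param graph An [directed_graph()].
#' @param metric `"in_degree"` or `"betweenness"`.
#' @param k Number of nodes to return (`k` larger than the node count
#'   returns all nodes).
#' @param kind Optional node kind filter (e.g. `"reaction"` to rank only
#'   reaction nodes).
#' @return Character vector of node ids, best first.
#' @export
hub_ranking <- function(graph, metric = c("in_degree", "betweenness"),
                        k = 5L, kind = NULL) {
  metric <- match.arg(metric)
  stopifnot(k >= 1L)
  nm <- node_metrics(graph)
  if (!is.null(kind)) nm <- nm[nm$kind %in% kind, , drop = FALSE]
  nm <- nm[order(-nm[[metric]], nm$id), , drop = FALSE]
  utils::head(nm$id, k)
}
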