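#' Read an undirected interaction network from an edge-list file
#'
#' Each non-comment line holds two tab- (or whitespace-) separated node
#' identifiers. Duplicate pairs in either orientation are collapsed and
#' self-loops dropped, with the counts reported via `message()`.
#'
#' @param path Path to the edge-list file; `#` lines are comments.
#' @return An undirected simple [igraph::graph] object.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("no edges in ", path, call. = FALSE)
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 2L))
    stop("line(s) without exactly two fields: ",
         paste(which(nf != 2L), collapse = ", "), call. = FALSE)
  a <- vapply(fields, `[`, character(1L), 1L)
  b <- vapply(fields, `[`, character(1L), 2L)
  loops <- a == b
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  a2 <- a[!loops]; b2 <- b[!loops]
  key <- ifelse(a2 < b2, paste(a2, b2, sep = "\r"), paste(b2, a2, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup))
    message(sum(dup), " duplicate edge(s) collapsed")
  if (!any(!loops))
    stop("edge list contains only self-loops: ", path, call. = FALSE)
  edges <- do.call(rbind, strsplit(unique(key), "\r", fixed = TRUE))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# 0-based adjacency list of an igraph, in vertex order.
adjacency_list0 <- function(net) {
  lapply(igraph::adjacent_vertices(net, igraph::V(net)),
         function(v) as.integer(v) - 1L)
}

#' Normalized betweenness centrality
#'
#' For every node v, `B_v = sum over ordered pairs i != j (both != v) of
#' sigma_ivj / sigma_ij, divided by (n-1)(n-2)`, where `sigma_ij` counts
#' the shortest i-j paths and `sigma_ivj` those passing through v.
#' Unreachable pairs contribute 0. Computed by Brandes' accumulation;
#' the ordered-pair normalisation uses the whole-graph n even when the
#' graph is disconnected.
#'
#' @param net An undirected simple igraph (at least 3 nodes, so that
#'   `(n-1)(n-2) > 0`).
#' @return Named numeric vector of `B_v` in \[0, 1\].
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3L)
    stop("betweenness normalisation needs at least 3 nodes", call. = FALSE)
  raw <- .brandes_cpp(adjacency_list0(net))
  # Brandes from every source counts each ordered (s, t) pair once.
  setNames(raw / ((n - 1) * (n - 2)), igraph::V(net)$name)
}

#' Local clustering coefficient
#'
#' `CC_v = 2 e_v / (k (k - 1))` where `e_v` is the number of edges among
#' the k neighbours of v; `CC_v = 0` when `k < 2`.
#'
#' @param net An undirected simple igraph.
#' @return Named numeric vector of `CC_v` in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)), as.integer)
  cc <- vapply(adj, function(nb) {
    k <- length(nb)
    if (k < 2L) return(0)
    e <- sum(vapply(adj[nb], function(x) sum(x %in% nb), numeric(1L))) / 2
    2 * e / (k * (k - 1))
  }, numeric(1L))
  setNames(cc, igraph::V(net)$name)
}

#' Average shortest path length per node
#'
#' Mean breadth-first hop distance from each node to every *reachable*
#' other node; `NA` for isolated nodes. Nodes in other components are
#' ignored rather than treated as infinitely far.
#'
#' @param net An undirected simple igraph.
#' @return Named numeric vector (values >= 1 where defined).
#' @export
avg_shortest_path <- function(net) {
  d <- igraph::distances(net)
  diag(d) <- Inf
  out <- apply(d, 1L, function(row) {
    finite <- row[is.finite(row)]
    if (length(finite) == 0L) NA_real_ else mean(finite)
  })
  setNames(out, igraph::V(net)$name)
}

#' Node degree
#'
#' @param net An undirected simple igraph.
#' @return Named integer vector of simple-graph degrees.
#' @export
node_degree <- function(net) {
  setNames(as.integer(igraph::degree(net)), igraph::V(net)$name)
}

#' Topology metrics for a gene set
#'
#' One row per gene present as a network node, carrying all four node
#' metrics; genes not in the network are omitted with a warning and the
#' count attached as the `"omitted"` attribute.
#'
#' @param net An undirected simple igraph.
#' @param genes A [gene_set()].
#' @return `data.frame` with columns `node`, `degree`, `clustering`,
#'   `betweenness`, `aspl`.
#' @export
topology_table <- function(net, genes) {
  stopifnot(inherits(genes, "gene_set"))
  nodes <- igraph::V(net)$name
  present <- intersect(genes$genes, nodes)
  omitted <- length(genes$genes) - length(present)
  if (omitted > 0L)
    warning(omitted, " gene(s) of '", genes$label,
            "' absent from the network", call. = FALSE)
  deg <- node_degree(net)
  cc <- clustering_coefficient(net)
  bc <- betweenness_centrality(net)
  aspl <- avg_shortest_path(net)
  out <- data.frame(node = present,
                    degree = unname(deg[present]),
                    clustering = unname(cc[present]),
                    betweenness = unname(bc[present]),
                    aspl = unname(aspl[present]),
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  out
}
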