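#' Construct a tubular network
#'
#' A `tubular_network` is the package's basic container: a connected planar
#' graph whose nodes carry 2D coordinates (micrometres) and a role, and whose
#' edges are cylindrical tubules with a length and a radius. It is the geometry
#' on which flows are solved and particles are advected.
#'
#' @param nodes data.frame with columns `id` (integer, 1..N), `x`, `y`
#'   (micrometres) and `role` (one of `"normal"`, `"exit"`, `"sheet"`).
#' @param edges data.frame with columns `i`, `j` (node ids), `length`
#'   (micrometres) and `radius` (micrometres).
#' @param metadata free-form provenance list.
#' @param validate check the class invariants (connectivity, positive lengths
#'   and radii, no self-loops or duplicate edges, lengths consistent with node
#'   coordinates). Lengths may deviate from the Euclidean node distance only if
#'   `metadata$lengths_overridden` is `TRUE`.
#' @return an object of class `tubular_network`.
#' @export
tubular_network <- function(nodes, edges, metadata = list(), validate = TRUE) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y", "role") %in% names(nodes)),
            all(c("i", "j", "length", "radius") %in% names(edges)))
  nodes$id <- as.integer(nodes$id)
  edges$i <- as.integer(edges$i)
  edges$j <- as.integer(edges$j)
  net <- structure(list(nodes = nodes, edges = edges, metadata = metadata),
                   class = "tubular_network")
  if (validate) validate_network(net)
  net
}

validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(edges$i %in% nodes$id) || !all(edges$j %in% nodes$id))
    stop("edge endpoint not among node ids")
  if (any(edges$i == edges$j)) stop("self-loop edge")
  key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  if (anyDuplicated(key)) stop("duplicate edge")
  if (any(edges$length <= 0)) stop("non-positive edge length")
  if (any(edges$radius <= 0)) stop("non-positive edge radius")
  if (!all(nodes$role %in% c("normal", "exit", "sheet")))
    stop("node role must be one of 'normal', 'exit', 'sheet'")
  if (!isTRUE(net$metadata$lengths_overridden)) {
    ii <- match(edges$i, nodes$id)
    jj <- match(edges$j, nodes$id)
    d <- sqrt((nodes$x[ii] - nodes$x[jj])^2 + (nodes$y[ii] - nodes$y[jj])^2)
    if (any(abs(d - edges$length) > 1e-9))
      stop("edge lengths inconsistent with node coordinates (> 1e-9 um)")
  }
  g <- network_igraph(net)
  if (igraph::components(g)$no != 1L) stop("network is not connected")
  invisible(net)
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$i, to = net$edges$j),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
}

#' @method print tubular_network
#' @export
print.tubular_network <- function(x, ...) {
  s <- network_statistics(x)
  cat(sprintf(
    "tubular_network: %d nodes, %d edges\n  mean degree %.2f, mean edge length %.3f um, radius %.3g um\n  roles: %s\n",
    s$n_nodes, s$n_edges, s$mean_degree, s$mean_edge_length,
    x$edges$radius[1], paste(names(table(x$nodes$role)),
                             table(x$nodes$role), collapse = ", ")))
  invisible(x)
}

#' Exit nodes of a network
#' @param net a `tubular_network`.
#' @return integer vector of node ids with role `"exit"`.
#' @export
exit_nodes <- function(net) net$nodes$id[net$nodes$role == "exit"]

#' Sheet nodes of a network
#' @param net a `tubular_network`.
#' @return integer vector of node ids with role `"sheet"`.
#' @export
sheet_nodes <- function(net) net$nodes$id[net$nodes$role == "sheet"]

#' Build a regular honeycomb network
#'
#' Constructs a planar hexagonal lattice of `rows` x `cols` hexagonal faces
#' with a uniform edge (tubule) length, the idealised stand-in for a peripheral
#' ER network: every interior node has degree 3. Boundary nodes (degree < 3)
#' are given the role `"exit"`, modelling connections to a large fluid
#' reservoir at the network periphery.
#'
#' Coordinates are generated on the exact integer lattice
#' (x = sqrt(3)/2 * u, y = 1/2 * v in units of the edge length), so shared
#' hexagon corners coincide exactly and all edges have exactly the requested
#' length.
#'
#' @param rows,cols number of hexagon rows and columns (both >= 1; the
#'   degenerate 1x1 case is a single hexagon).
#' @param edge_length tubule length in micrometres (default 1).
#' @param radius tubule radius in micrometres (default 0.03, i.e. 30 nm).
#' @return a `tubular_network`; `E - N + 1 == rows * cols` (one independent
#'   cycle per hexagonal face).
#' @export
build_honeycomb <- function(rows, cols, edge_length = 1, radius = 0.03) {
  if (length(rows) != 1 || length(cols) != 1 || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols))
    stop("invalid argument: rows and cols must be positive integers")
  if (edge_length <= 0) stop("invalid argument: edge_length must be positive")
  # pointy-top hexagons; centre of hexagon (r,c) at integer lattice
  # (u, v) with x = sqrt(3)/2 * s * u, y = s * v / 2
  corners_u <- c(0L, 1L, 1L, 0L, -1L, -1L)
  corners_v <- c(2L, 1L, -1L, -2L, -1L, 1L)
  uu <- integer(0); vv <- integer(0)
  hex_id <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      cu <- 2L * c + (r %% 2L)
      cv <- 3L * r
      uu <- c(uu, cu + corners_u)
      vv <- c(vv, cv + corners_v)
    }
  }
  key <- paste(uu, vv)
  uniq <- !duplicated(key)
  node_u <- uu[uniq]; node_v <- vv[uniq]
  ord <- order(node_v, node_u)
  node_u <- node_u[ord]; node_v <- node_v[ord]
  node_key <- paste(node_u, node_v)
  n_hex <- rows * cols
  # edges: consecutive corners of each hexagon
  e_from <- integer(0); e_to <- integer(0)
  idx <- match(key, node_key)
  for (h in seq_len(n_hex)) {
    base <- (h - 1L) * 6L
    a <- idx[base + 1:6]
    b <- idx[base + c(2:6, 1L)]
    e_from <- c(e_from, pmin(a, b))
    e_to <- c(e_to, pmax(a, b))
  }
  ekey <- paste(e_from, e_to)
  keep <- !duplicated(ekey)
  e_from <- e_from[keep]; e_to <- e_to[keep]
  s <- edge_length
  nodes <- data.frame(id = seq_along(node_u),
                      x = sqrt(3) / 2 * s * node_u,
                      y = s * node_v / 2,
                      role = "normal", stringsAsFactors = FALSE)
  deg <- tabulate(c(e_from, e_to), nbins = nrow(nodes))
  nodes$role[deg < 3] <- "exit"
  edges <- data.frame(i = e_from, j = e_to, length = s, radius = radius)
  net <- tubular_network(nodes, edges,
                         metadata = list(kind = "honeycomb", rows = rows,
                                         cols = cols,
                                         lengths_overridden = TRUE))
  net$metadata$lengths_overridden <- NULL  # lengths are exact; re-validate
  validate_network(net)
  net
}

#' Generate a synthetic ER-like planar network
#'
#' Produces a connected planar network with the summary statistics typical of
#' reconstructed peripheral ER networks: mean node degree close to 3 and a
#' prescribed mean edge length (about 1 micrometre in COS-7 cells). The
#' construction dilutes and jitters a disc-clipped honeycomb lattice: node
#' positions are perturbed uniformly, a fraction of edges is removed (keeping
#' the graph connected), and coordinates are rescaled so the mean edge length
#' matches the target exactly.
#'
#' @param n_nodes approximate number of nodes (>= 10).
#' @param target_mean_edge_length target mean tubule length in micrometres.
#' @param seed integer seed; the same seed reproduces the same network.
#' @param radius tubule radius in micrometres.
#' @param jitter positional jitter amplitude as a fraction of the edge length.
#' @param dilution fraction of edges considered for removal.
#' @return a `tubular_network` with mean degree in [2.5, 3.5].
#' @export
generate_er_like_network <- function(n_nodes, target_mean_edge_length = 1,
                                     seed = 1, radius = 0.03,
                                     jitter = 0.2, dilution = 0.1) {
  if (n_nodes < 10) stop("invalid argument: n_nodes must be >= 10")
  if (target_mean_edge_length <= 0) stop("invalid argument: target length")
  for (attempt in 0:4) {
    net <- try(er_like_attempt(n_nodes, target_mean_edge_length,
                               seed + 1000L * attempt, radius,
                               jitter, dilution), silent = TRUE)
    if (!inherits(net, "try-error")) {
      s <- network_statistics(net)
      if (s$mean_degree >= 2.5 && s$mean_degree <= 3.5) return(net)
    }
  }
  stop("generation-failure: could not satisfy network constraints")
}

er_like_attempt <- function(n_nodes, target, seed, radius, jitter, dilution) {
  side <- max(2L, ceiling(sqrt(n_nodes / 2) * 1.4))
  base <- build_honeycomb(side, side, edge_length = 1, radius = radius)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nodes <- base$nodes
  edges <- base$edges
  # clip to disc: keep the n_nodes nodes closest to the centroid
  d2 <- (nodes$x - mean(nodes$x))^2 + (nodes$y - mean(nodes$y))^2
  keep_ids <- nodes$id[order(d2)][seq_len(min(n_nodes, nrow(nodes)))]
  edges <- edges[edges$i %in% keep_ids & edges$j %in% keep_ids, ]
  # largest connected component
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j), directed = FALSE,
    vertices = data.frame(name = keep_ids))
  comp <- igraph::components(g)
  big <- as.integer(igraph::V(g)$name[comp$membership == which.max(comp$csize)])
  nodes <- nodes[nodes$id %in% big, ]
  edges <- edges[edges$i %in% big & edges$j %in% big, ]
  # dilute edges, preserving connectivity and a mean degree comfortably
  # inside the target band (each deletion lowers the degree sum by 2)
  md0 <- 2 * nrow(edges) / nrow(nodes)
  n_del <- min(round(dilution * nrow(edges)),
               max(0L, floor((md0 - 2.55) * nrow(nodes) / 2)))
  cand <- sample(nrow(edges), size = n_del)
  for (e in sort(cand, decreasing = TRUE)) {
    sub <- edges[-e, ]
    gs <- igraph::graph_from_data_frame(
      data.frame(from = sub$i, to = sub$j), directed = FALSE,
      vertices = data.frame(name = nodes$id))
    if (igraph::components(gs)$no == 1L) edges <- sub
  }
  # jitter positions
  nodes$x <- nodes$x + stats::runif(nrow(nodes), -jitter, jitter)
  nodes$y <- nodes$y + stats::runif(nrow(nodes), -jitter, jitter)
  ii <- match(edges$i, nodes$id); jj <- match(edges$j, nodes$id)
  len <- sqrt((nodes$x[ii] - nodes$x[jj])^2 + (nodes$y[ii] - nodes$y[jj])^2)
  scale <- target / mean(len)
  nodes$x <- nodes$x * scale; nodes$y <- nodes$y * scale
  edges$length <- len * scale
  # renumber 1..N
  nodes$id2 <- seq_len(nrow(nodes))
  edges$i <- nodes$id2[match(edges$i, nodes$id)]
  edges$j <- nodes$id2[match(edges$j, nodes$id)]
  nodes$id <- nodes$id2; nodes$id2 <- NULL
  deg <- tabulate(c(edges$i, edges$j), nbins = nrow(nodes))
  nodes$role <- ifelse(deg <= 2, "exit", "normal")
  tubular_network(nodes, edges,
                  metadata = list(kind = "er_like", seed = seed,
                                  target_mean_edge_length = target))
}

#' Spanning tree and fundamental cycle basis
#'
#' Computes a breadth-first-search spanning tree and the fundamental cycle
#' basis of a connected network: one cycle per non-tree edge, obtained by
#' closing the unique tree path between the edge's endpoints. The pressure
#' consistency law (K2) of the hydraulic solver is imposed on exactly these
#' E - N + 1 independent cycles.
#'
#' The BFS starts from the lowest node id and explores neighbours in ascending
#' id order, so the basis is reproducible.
#'
#' @param net a connected `tubular_network`.
#' @return a list of class `cycle_basis` with elements `tree_edges` (indices
#'   into `net$edges`), `non_tree_edges`, `parent` (tree parent of each node,
#'   0 for the root), `parent_edge` (edge index to the parent), and `cycles`
#'   (list of node-id sequences; the closing non-tree edge joins the last node
#'   back to the first).
#' @export
compute_cycle_basis <- function(net) {
  N <- nrow(net$nodes)
  E <- nrow(net$edges)
  adj <- vector("list", N)
  for (e in seq_len(E)) {
    i <- net$edges$i[e]; j <- net$edges$j[e]
    adj[[i]] <- rbind(adj[[i]], c(j, e))
    adj[[j]] <- rbind(adj[[j]], c(i, e))
  }
  adj <- lapply(adj, function(m) if (is.null(m)) m else m[order(m[, 1]), , drop = FALSE])
  root <- min(net$nodes$id)
  parent <- integer(N); parent_edge <- integer(N)
  visited <- logical(N)
  visited[root] <- TRUE
  queue <- root
  tree_edges <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1]; e <- nb[k, 2]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        parent_edge[w] <- e
        tree_edges <- c(tree_edges, e)
        queue <- c(queue, w)
      }
    }
  }
  if (!all(visited)) stop("invalid-network: graph is disconnected")
  non_tree <- setdiff(seq_len(E), tree_edges)
  path_to_root <- function(v) {
    p <- v
    while (parent[v] != 0L) { v <- parent[v]; p <- c(p, v) }
    p
  }
  cycles <- lapply(non_tree, function(e) {
    i <- net$edges$i[e]; j <- net$edges$j[e]
    pi <- path_to_root(i); pj <- path_to_root(j)
    common <- intersect(pi, pj)
    lca <- common[which.min(match(common, pi))]
    c(pi[seq_len(match(lca, pi))], rev(pj[seq_len(match(lca, pj) - 1L)]))
  })
  structure(list(tree_edges = tree_edges, non_tree_edges = non_tree,
                 parent = parent, parent_edge = parent_edge, root = root,
                 cycles = cycles),
            class = "cycle_basis")
}

#' Tree path between two nodes
#'
#' Node sequence of the unique path between `a` and `b` in the spanning tree of
#' a `cycle_basis`. Used to impose equal-pressure conditions between exit (or
#' sheet) nodes.
#' @param basis a `cycle_basis`.
#' @param a,b node ids.
#' @return integer vector of node ids from `a` to `b`.
#' @export
tree_path <- function(basis, a, b) {
  up <- function(v) {
    p <- v
    while (basis$parent[v] != 0L) { v <- basis$parent[v]; p <- c(p, v) }
    p
  }
  pa <- up(a); pb <- up(b)
  common <- intersect(pa, pb)
  lca <- common[which.min(match(common, pa))]
  c(pa[seq_len(match(lca, pa))], rev(pb[seq_len(match(lca, pb) - 1L)]))
}

#' Summary statistics of a network
#'
#' @param net a `tubular_network`.
#' @return list with `n_nodes`, `n_edges`, `mean_degree`, `mean_edge_length`,
#'   `degree_distribution` (table) and `edge_lengths` (numeric vector).
#' @export
network_statistics <- function(net) {
  deg <- tabulate(c(net$edges$i, net$edges$j), nbins = nrow(net$nodes))
  list(n_nodes = nrow(net$nodes),
       n_edges = nrow(net$edges),
       mean_degree = mean(deg),
       mean_edge_length = mean(net$edges$length),
       degree_distribution = table(deg),
       edge_lengths = net$edges$length)
}

#' Read or write a tubular network
#'
#' Supported formats: `"json"` (a single file with `nodes`, `edges`,
#' `metadata`), `"csv"` (a directory holding `nodes.csv` and `edges.csv`), and
#' `"graphml"` (via igraph, with identical attribute names). Coordinates and
#' lengths are stored in micrometres. `write_network` followed by
#' `read_network` is the identity on all fields.
#'
#' @param path file (json, graphml) or directory (csv).
#' @param format one of `"json"`, `"csv"`, `"graphml"`; inferred from the file
#'   extension when missing.
#' @return `read_network` returns a `tubular_network`; `write_network` returns
#'   `path` invisibly.
#' @export
read_network <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  net <- switch(format,
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (is.null(x$nodes) || is.null(x$edges))
        stop("parse-error: missing 'nodes' or 'edges' in ", path)
      tubular_network(x$nodes, x$edges, metadata = as.list(x$metadata))
    },
    csv = {
      nf <- file.path(path, "nodes.csv"); ef <- file.path(path, "edges.csv")
      if (!file.exists(nf) || !file.exists(ef))
        stop("parse-error: expected nodes.csv and edges.csv under ", path)
      tubular_network(utils::read.csv(nf), utils::read.csv(ef))
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      vd <- igraph::as_data_frame(g, what = "vertices")
      ed <- igraph::as_data_frame(g, what = "edges")
      nodes <- data.frame(id = as.integer(vd$name), x = vd$x, y = vd$y,
                          role = vd$role)
      edges <- data.frame(i = as.integer(ed$from), j = as.integer(ed$to),
                          length = ed$length, radius = ed$radius)
      tubular_network(nodes, edges)
    },
    stop("unknown format: ", format))
  net
}

#' @rdname read_network
#' @param net a `tubular_network`.
#' @export
write_network <- function(net, path, format = NULL) {
  format <- format %||% infer_format(path)
  switch(format,
    json = jsonlite::write_json(
      list(nodes = net$nodes, edges = net$edges, metadata = net$metadata),
      path, digits = NA, auto_unbox = TRUE),
    csv = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(net$nodes, file.path(path, "nodes.csv"), row.names = FALSE)
      utils::write.csv(net$edges, file.path(path, "edges.csv"), row.names = FALSE)
    },
    graphml = {
      g <- igraph::graph_from_data_frame(
        data.frame(from = net$edges$i, to = net$edges$j,
                   length = net$edges$length, radius = net$edges$radius),
        directed = FALSE,
        vertices = data.frame(name = net$nodes$id,
                              x = net$nodes$x, y = net$nodes$y,
                              role = net$nodes$role))
      igraph::write_graph(g, path, format = "graphml")
    },
    stop("unknown format: ", format))
  invisible(path)
}

infer_format <- function(path) {
  if (grepl("\\.json$", path)) "json"
  else if (grepl("\\.graphml$", path)) "graphml"
  else "csv"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
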