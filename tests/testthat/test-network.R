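test_that("honeycomb lattice has degree-3 interior, exact edge lengths, one cycle per face", {
  for (dims in list(c(2, 2), c(2, 1), c(3, 3))) {
    net <- build_honeycomb(dims[1], dims[2], edge_length = 1)
    s <- network_statistics(net)
    deg <- tabulate(c(net$edges$i, net$edges$j), nbins = s$n_nodes)
    expect_true(all(deg[net$nodes$role == "normal"] == 3))
    expect_true(all(deg <= 3))
    expect_true(all(net$edges$length == 1))
    # graph-rank identity: independent cycles = hexagonal faces
    expect_equal(s$n_edges - s$n_nodes + 1L, dims[1] * dims[2])
  }
  expect_error(build_honeycomb(0, 2), "invalid")
  expect_error(build_honeycomb(2, 2, edge_length = -1), "invalid")
})

test_that("honeycomb coordinates are planar (no crossing edges)", {
  net <- build_honeycomb(3, 4)
  seg <- cbind(net$nodes$x[net$edges$i], net$nodes$y[net$edges$i],
               net$nodes$x[net$edges$j], net$nodes$y[net$edges$j])
  crosses <- function(p, q) {
    d <- function(ax, ay, bx, by, cx, cy)
      (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(p[1], p[2], p[3], p[4], q[1], q[2])
    d2 <- d(p[1], p[2], p[3], p[4], q[3], q[4])
    d3 <- d(q[1], q[2], q[3], q[4], p[1], p[2])
    d4 <- d(q[1], q[2], q[3], q[4], p[3], p[4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  E <- nrow(net$edges)
  bad <- 0L
  for (e1 in seq_len(E - 1)) for (e2 in (e1 + 1):E) {
    sh <- length(intersect(c(net$edges$i[e1], net$edges$j[e1]),
                           c(net$edges$i[e2], net$edges$j[e2])))
    if (sh == 0 && crosses(seg[e1, ], seg[e2, ])) bad <- bad + 1L
  }
  expect_identical(bad, 0L)
})

test_that("synthetic ER-like generator meets its summary-statistic contract", {
  net <- generate_er_like_network(200, 1.0, seed = 1)
  s <- network_statistics(net)
  expect_gte(s$mean_degree, 2.5)
  expect_lte(s$mean_degree, 3.5)
  expect_lt(abs(s$mean_edge_length - 1.0) / 1.0, 0.2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$i, to = net$edges$j), directed = FALSE,
    vertices = data.frame(name = net$nodes$id))
  expect_equal(igraph::components(g)$no, 1)
  # determinism
  net2 <- generate_er_like_network(200, 1.0, seed = 1)
  expect_identical(net$edges, net2$edges)
  expect_identical(net$nodes, net2$nodes)
  expect_error(generate_er_like_network(5, 1, seed = 1), "invalid")
})

test_that("cycle basis: counts, tree size, partition, generating-edge membership", {
  # a tree (path) network has no cycles
  path_net <- tubular_network(
    data.frame(id = 1:4, x = 0:3, y = 0, role = c("exit", "normal", "normal", "exit")),
    data.frame(i = 1:3, j = 2:4, length = 1, radius = 0.03))
  cb <- compute_cycle_basis(path_net)
  expect_length(cb$cycles, 0)
  expect_length(cb$tree_edges, 3)

  # single triangle: one cycle through all three nodes
  tri <- tubular_network(
    data.frame(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1), role = "exit"),
    data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
               length = c(1, sqrt(1.25), sqrt(1.25)), radius = 0.03))
  cb <- compute_cycle_basis(tri)
  expect_length(cb$cycles, 1)
  expect_setequal(cb$cycles[[1]], 1:3)

  for (net in list(build_honeycomb(3, 3), generate_er_like_network(80, 1, seed = 4))) {
    N <- nrow(net$nodes); E <- nrow(net$edges)
    cb <- compute_cycle_basis(net)
    expect_length(cb$tree_edges, N - 1)
    expect_length(cb$cycles, E - N + 1)
    # tree and non-tree edges partition the edge set
    expect_setequal(c(cb$tree_edges, cb$non_tree_edges), seq_len(E))
    # each fundamental cycle contains its generating edge exactly once
    for (k in seq_along(cb$cycles)) {
      cy <- cb$cycles[[k]]
      gen <- cb$non_tree_edges[k]
      ends <- c(net$edges$i[gen], net$edges$j[gen])
      expect_setequal(c(cy[1], cy[length(cy)]), ends)
      expect_identical(sum(cy %in% ends), 2L)
    }
    # tree is acyclic and connected: spans all nodes with N-1 edges
    tg <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$i[cb$tree_edges],
                 to = net$edges$j[cb$tree_edges]),
      directed = FALSE, vertices = data.frame(name = net$nodes$id))
    expect_equal(igraph::components(tg)$no, 1)
  }
})

test_that("network statistics match a direct recount of the edge list", {
  net <- build_honeycomb(4, 4, edge_length = 1)
  s <- network_statistics(net)
  expect_equal(s$mean_edge_length, 1.0)
  one <- single_tubule_net(l = 2)
  expect_equal(network_statistics(one)$mean_degree, 1)
  gen <- generate_er_like_network(60, 1, seed = 9)
  s <- network_statistics(gen)
  deg_recount <- table(factor(c(gen$edges$i, gen$edges$j),
                              levels = gen$nodes$id))
  expect_equal(s$mean_degree, mean(as.integer(deg_recount)))
  expect_equal(s$mean_edge_length, mean(gen$edges$length))
  expect_identical(s$n_edges, nrow(gen$edges))
})

test_that("network io round-trips and rejects malformed input", {
  net <- build_honeycomb(2, 2)
  td <- withr::local_tempdir()
  for (fmt in c("json", "graphml")) {
    f <- file.path(td, paste0("net.", fmt))
    write_network(net, f, fmt)
    back <- read_network(f, fmt)
    expect_equal(back$nodes[c("id", "x", "y", "role")],
                 net$nodes[c("id", "x", "y", "role")])
    expect_equal(back$edges[c("i", "j", "length", "radius")],
                 net$edges[c("i", "j", "length", "radius")])
  }
  d <- file.path(td, "csvnet")
  write_network(net, d, "csv")
  back <- read_network(d, "csv")
  expect_equal(back$edges$length, net$edges$length)

  # explicit small fixture: 3 nodes / 2 edges
  d2 <- file.path(td, "tiny")
  dir.create(d2)
  writeLines(c("id,x,y,role", "1,0,0,exit", "2,1,0,normal", "3,2,0,exit"),
             file.path(d2, "nodes.csv"))
  writeLines(c("i,j,length,radius", "1,2,1,0.03", "2,3,1,0.03"),
             file.path(d2, "edges.csv"))
  tiny <- read_network(d2, "csv")
  expect_identical(nrow(tiny$nodes), 3L)
  expect_identical(nrow(tiny$edges), 2L)

  # duplicate edge must be rejected on read
  writeLines(c("i,j,length,radius", "1,2,1,0.03", "2,1,1,0.03"),
             file.path(d2, "edges.csv"))
  expect_error(read_network(d2, "csv"), "duplicate")
})
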