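# Independent oracles used to cross-check the implementation.

# Hydraulic resistance of one tubule segment by adaptive quadrature of the
# lubrication integrand 1 / (a(z)^4 (1 + 4 lambda / a(z))): straight part of
# length L1 at radius R plus one linear pinch flank from R down to b over
# length L. Independent of the closed forms in the package.
oracle_segment_resistance <- function(L1, L, R, b, lambda = 0, mu = 1) {
  flank <- if (L > 0) {
    f <- function(s) {
      a <- R - (R - b) * s / L
      1 / (a^4 * (1 + 4 * lambda / a))
    }
    stats::integrate(f, 0, L, rel.tol = 1e-12, abs.tol = 0)$value
  } else 0
  (8 * mu / pi) * (L1 / (R^4 * (1 + 4 * lambda / R)) + flank)
}

# Dense nodal-analysis flow solve built from first principles: unknown
# pressures at all non-exit nodes of the dummy-node-expanded graph (sheet
# nodes share a single pressure unknown), exit pressures fixed at zero,
# conductances from quadrature resistances, base::solve on the dense system.
oracle_dense_flow <- function(net, b = NULL, bdot = NULL, L = NULL,
                              node_q = NULL, sheet_total = 0, lambda = 0,
                              mu = 1) {
  N <- nrow(net$nodes); E <- nrow(net$edges)
  R <- net$edges$radius; l <- net$edges$length
  if (is.null(b)) b <- R
  if (is.null(bdot)) bdot <- numeric(E)
  if (is.null(L)) L <- numeric(E)
  if (is.null(node_q)) node_q <- numeric(N)
  L1 <- (l - 2 * L) / 2
  r1 <- r2 <- numeric(E)
  for (e in seq_len(E)) {
    r1[e] <- oracle_segment_resistance(L1[e], L[e], R[e], b[e], lambda, mu)
    r2[e] <- r1[e]  # symmetric midpoint pinch
  }
  q_pinch <- -(2 * pi / 3) * bdot * L * (R + 2 * b)
  exits <- net$nodes$id[net$nodes$role == "exit"]
  sheets <- net$nodes$id[net$nodes$role == "sheet"]
  # pressure unknown index per expanded node (0 = grounded exit)
  n_exp <- N + E
  pidx <- integer(n_exp)
  nun <- 0L
  for (n in seq_len(N)) {
    if (n %in% exits) next
    if (n %in% sheets) next
    nun <- nun + 1L; pidx[n] <- nun
  }
  sheet_idx <- if (length(sheets)) { nun <- nun + 1L; nun } else 0L
  pidx[sheets] <- sheet_idx
  for (e in seq_len(E)) { nun_d <- N + e; nun <- nun + 1L; pidx[nun_d] <- nun }
  # segments of the expanded graph: (i -> dummy, r1), (dummy -> j, r2)
  seg_a <- c(net$edges$i, N + seq_len(E))
  seg_b <- c(N + seq_len(E), net$edges$j)
  seg_r <- c(r1, r2)
  A <- matrix(0, nun, nun); rhs <- numeric(nun)
  add_k1 <- function(row, n, A, rhs) {
    for (s in seq_along(seg_r)) {
      if (seg_a[s] == n || seg_b[s] == n) {
        other <- if (seg_a[s] == n) seg_b[s] else seg_a[s]
        g <- 1 / seg_r[s]
        A[row, pidx[n]] <- A[row, pidx[n]] + g
        if (pidx[other] > 0) A[row, pidx[other]] <- A[row, pidx[other]] - g
      }
    }
    list(A = A, rhs = rhs)
  }
  row <- 0L
  for (n in seq_len(N)) {
    if (n %in% exits || n %in% sheets) next
    row <- row + 1L
    tmp <- add_k1(row, n, A, rhs)
    A <- tmp$A
    rhs[row] <- node_q[n]
  }
  if (length(sheets)) {
    row <- row + 1L
    for (n in sheets) { tmp <- add_k1(row, n, A, rhs); A <- tmp$A }
    rhs[row] <- sheet_total
  }
  for (e in seq_len(E)) {
    row <- row + 1L
    tmp <- add_k1(row, N + e, A, rhs)
    A <- tmp$A
    rhs[row] <- q_pinch[e]
  }
  p <- solve(A, rhs)
  pr <- function(n) if (pidx[n] > 0) p[pidx[n]] else 0
  Q1 <- vapply(seq_len(E), function(e) (pr(net$edges$i[e]) - pr(N + e)) / r1[e],
               numeric(1))
  Q4 <- vapply(seq_len(E), function(e) (pr(N + e) - pr(net$edges$j[e])) / r2[e],
               numeric(1))
  list(Q1 = Q1, Q4 = Q4)
}

# Small random connected planar-ish network for solver cross-checks: a jittered
# triangular patch via a random spanning structure -- build from a random
# geometric construction independent of the package generators.
oracle_random_network <- function(n, seed, radius = 0.03) {
  set.seed(seed)
  repeat {
    x <- runif(n, 0, 3); y <- runif(n, 0, 3)
    # connect each node to its 2 nearest neighbours, dedupe
    d <- as.matrix(dist(cbind(x, y)))
    ei <- integer(0); ej <- integer(0)
    for (k in seq_len(n)) {
      nb <- order(d[k, ])[2:3]
      ei <- c(ei, rep(k, 2)); ej <- c(ej, nb)
    }
    a <- pmin(ei, ej); bb <- pmax(ei, ej)
    keep <- !duplicated(paste(a, bb))
    a <- a[keep]; bb <- bb[keep]
    g <- igraph::graph_from_edgelist(cbind(a, bb), directed = FALSE)
    if (igraph::vcount(g) == n && igraph::components(g)$no == 1) break
  }
  len <- sqrt((x[a] - x[bb])^2 + (y[a] - y[bb])^2)
  deg <- tabulate(c(a, bb), nbins = n)
  role <- ifelse(deg <= 2, "exit", "normal")
  if (!any(role == "exit")) role[which.min(deg)] <- "exit"
  nodes <- data.frame(id = seq_len(n), x = x, y = y, role = role)
  edges <- data.frame(i = a, j = bb, length = len, radius = radius)
  tubular_network(nodes, edges)
}

# Pure-R Brownian walk in a static cylinder of radius a (no flow), specular
# reflection, recording (z, y1) at a given cadence. Independent of the C++
# kernel.
oracle_confined_walk <- function(n_particles, n_steps, dt, D, a, rp,
                                 rec_every) {
  sig <- sqrt(2 * D * dt)
  z <- numeric(n_particles)
  y1 <- numeric(n_particles); y2 <- numeric(n_particles)
  aeff <- a - rp
  nrec <- n_steps %/% rec_every
  zx <- matrix(0, n_particles, nrec); yx <- matrix(0, n_particles, nrec)
  for (s in seq_len(n_steps)) {
    z <- z + sig * rnorm(n_particles)
    y1 <- y1 + sig * rnorm(n_particles)
    y2 <- y2 + sig * rnorm(n_particles)
    r <- sqrt(y1^2 + y2^2)
    out <- which(r > aeff)
    for (k in out) {
      rr <- r[k]; it <- 0
      while (rr > aeff && it < 10) { rr <- abs(2 * aeff - rr); it <- it + 1 }
      if (rr > aeff) rr <- 0
      sc <- rr / r[k]
      y1[k] <- y1[k] * sc; y2[k] <- y2[k] * sc
    }
    if (s %% rec_every == 0) {
      zx[, s %/% rec_every] <- z
      yx[, s %/% rec_every] <- y1
    }
  }
  list(z = zx, y1 = yx)
}

# two-node, one-edge tubule with both ends open (exit nodes)
single_tubule_net <- function(l = 1, radius = 0.03, roles = c("exit", "exit")) {
  tubular_network(
    data.frame(id = 1:2, x = c(0, l), y = c(0, 0), role = roles),
    data.frame(i = 1, j = 2, length = l, radius = radius))
}

# direct access to the compiled kernel for controlled setups (frozen flow)
kernel_call <- function(state, n_sub, dt, D, rp, net, Q1, Q4,
                        b = NULL, bdot = NULL, L = NULL, slip = 0,
                        rec_every = 0L, n_rec = 1L, record_visits = FALSE) {
  E <- nrow(net$edges)
  l <- net$edges$length; R <- net$edges$radius
  if (is.null(b)) b <- R
  if (is.null(bdot)) bdot <- numeric(E)
  if (is.null(L)) L <- numeric(E)
  Q1 <- rep_len(Q1, E); Q4 <- rep_len(Q4, E)
  b <- rep_len(b, E); bdot <- rep_len(bdot, E); L <- rep_len(L, E)
  ii <- match(net$edges$i, net$nodes$id); jj <- match(net$edges$j, net$nodes$id)
  ex1 <- net$nodes$x[ii]; ey1 <- net$nodes$y[ii]
  eax <- (net$nodes$x[jj] - ex1) / l; eay <- (net$nodes$y[jj] - ey1) / l
  inc <- tubuleflow:::node_incidence(net)
  rec_x <- matrix(NA_real_, nrow(state), n_rec)
  rec_y <- matrix(NA_real_, nrow(state), n_rec)
  res <- tubuleflow:::advance_particles(
    state, as.integer(n_sub), dt, 0, D, rp, slip,
    net$edges$i, net$edges$j, l, R,
    ex1, ey1, eax, eay, Q1, Q4, b, bdot, L, (l - 2 * L) / 2,
    inc$ptr, inc$edge, inc$orient, rec_x, rec_y, as.integer(rec_every), 0L,
    record_visits, TRUE)
  list(state = state, res = res, rec_x = rec_x, rec_y = rec_y)
}
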