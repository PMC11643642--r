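#' Hagen-Poiseuille resistance of a straight tubule
#'
#' Hydraulic resistance (pressure drop per unit flux) of a uniform cylinder of
#' length `l` and radius `R`, optionally with a wall slip length `lambda`:
#' `r = (8 mu / pi) * l / (R^4 (1 + 4 lambda / R))`. With `mu = 1` the value is
#' viscosity-scaled; the network solve is independent of `mu` because the
#' viscosity multiplies every pressure equation uniformly.
#'
#' @param l tubule length (um).
#' @param R tubule radius (um).
#' @param lambda slip length (um, >= 0).
#' @param mu dynamic viscosity (arbitrary units; default 1, i.e. mu-scaled).
#' @return resistance (pressure / flux, mu-scaled by default).
#' @export
hp_resistance <- function(l, R, lambda = 0, mu = 1) {
  stopifnot(all(R > 0), all(lambda >= 0))
  (8 * mu / pi) * l / (R^4 * (1 + 4 * lambda / R))
}

# Pinch-region resistance factor per unit pinch half-length:
# integral of dz / (a^4 (1 + 4 lambda / a)) over one linear flank of the
# pinch, divided by L. For lambda = 0 the (R - b) denominator cancels
# algebraically: factor = (R^2 + R b + b^2) / (3 b^3 R^3). For lambda > 0 the
# closed logarithmic form is used, switching to a series in lambda when
# 4 lambda / b < 0.1 (the closed form loses the O(lambda^3) bracket to
# cancellation there).
pinch_flank_factor <- function(R, b, lambda = 0) {
  n <- max(length(R), length(b))
  R <- rep_len(R, n); b <- rep_len(b, n)
  if (lambda == 0) return((R^2 + R * b + b^2) / (3 * b^3 * R^3))
  out <- numeric(n)
  small <- 4 * lambda / b < 0.1
  if (any(!small)) {
    Rn <- R[!small]; bn <- b[!small]
    eq <- abs(Rn - bn) < 1e-12 * Rn
    val <- numeric(length(Rn))
    if (any(!eq)) {
      R2 <- Rn[!eq]; b2 <- bn[!eq]
      br <- log((1 + 4 * lambda / b2) / (1 + 4 * lambda / R2)) -
        (4 * lambda / b2) * (1 - 2 * lambda / b2) +
        (4 * lambda / R2) * (1 - 2 * lambda / R2)
      val[!eq] <- br / (64 * lambda^3 * (R2 - b2))
    }
    if (any(eq)) val[eq] <- 1 / (Rn[eq]^4 * (1 + 4 * lambda / Rn[eq]))
    out[!small] <- val
  }
  if (any(small)) {
    Rs <- R[small]; bs <- b[small]
    acc <- numeric(length(Rs))
    # sum_{k>=3} (-1)^(k+1) (4 lambda)^(k-3) S_k / (k b^k R^k),
    # S_k = sum_{j=0}^{k-1} R^j b^(k-1-j); exact at lambda = 0 (k = 3 term)
    for (k in 3:40) {
      j <- 0:(k - 1)
      Sk <- colSums(outer(j, Rs, function(p, r) r^p) *
                    outer(k - 1 - j, bs, function(p, bb) bb^p))
      term <- (-1)^(k + 1) * (4 * lambda)^(k - 3) * Sk / (k * bs^k * Rs^k)
      acc <- acc + term
      if (all(abs(term) <= 1e-16 * abs(acc))) break
    }
    out[small] <- acc
  }
  out
}

#' Segment resistances of a pinching tubule
#'
#' The modified Hagen-Poiseuille relation for a tubule carrying a symmetric
#' linear pinch splits the tubule at the pinch centre into two resistor
#' segments: `r1` spans the straight entry length `L1` plus the upstream pinch
#' flank of half-length `L`, and `r2` spans the downstream flank plus `L2`.
#' Without slip,
#' `r1 = (8 mu / pi) (L1 / R^4 + L (R^2 + R b + b^2) / (3 b^3 R^3))`,
#' which equals the textbook form `L / (3 (R - b)) * (1/b^3 - 1/R^3)` (the
#' apparent singularity at `b = R` cancels algebraically) and reduces to the
#' classical Hagen-Poiseuille resistance as `b -> R`. With slip the bracketed
#' logarithmic form is used; it recovers the no-slip values as `lambda -> 0`
#' and the slip-corrected straight-tube resistance as `b -> R`.
#'
#' @param L1,L2 straight segment lengths before/after the pinch (um).
#' @param L pinch half-length (um).
#' @param R tubule radius (um).
#' @param b current minimum pinch radius (um), `0 < b <= R`.
#' @param lambda slip length (um).
#' @param mu viscosity (default 1: mu-scaled resistances).
#' @return list with `r1` and `r2`.
#' @export
pinch_segment_resistances <- function(L1, L2, L, R, b, lambda = 0, mu = 1) {
  if (any(b <= 0)) stop("invalid argument: b must be positive (use b0 > 0)")
  if (any(b > R + 1e-15)) stop("invalid argument: b must not exceed R")
  fac <- pinch_flank_factor(R, pmin(b, R), lambda)
  straight <- 1 / (R^4 * (1 + 4 * lambda / R))
  list(r1 = (8 * mu / pi) * (L1 * straight + L * fac),
       r2 = (8 * mu / pi) * (L2 * straight + L * fac))
}

#' Build a reusable Kirchhoff flow solver
#'
#' Precomputes the sparse structure of the quasi-steady hydraulic problem on a
#' network. Every edge is split at its (potential) pinch site into two
#' resistor segments joined at a dummy node that carries the pinch volume
#' source. The unknowns are the `2E` segment fluxes, the `M1` exit-node
#' sources and, when sheet nodes are present, the `M2` sheet-node sources. The
#' equations are mass conservation (K1) at every node including dummies,
#' pressure consistency (K2) around each fundamental cycle, equal pressure
#' along tree paths between exit nodes (and between sheet nodes), and the
#' prescribed total sheet source. Only the resistance values change between
#' instants, so the sparse pattern and the value-permutation are cached.
#'
#' @param net a `tubular_network` with at least one exit node.
#' @param exit_ids,sheet_ids optional overrides of the node roles.
#' @return an object of class `flow_solver` for [solve_flow()].
#' @export
build_flow_solver <- function(net, exit_ids = NULL, sheet_ids = NULL) {
  N <- nrow(net$nodes); E <- nrow(net$edges)
  exit_ids <- sort(exit_ids %||% exit_nodes(net))
  sheet_ids <- sort(sheet_ids %||% sheet_nodes(net))
  if (length(intersect(exit_ids, sheet_ids)))
    stop("config-error: sheet nodes must be disjoint from exit nodes")
  if (length(exit_ids) < 1)
    stop("solver-error: at least one exit node is required")
  M1 <- length(exit_ids); M2 <- length(sheet_ids)
  basis <- compute_cycle_basis(net)
  # unknown columns: he1 (1..E), he2 (E+1..2E), exits, sheets
  col_he1 <- seq_len(E)
  col_he2 <- E + seq_len(E)
  col_exit <- 2L * E + seq_len(M1)
  col_sheet <- 2L * E + M1 + seq_len(M2)
  n_unknown <- 2L * E + M1 + M2
  ti <- integer(0); tj <- integer(0)      # triplet row/col
  tconst <- numeric(0)                    # constant values (NA when variable)
  the <- integer(0); tsign <- numeric(0)  # variable slots: halfedge id, sign
  add_const <- function(r, c, v) {
    ti <<- c(ti, r); tj <<- c(tj, c); tconst <<- c(tconst, v)
    the <<- c(the, 0L); tsign <<- c(tsign, 0)
  }
  add_res <- function(r, he, s) {
    ti <<- c(ti, r); tj <<- c(tj, he); tconst <<- c(tconst, NA_real_)
    the <<- c(the, he); tsign <<- c(tsign, s)
  }
  # K1 at original nodes (rows 1..N): sum of outflows - unknown source = rhs
  for (n in seq_len(N)) {
    es_i <- which(net$edges$i == n)
    es_j <- which(net$edges$j == n)
    for (e in es_i) add_const(n, col_he1[e], +1)
    for (e in es_j) add_const(n, col_he2[e], -1)
    if (n %in% exit_ids) add_const(n, col_exit[match(n, exit_ids)], -1)
    if (n %in% sheet_ids) add_const(n, col_sheet[match(n, sheet_ids)], -1)
  }
  # K1 at dummy nodes (rows N+1 .. N+E): Q_he2 - Q_he1 = q_pinch
  for (e in seq_len(E)) {
    add_const(N + e, col_he1[e], -1)
    add_const(N + e, col_he2[e], +1)
  }
  edge_lookup <- new.env(hash = TRUE)
  for (e in seq_len(E))
    assign(paste(net$edges$i[e], net$edges$j[e]), e, envir = edge_lookup)
  find_edge <- function(a, b) {
    e <- mget(paste(a, b), envir = edge_lookup, ifnotfound = list(NULL))[[1]]
    if (is.null(e)) {
      e <- get(paste(b, a), envir = edge_lookup)
      list(e = e, sign = -1)
    } else list(e = e, sign = +1)
  }
  add_pressure_row <- function(row, path) {
    # sum over traversed edges of sign * (r1 Q1 + r2 Q4) = 0
    for (k in seq_len(length(path) - 1L)) {
      fe <- find_edge(path[k], path[k + 1L])
      add_res(row, col_he1[fe$e], fe$sign)
      add_res(row, col_he2[fe$e], fe$sign)
    }
  }
  row <- N + E
  for (cy in basis$cycles) {
    row <- row + 1L
    add_pressure_row(row, c(cy, cy[1]))
  }
  if (M1 > 1) for (k in 2:M1) {
    row <- row + 1L
    add_pressure_row(row, tree_path(basis, exit_ids[1], exit_ids[k]))
  }
  if (M2 > 1) for (k in 2:M2) {
    row <- row + 1L
    add_pressure_row(row, tree_path(basis, sheet_ids[1], sheet_ids[k]))
  }
  if (M2 > 0) {
    row <- row + 1L
    for (c in col_sheet) add_const(row, c, 1)
  }
  stopifnot(row == n_unknown)
  template <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                                   dims = c(n_unknown, n_unknown))
  perm <- as.integer(template@x)  # triplet index stored at each slot
  structure(list(net = net, basis = basis, N = N, E = E,
                 exit_ids = exit_ids, sheet_ids = sheet_ids,
                 M1 = M1, M2 = M2, n_unknown = n_unknown,
                 template = template, perm = perm,
                 tconst = tconst, the = the, tsign = tsign,
                 col_exit = col_exit, col_sheet = col_sheet),
            class = "flow_solver")
}

#' Solve the instantaneous network flow
#'
#' Solves the precomputed Kirchhoff system of a [build_flow_solver()] object
#' for one instant. The pinch state is given per edge; inactive edges have
#' `b = R`, `bdot = 0`, `L = 0` and behave as plain Hagen-Poiseuille
#' resistors. Junction contractions enter as prescribed sources at ordinary
#' nodes; a perinuclear sheet enters through its total source, split among the
#' equal-pressure sheet nodes by the solver.
#'
#' @param solver a `flow_solver`.
#' @param b,bdot per-edge minimum pinch radius (um) and its rate (um/s);
#'   defaults: no pinching.
#' @param L per-edge pinch half-length (um; 0 = inactive).
#' @param node_q prescribed sources at original nodes (um^3/s, length N).
#' @param sheet_total total sheet source (um^3/s).
#' @param lambda slip length (um).
#' @param mu viscosity (fluxes are independent of it).
#' @return list of class `flow_solution`: `Q1`, `Q4` (per-edge segment fluxes,
#'   um^3/s, positive i -> j), `q_pinch`, `q_exit` (named by node id),
#'   `q_sheet`, `residual` (max absolute equation residual).
#' @export
solve_flow <- function(solver, b = NULL, bdot = NULL, L = NULL,
                       node_q = NULL, sheet_total = 0, lambda = 0, mu = 1) {
  E <- solver$E; N <- solver$N
  edges <- solver$net$edges
  R <- edges$radius; l <- edges$length
  if (is.null(b)) b <- R
  if (is.null(bdot)) bdot <- numeric(E)
  if (is.null(L)) L <- numeric(E)
  if (is.null(node_q)) node_q <- numeric(N)
  active <- L > 0
  L1 <- (l - 2 * L) / 2
  r1 <- r2 <- numeric(E)
  if (any(active)) {
    rr <- pinch_segment_resistances(L1[active], L1[active], L[active],
                                    R[active], b[active], lambda, mu)
    r1[active] <- rr$r1; r2[active] <- rr$r2
  }
  if (any(!active)) {
    r0 <- hp_resistance(l[!active] / 2, R[!active], lambda, mu)
    r1[!active] <- r0; r2[!active] <- r0
  }
  q_pinch <- numeric(E)
  q_pinch[active] <- -(2 * pi / 3) * bdot[active] * L[active] *
    (R[active] + 2 * b[active])
  # resistance value per halfedge column (he1 = 1..E, he2 = E+1..2E)
  rhe <- c(r1, r2)
  vals <- solver$tconst
  vi <- solver$the > 0L
  vals[vi] <- solver$tsign[vi] * rhe[solver$the[vi]]
  A <- solver$template
  A@x <- vals[solver$perm]
  rhs <- numeric(solver$n_unknown)
  rhs[seq_len(N)] <- node_q
  rhs[N + seq_len(E)] <- q_pinch
  if (solver$M2 > 0) rhs[solver$n_unknown] <- sheet_total
  x <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e)
                  stop("solver-error: singular hydraulic system (",
                       conditionMessage(e), ")"))
  res <- max(abs(A %*% x - rhs))
  list(Q1 = x[seq_len(E)], Q4 = x[E + seq_len(E)],
       q_pinch = q_pinch,
       q_exit = stats::setNames(x[solver$col_exit], solver$exit_ids),
       q_sheet = if (solver$M2 > 0)
         stats::setNames(x[solver$col_sheet], solver$sheet_ids) else numeric(0),
       residual = res)
}

#' One-call assembly and solve
#'
#' Convenience wrapper building a [build_flow_solver()] for `net` and solving
#' one instant; see [solve_flow()] for the arguments and value.
#'
#' @inheritParams solve_flow
#' @inheritParams build_flow_solver
#' @export
assemble_and_solve <- function(net, b = NULL, bdot = NULL, L = NULL,
                               node_q = NULL, sheet_total = 0, lambda = 0,
                               mu = 1, exit_ids = NULL, sheet_ids = NULL) {
  solver <- build_flow_solver(net, exit_ids = exit_ids, sheet_ids = sheet_ids)
  solve_flow(solver, b = b, bdot = bdot, L = L, node_q = node_q,
             sheet_total = sheet_total, lambda = lambda, mu = mu)
}

#' Axial flux profile along a pinching tubule
#'
#' Integrates mass conservation `dQ/dz = -2 pi a da/dt` through the
#' piecewise-linear pinch profile, starting from the entry flux `Q1`:
#' `Q(z)` is constant in the straight segments, varies cubically through the
#' pinch flanks, and satisfies `Q(l) - Q(0) = q`, the pinch source.
#'
#' @param z axial positions (um, in `[0, l]`).
#' @param Q1 entry flux at `z = 0` (um^3/s).
#' @param b,bdot minimum pinch radius (um) and its rate (um/s).
#' @param L pinch half-length (um).
#' @param L1 entry straight length (um).
#' @param l tubule length (um).
#' @param R tubule radius (um).
#' @return flux Q(z, t) (um^3/s) at each `z`.
#' @export
flux_profile <- function(z, Q1, b, bdot, L, L1, l, R) {
  stopifnot(all(z >= -1e-12), all(z <= l + 1e-12))
  if (L <= 0 || bdot == 0) return(rep(Q1, length(z)))
  z0 <- L1 + L
  Qz0 <- Q1 - 2 * pi * bdot * L * (R / 6 + b / 3)
  q <- -2 * pi * bdot * L * (R / 3 + 2 * b / 3)
  out <- numeric(length(z))
  for (k in seq_along(z)) {
    zz <- z[k]
    if (zz <= L1) out[k] <- Q1
    else if (zz <= z0) {
      w <- (zz - L1) / L
      out[k] <- Q1 - 2 * pi * L * bdot * ((b - R) * w^3 / 3 + R * w^2 / 2)
    } else if (zz <= L1 + 2 * L) {
      w <- (zz - z0) / L
      out[k] <- Qz0 - 2 * pi * L * bdot *
        (b * (1 - (1 - w)^3) / 3 + R * (w^2 / 2 - w^3 / 3))
    } else out[k] <- Q1 + q
  }
  out
}

#' Lubrication velocity field in a deforming tubule
#'
#' Long-wavelength axial and radial velocity components at radius `r` inside
#' an axisymmetric tubule of local radius `a`, wall velocity `adot`, wall
#' slope `az` and local flux `Q`. With `lambda = 0` the axial profile is
#' parabolic (Poiseuille) with no-slip at the wall; with slip the profile
#' flattens but the cross-sectional average `Q / (pi a^2)` is unchanged. The
#' radial component enforces incompressibility and the kinematic wall
#' condition.
#'
#' @param a local radius (um).
#' @param adot wall radial velocity (um/s).
#' @param az wall slope da/dz (dimensionless).
#' @param Q local flux (um^3/s).
#' @param r radial position (um, `0 <= r <= a`).
#' @param lambda slip length (um).
#' @return list with axial `u` and radial `v` velocities (um/s).
#' @export
velocity_field <- function(a, adot, az, Q, r, lambda = 0) {
  if (any(r > a)) stop("invalid argument: r must not exceed the local radius")
  rho <- r / a
  g <- lambda / a
  denom <- 1 + 4 * g
  u <- 2 / denom * Q / (pi * a^2) * (1 - rho^2 + 2 * g)
  v <- 1 / denom * adot * rho * (2 - rho^2 + 4 * g) +
    2 / denom * az * Q / (pi * a^2) * rho *
      (1 + 3 * g - rho^2 - g / denom * (4 * g + 2 - rho^2))
  list(u = u, v = v)
}
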