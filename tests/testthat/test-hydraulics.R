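test_that("pinch segment resistances match the quadrature oracle and classical limits", {
  mu <- 1
  # b = R, no slip: classical Hagen-Poiseuille for the full tubule
  rr <- pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, 0.03)
  expect_equal(rr$r1 + rr$r2, 8 * mu * (0.43 + 0.14 + 0.43) / (pi * 0.03^4),
               tolerance = 1e-12)
  # deep pinch vs adaptive quadrature of the lubrication integrand
  rr <- pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, 3e-4)
  expect_equal(rr$r1, oracle_segment_resistance(0.43, 0.07, 0.03, 3e-4),
               tolerance = 1e-8)
  # slip closed form vs quadrature, across moderate and deep pinches
  for (lam in c(0.003, 0.03, 0.3)) for (b in c(0.029, 0.01, 3e-4)) {
    rr <- pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, b, lambda = lam)
    expect_equal(rr$r1,
                 oracle_segment_resistance(0.43, 0.07, 0.03, b, lambda = lam),
                 tolerance = 1e-8)
  }
  # lambda -> 0 recovers the no-slip resistances
  r0 <- pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, 0.01)
  rs <- pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, 0.01, lambda = 1e-12)
  expect_equal(rs$r1, r0$r1, tolerance = 1e-9)
  # monotonicity: r1 strictly increases as b decreases
  bs <- seq(0.03, 3e-4, length.out = 30)
  r1s <- vapply(bs, function(b)
    pinch_segment_resistances(0.43, 0.43, 0.07, 0.03, b)$r1, numeric(1))
  expect_true(all(diff(r1s) > 0))
  expect_error(pinch_segment_resistances(0.4, 0.4, 0.07, 0.03, 0), "invalid")
})

test_that("Kirchhoff solve: homogeneous case, symmetry, and conservation", {
  net <- build_honeycomb(3, 3)
  sol <- assemble_and_solve(net)
  expect_true(all(sol$Q1 == 0) && all(sol$Q4 == 0))
  expect_true(all(sol$q_exit == 0))

  # single tubule between two exit nodes, midpoint pinch: the source splits
  # symmetrically, Q1 = -q/2 and Q4 = +q/2
  one <- single_tubule_net(l = 1)
  b <- 0.015; bdot <- -1.2; L <- 0.07
  sol <- assemble_and_solve(one, b = b, bdot = bdot, L = L)
  q <- -(2 * pi / 3) * bdot * L * (0.03 + 2 * b)
  expect_equal(sol$Q1, -q / 2, tolerance = 1e-12)
  expect_equal(sol$Q4, +q / 2, tolerance = 1e-12)

  # global conservation: exit sources balance pinch sources
  net <- build_honeycomb(4, 4)
  set.seed(2)
  E <- nrow(net$edges); R <- net$edges$radius
  act <- sample(E, 10)
  b <- R; bdot <- numeric(E); L <- numeric(E)
  b[act] <- R[act] * runif(10, 0.1, 0.9)
  bdot[act] <- runif(10, -2, 2)
  L[act] <- 0.07
  sol <- assemble_and_solve(net, b = b, bdot = bdot, L = L)
  expect_lt(abs(sum(sol$q_exit) + sum(sol$q_pinch)),
            1e-10 * max(abs(sol$q_pinch)))
  # K1 residual at every node, from the fluxes themselves
  for (n in net$nodes$id) {
    out_flux <- sum(sol$Q1[net$edges$i == n]) - sum(sol$Q4[net$edges$j == n])
    qn <- if (n %in% names(sol$q_exit)) sol$q_exit[as.character(n)] else 0
    expect_lt(abs(out_flux - qn), 1e-10 * max(abs(sol$Q1)))
  }
  expect_error(assemble_and_solve(single_tubule_net(roles = c("normal", "normal"))),
               "exit")
})

test_that("sparse cycle-basis solve equals the dense nodal-analysis oracle", {
  for (seed in 1:5) {
    net <- oracle_random_network(12 + 3 * seed, seed = seed)
    E <- nrow(net$edges); R <- net$edges$radius
    set.seed(100 + seed)
    n_act <- min(3, E)
    act <- sample(E, n_act)
    b <- R; bdot <- numeric(E); L <- numeric(E)
    b[act] <- R[act] * runif(n_act, 0.05, 0.9)
    bdot[act] <- runif(n_act, -3, 3)
    L[act] <- pmin(0.07, net$edges$length[act] / 4)
    sol <- assemble_and_solve(net, b = b, bdot = bdot, L = L)
    ora <- oracle_dense_flow(net, b = b, bdot = bdot, L = L)
    scale <- max(abs(ora$Q1), abs(ora$Q4))
    expect_lt(max(abs(sol$Q1 - ora$Q1), abs(sol$Q4 - ora$Q4)), 1e-9 * scale)
  }
})

test_that("fluxes are independent of the viscosity", {
  net <- build_honeycomb(3, 3)
  E <- nrow(net$edges); R <- net$edges$radius
  set.seed(7)
  act <- sample(E, 6)
  b <- R; bdot <- numeric(E); L <- numeric(E)
  b[act] <- R[act] * 0.4; bdot[act] <- -1; L[act] <- 0.07
  s1 <- assemble_and_solve(net, b = b, bdot = bdot, L = L, mu = 1)
  s2 <- assemble_and_solve(net, b = b, bdot = bdot, L = L, mu = 10)
  expect_equal(s1$Q1, s2$Q1, tolerance = 1e-12)
  expect_equal(s1$q_exit, s2$q_exit, tolerance = 1e-12)
})

test_that("flux profile integrates mass conservation through the pinch", {
  R <- 0.03; b <- 0.01; bdot <- -1.5; L <- 0.07; L1 <- 0.43; l <- 1
  Q1 <- 0.002
  # bdot = 0: constant flux
  expect_equal(flux_profile(c(0, 0.3, 0.5, 1), Q1, R, 0, L, L1, l, R),
               rep(Q1, 4))
  # endpoint equals Q1 + q (the pinch source)
  q <- -(2 * pi / 3) * bdot * L * (R + 2 * b)
  expect_equal(flux_profile(l, Q1, b, bdot, L, L1, l, R), Q1 + q,
               tolerance = 1e-12)
  # interior values match direct quadrature of 2 pi a da/dt
  a_of <- function(z) {
    dz <- abs(z - (L1 + L))
    if (dz <= L) b + (R - b) * dz / L else R
  }
  adot_of <- function(z) {
    dz <- abs(z - (L1 + L))
    if (dz <= L) bdot * (1 - dz / L) else 0
  }
  for (zz in c(L1 + 0.3 * L, L1 + L, L1 + 1.7 * L)) {
    direct <- Q1 - 2 * pi * stats::integrate(
      function(s) vapply(s, function(x) a_of(x) * adot_of(x), numeric(1)),
      0, zz, rel.tol = 1e-12)$value
    expect_equal(flux_profile(zz, Q1, b, bdot, L, L1, l, R), direct,
                 tolerance = 1e-10)
  }
  # continuity in z
  zs <- seq(0, l, length.out = 400)
  Qs <- flux_profile(zs, Q1, b, bdot, L, L1, l, R)
  max_jump <- 2 * pi * R * abs(bdot) * (l / 399) * 1.5  # max |dQ/dz| * dz
  expect_true(all(abs(diff(Qs)) < max_jump))
})

test_that("velocity field: no-slip wall, centreline speed, incompressibility", {
  R <- 0.03; Q <- 0.002
  vf <- velocity_field(R, 0, 0, Q, R)
  expect_equal(vf$u, 0)
  vf <- velocity_field(R, 0, 0, Q, 0)
  expect_equal(vf$u, 2 * Q / (pi * R^2))
  expect_error(velocity_field(R, 0, 0, Q, 2 * R), "invalid")

  # divergence of (u, v) vanishes inside a pinching tube (finite differences)
  b <- 0.012; bdot <- -1.5; L <- 0.07; L1 <- 0.43; l <- 1; Q1 <- 1e-3
  afun <- function(z) {
    dz <- abs(z - (L1 + L)); if (dz <= L) b + (R - b) * dz / L else R
  }
  adotfun <- function(z) {
    dz <- abs(z - (L1 + L)); if (dz <= L) bdot * (1 - dz / L) else 0
  }
  azfun <- function(z) {
    dz <- z - (L1 + L)
    if (abs(dz) > L) 0 else if (dz < 0) (b - R) / L else (R - b) / L
  }
  for (lam in c(0, 0.03)) {
    set.seed(1)
    for (k in 1:12) {
      z <- runif(1, L1 + 0.05 * L, L1 + 0.95 * L)
      r <- runif(1, 0.1, 0.8) * afun(z)
      h <- 1e-6
      u_at <- function(zz, rr)
        velocity_field(afun(zz), adotfun(zz), azfun(zz),
                       flux_profile(zz, Q1, b, bdot, L, L1, l, R), rr,
                       lambda = lam)
      dudz <- (u_at(z + h, r)$u - u_at(z - h, r)$u) / (2 * h)
      rv <- function(rr) rr * u_at(z, rr)$v
      drv <- (rv(r + h) - rv(r - h)) / (2 * h) / r
      scale <- abs(u_at(z, r)$u) / (2 * L)
      expect_lt(abs(dudz + drv), 1e-6 * max(scale, 1))
    }
  }
})

test_that("slip redistributes the profile but preserves the flux", {
  R <- 0.03; Q <- 0.002
  u0 <- velocity_field(R, 0, 0, Q, 0, lambda = 0)$u
  last <- u0
  for (lam in c(0.003, 0.03, 0.3)) {
    u <- velocity_field(R, 0, 0, Q, 0, lambda = lam)$u
    expect_lt(u, last)  # centreline speed decreases with slip
    last <- u
    # cross-sectional integral of u equals Q regardless of slip
    Qnum <- stats::integrate(function(r)
      velocity_field(R, 0, 0, Q, r, lambda = lam)$u * 2 * pi * r,
      0, R, rel.tol = 1e-10)$value
    expect_equal(Qnum, Q, tolerance = 1e-8)
  }
})
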