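test_that("a particle with no flow and no diffusion does not move", {
  net <- single_tubule_net(l = 1)
  st <- cbind(edge = 1, z = 0.5, y1 = 0.01, y2 = -0.005,
              last_node = 0, depart_time = 0)
  out <- kernel_call(st, 100, 1e-5, D = 0, rp = 0.0025, net,
                     Q1 = 0, Q4 = 0)
  expect_equal(out$state[1, 2:4], c(z = 0.5, y1 = 0.01, y2 = -0.005))
  # R reference step agrees
  expect_equal(step_particle(c(0.5, 0.01, -0.005), 0, 0, 0.03, 0, 1e-5),
               c(0.5, 0.01, -0.005))
})

test_that("deterministic centreline advection moves at twice the mean speed", {
  net <- single_tubule_net(l = 1)
  Q <- 5e-4; R <- 0.03
  st <- cbind(edge = 1, z = 0.2, y1 = 0, y2 = 0,
              last_node = 0, depart_time = 0)
  n <- 200; dt <- 1e-5
  out <- kernel_call(st, n, dt, D = 0, rp = 0.0025, net, Q1 = Q, Q4 = Q)
  expect_equal(out$state[1, 2], 0.2 + 2 * Q / (pi * R^2) * n * dt,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("free axial diffusion recovers MSD = 2 D t", {
  net <- single_tubule_net(l = 1000)
  np <- 3000; D <- 0.6; dt <- 1e-5; n <- 2000
  st <- cbind(edge = rep(1, np), z = 500, y1 = 0, y2 = 0,
              last_node = 0, depart_time = 0)
  set.seed(99)
  out <- kernel_call(st, n, dt, D = D, rp = 0.0025, net, Q1 = 0, Q4 = 0)
  msd <- mean((out$state[, 2] - 500)^2)
  expect_lt(abs(msd - 2 * D * n * dt), 3 * sqrt(2 / np) * 2 * D * n * dt)
})

test_that("node transitions are Peclet-weighted with uniform zero-flow limit", {
  expect_equal(node_transition_probs(c(0, 0, 0), 0.03, 0.6), rep(1 / 3, 3))
  # Pe = (9, -1, -1): weights (10, 0, 0)
  U <- c(9, -1, -1) * 0.6 / 0.03
  expect_equal(node_transition_probs(U, 0.03, 0.6), c(1, 0, 0))
  # Pe = (1, 0.5, -0.5): probabilities (2, 1.5, 0.5) / 4
  U <- c(1, 0.5, -0.5) * 0.6 / 0.03
  expect_equal(node_transition_probs(U, 0.03, 0.6), c(2, 1.5, 0.5) / 4)
  # flow-magnitude deviation from uniform is O(Pe) for typical ER numbers
  pe <- peclet(1.3, 0.03, 0.6)
  pr <- node_transition_probs(c(1.3, -1.3), 0.03, 0.6)
  expect_equal(pr[1] - 0.5, pe / 2, tolerance = 1e-12)

  # kernel sampling frequencies match the analytic probabilities: a 3-arm
  # star with a short edge so nearly every step triggers a node visit
  R <- 0.03; D <- 0.6; l <- 1e-4
  net <- tubular_network(
    data.frame(id = 1:4, x = c(0, l, -l, 0), y = c(0, 0, 0, l),
               role = c("normal", "exit", "exit", "exit")),
    data.frame(i = c(1, 1, 1), j = c(2, 3, 4), length = l, radius = R),
    metadata = list(lengths_overridden = TRUE))
  Pe <- c(1, 0.5, -0.5)
  Q <- Pe * D / R * pi * R^2
  st <- cbind(edge = 1, z = l / 2, y1 = 0, y2 = 0,
              last_node = 0, depart_time = 0)
  set.seed(4)
  # dt small enough that advection cannot bias which node end is reached
  out <- kernel_call(st, 1e5, 1e-7, D = D, rp = 0.0025, net,
                     Q1 = Q, Q4 = Q)
  ev <- as.data.frame(out$res$events)
  from_centre <- ev[ev$from == 1, ]
  counts <- table(factor(from_centre$to, levels = 2:4))
  p_emp <- as.numeric(counts) / sum(counts)
  p_th <- node_transition_probs(Pe * D / R, R, D)
  se <- sqrt(p_th * (1 - p_th) / sum(counts))
  expect_true(all(abs(p_emp - p_th) < 4 * se))
})

test_that("ensembles are reproducible, conserve colour, and stay confined", {
  net <- build_honeycomb(3, 3)
  cfg <- transport_config(t_end = 0.3, n_particles = 40, seed = 21)
  sch <- sample_pinch_schedule(net, pinch_params(), t_end = 0.3, seed = 22)
  t1 <- simulate_ensemble(net, cfg, schedule = sch, colour_split = TRUE)
  t2 <- simulate_ensemble(net, cfg, schedule = sch, colour_split = TRUE)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$colour, t2$colour)
  expect_identical(sum(t1$colour == 1L), 20L)
  expect_identical(sum(t1$colour == 2L), 20L)
  expect_identical(t1$confinement_violations, 0L)
  expect_false(anyNA(t1$x))
})

test_that("diffusivity is recovered from passive trajectories within 5%", {
  net <- single_tubule_net(l = 200)
  cfg <- transport_config(t_end = 2, n_particles = 300, seed = 31,
                          record_flows = FALSE)
  st_traj <- simulate_ensemble(net, cfg)
  # edge lies along x: axial displacements over the 18 ms cadence
  dx <- diff(t(st_traj$x))
  D_hat <- mean(dx^2) / (2 * cfg$record_dt)
  expect_lt(abs(D_hat - cfg$D) / cfg$D, 0.05)
})

test_that("zero-flow speeds match an independent confined-diffusion oracle", {
  R <- 0.03; D <- 0.6; rp <- 0.0025
  net <- single_tubule_net(l = 100)
  cfg <- transport_config(t_end = 0.6, n_particles = 80, seed = 8,
                          record_flows = FALSE)
  traj <- simulate_ensemble(net, cfg)
  v_pkg <- instantaneous_speeds(traj)
  set.seed(9)
  ora <- oracle_confined_walk(80, 1.2e4, 5e-5, D, R, rp, rec_every = 360)
  dz <- diff(t(ora$z)); dy <- diff(t(ora$y1))
  v_ora <- as.numeric(sqrt(dz^2 + dy^2)) / 0.018
  ks <- stats::ks.test(v_pkg, v_ora)
  expect_gt(ks$p.value, 0.001)
  # closed-form check: axially dominated folded-Gaussian mean speed
  m_th <- sqrt(2 * D * 0.018) * sqrt(2 / pi) / 0.018
  expect_lt(abs(mean(v_pkg) - m_th) / m_th, 0.05)
})

test_that("mixing variance is zero for perfectly alternating strip counts", {
  # fabricate a trajectory snapshot with equal blue/red counts in every strip
  net <- build_honeycomb(3, 3)
  xr <- range(net$nodes$x)
  centres <- seq(xr[1], xr[2], length.out = 41)[seq(2, 40, by = 2)]
  fake <- list(times = 0.018,
               x = matrix(rep(centres, 2), ncol = 1),
               colour = rep(1:2, each = 20),
               config = list(record_dt = 0.018))
  v <- mixing_variance(fake, net, n_strips = 20)
  expect_equal(v$var, 0)

  # fully segregated halves: variance computable by direct recount
  n_half <- 30
  xs <- c(rep(xr[1] + 0.01, n_half), rep(xr[2] - 0.01, n_half))
  fake$x <- matrix(xs, ncol = 1)
  fake$colour <- rep(1:2, each = n_half)
  v <- mixing_variance(fake, net, n_strips = 20)
  phi <- c(n_half, rep(0, 18), -n_half)
  expect_equal(v$var, stats::var(phi))
})
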