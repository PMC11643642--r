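#' Transport simulation configuration
#'
#' @param t_end total simulated time (s).
#' @param n_particles number of independent Brownian particles.
#' @param D particle diffusivity (um^2/s; default 0.6, the measured luminal
#'   marker diffusivity).
#' @param dt_bd Brownian-dynamics time step (s; default 1e-5, giving a step
#'   length of about 3.5 nm, roughly R/9 for a 30 nm tubule).
#' @param dt_flow flow update interval (s; default 1e-3, well below the mean
#'   pinch duration of 72.5 ms). Must be a multiple of `dt_bd`.
#' @param record_dt trajectory recording cadence (s; default 0.018, matching
#'   the particle-tracking resolution the instantaneous speeds refer to).
#' @param particle_diameter rigid-sphere particle diameter (um; default 0.005).
#' @param slip wall slip length (um; default 0, no-slip).
#' @param seed optional integer seed controlling every stochastic element.
#' @param record_flows keep the per-interval entry fluxes Q1 (needed for flow
#'   statistics; default TRUE).
#' @param record_visits also return every node visit (for cross-checking the
#'   traversal-event extraction; default FALSE).
#' @return list of class `transport_config`.
#' @export
transport_config <- function(t_end, n_particles, D = 0.6, dt_bd = 1e-5,
                             dt_flow = 1e-3, record_dt = 0.018,
                             particle_diameter = 0.005, slip = 0,
                             seed = NULL, record_flows = TRUE,
                             record_visits = FALSE) {
  stopifnot(t_end > 0, n_particles >= 1, D >= 0, dt_bd > 0, dt_flow >= dt_bd)
  if (abs(dt_flow / dt_bd - round(dt_flow / dt_bd)) > 1e-9)
    stop("dt_flow must be an integer multiple of dt_bd")
  structure(list(t_end = t_end, n_particles = n_particles, D = D,
                 dt_bd = dt_bd, dt_flow = dt_flow, record_dt = record_dt,
                 particle_diameter = particle_diameter, slip = slip,
                 seed = seed, record_flows = record_flows,
                 record_visits = record_visits),
            class = "transport_config")
}

# node incidence in CSR form with orientation (+1 when the node is the i-end)
node_incidence <- function(net) {
  N <- nrow(net$nodes)
  inc <- vector("list", N)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$i[e]; j <- net$edges$j[e]
    inc[[i]] <- rbind(inc[[i]], c(e - 1L, +1L))
    inc[[j]] <- rbind(inc[[j]], c(e - 1L, -1L))
  }
  counts <- vapply(inc, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  ptr <- c(0L, cumsum(counts))
  m <- do.call(rbind, inc[counts > 0])
  list(ptr = as.integer(ptr), edge = as.integer(m[, 1]),
       orient = as.integer(m[, 2]))
}

# uniform initial placement over the network volume (edges weighted by
# length; radius uniform over the cross-section disc)
init_particles <- function(net, n, rp, colour_split = FALSE) {
  E <- nrow(net$edges)
  if (colour_split) {
    ii <- match(net$edges$i, net$nodes$id); jj <- match(net$edges$j, net$nodes$id)
    mx <- (net$nodes$x[ii] + net$nodes$x[jj]) / 2
    xmid <- stats::median(mx)
    left <- which(mx <= xmid); right <- which(mx > xmid)
    n_half <- n %/% 2
    pick <- c(sample(left, n_half, replace = TRUE,
                     prob = net$edges$length[left]),
              sample(right, n - n_half, replace = TRUE,
                     prob = net$edges$length[right]))
    colour <- c(rep(1L, n_half), rep(2L, n - n_half))
  } else {
    pick <- sample(E, n, replace = TRUE, prob = net$edges$length)
    colour <- rep(0L, n)
  }
  l <- net$edges$length[pick]
  R <- net$edges$radius[pick]
  z <- stats::runif(n) * l
  rr <- pmax(R - rp, 0) * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  state <- cbind(edge = pick, z = z, y1 = rr * cos(th), y2 = rr * sin(th),
                 last_node = 0, depart_time = 0)
  list(state = state, colour = colour)
}

# map schedule events to flow intervals: list of event-row indices per step
events_by_step <- function(t0, t1, n_steps, dt_flow) {
  if (!length(t0)) return(rep(list(integer(0)), n_steps))
  s0 <- pmax(1L, floor(t0 / dt_flow) + 1L)
  s1 <- pmin(n_steps, ceiling(t1 / dt_flow))
  keep <- s1 >= s0
  idx <- rep(which(keep), times = pmax(0L, s1[keep] - s0[keep] + 1L))
  stp <- unlist(lapply(which(keep), function(k) s0[k]:s1[k]), use.names = FALSE)
  out <- split(idx, factor(stp, levels = seq_len(n_steps)))
  unname(out)
}

#' Simulate an ensemble of Brownian particles in an active network
#'
#' The central simulation loop. Time is discretised into flow-update
#' intervals of length `dt_flow`; at each interval the quasi-steady Kirchhoff
#' system is solved for the instantaneous segment fluxes (evaluated at the
#' interval midpoint), and the particles are advanced through the frozen flow
#' with Brownian-dynamics substeps of length `dt_bd` (first-order Euler
#' advection plus isotropic Gaussian noise, specular wall reflection,
#' Peclet-weighted tubule choice at nodes). Particles are independent: no
#' interparticle hydrodynamic or steric interactions.
#'
#' @param net a `tubular_network`.
#' @param config a [transport_config()].
#' @param schedule optional [sample_pinch_schedule()] output (tubule pinches).
#' @param junction_schedule optional [sample_junction_schedule()] output.
#' @param sheet optional perinuclear sheet forcing: list with `V_sheet` (um^3),
#'   `T_half` (s) and `t0` (event start, s); the network must carry sheet
#'   nodes.
#' @param colour_split seed two particle colours, one per half of the network
#'   (for the mixing experiment).
#' @return object of class `particle_trajectories`: recorded positions
#'   (`times`, `x`, `y` matrices of n_particles x n_snapshots), traversal
#'   `events` data.frame (`particle`, `from`, `to`, `edge`, `t_depart`,
#'   `t_arrive`), `colour`, optional `flow_record` (Q1 per interval), `net`,
#'   `config`.
#' @export
simulate_ensemble <- function(net, config, schedule = NULL,
                              junction_schedule = NULL, sheet = NULL,
                              colour_split = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  E <- nrow(net$edges); N <- nrow(net$nodes)
  R <- net$edges$radius; l <- net$edges$length
  rp <- config$particle_diameter / 2
  if (config$D > 0 && any(sqrt(2 * config$D * config$dt_bd) > R / 3))
    warning("Brownian step exceeds R/3; confinement may be under-resolved")
  n_steps <- ceiling(config$t_end / config$dt_flow)
  n_sub <- round(config$dt_flow / config$dt_bd)
  rec_every <- round(config$record_dt / config$dt_bd)
  n_rec <- floor(n_steps * n_sub / rec_every)

  active_any <- (!is.null(schedule) && nrow(schedule) > 0) ||
    (!is.null(junction_schedule) && nrow(junction_schedule) > 0) ||
    !is.null(sheet)
  solver <- if (active_any) build_flow_solver(net) else NULL

  pstep <- if (!is.null(schedule) && nrow(schedule) > 0)
    events_by_step(schedule$t0, schedule$t0 + 2 * schedule$T_half,
                   n_steps, config$dt_flow) else NULL
  jstep <- if (!is.null(junction_schedule) && nrow(junction_schedule) > 0)
    events_by_step(junction_schedule$t0,
                   junction_schedule$t0 + 2 * junction_schedule$T_half,
                   n_steps, config$dt_flow) else NULL

  ip <- init_particles(net, config$n_particles, rp, colour_split)
  state <- ip$state

  ii <- match(net$edges$i, net$nodes$id); jj <- match(net$edges$j, net$nodes$id)
  ex1 <- net$nodes$x[ii]; ey1 <- net$nodes$y[ii]
  eax <- (net$nodes$x[jj] - ex1) / l; eay <- (net$nodes$y[jj] - ey1) / l
  inc <- node_incidence(net)

  rec_x <- matrix(NA_real_, config$n_particles, n_rec)
  rec_y <- matrix(NA_real_, config$n_particles, n_rec)
  flow_record <- if (config$record_flows && active_any)
    matrix(0, n_steps, E) else NULL
  events <- vector("list", n_steps)
  visits <- if (config$record_visits) vector("list", n_steps) else NULL
  zeroE <- numeric(E)
  confinement_violations <- 0L

  for (s in seq_len(n_steps)) {
    t_mid <- (s - 0.5) * config$dt_flow
    b <- R; bdot <- zeroE; L <- zeroE; L1 <- l / 2
    node_q <- NULL; sheet_total <- 0
    any_src <- FALSE
    if (!is.null(pstep) && length(pstep[[s]])) {
      evs <- schedule[pstep[[s]], ]
      tt <- t_mid - evs$t0
      ok <- tt >= 0 & tt <= 2 * evs$T_half
      if (any(ok)) {
        evs <- evs[ok, ]; tt <- tt[ok]
        e <- evs$edge
        b[e] <- pinch_b_vec(tt, evs$T_half, R[e], evs$b0)
        bdot[e] <- pinch_bdot_vec(tt, evs$T_half, R[e], evs$b0)
        L[e] <- evs$L
        L1[e] <- (l[e] - 2 * evs$L) / 2
        any_src <- TRUE
      }
    }
    if (!is.null(jstep) && length(jstep[[s]])) {
      evs <- junction_schedule[jstep[[s]], ]
      tt <- t_mid - evs$t0
      ok <- tt >= 0 & tt <= 2 * evs$T_half
      if (any(ok)) {
        evs <- evs[ok, ]; tt <- tt[ok]
        node_q <- numeric(N)
        q <- evs$dV * pi / (2 * evs$T_half) * sin(pi * tt / evs$T_half)
        for (k in seq_along(q)) node_q[evs$node[k]] <- node_q[evs$node[k]] + q[k]
        any_src <- TRUE
      }
    }
    if (!is.null(sheet)) {
      tt <- t_mid - (sheet$t0 %||% 0)
      if (tt >= 0 && tt <= 2 * sheet$T_half) {
        sheet_total <- sheet_source(sheet$V_sheet, sheet$T_half, tt)
        any_src <- TRUE
      }
    }
    if (any_src) {
      sol <- solve_flow(solver, b = b, bdot = bdot, L = L, node_q = node_q,
                        sheet_total = sheet_total, lambda = config$slip)
      Q1 <- sol$Q1; Q4 <- sol$Q4
    } else {
      Q1 <- zeroE; Q4 <- zeroE
    }
    if (!is.null(flow_record)) flow_record[s, ] <- Q1
    res <- advance_particles(state, n_sub, config$dt_bd,
                             (s - 1) * config$dt_flow, config$D, rp,
                             config$slip, net$edges$i, net$edges$j, l, R,
                             ex1, ey1, eax, eay, Q1, Q4, b, bdot, L, L1,
                             inc$ptr, inc$edge, inc$orient,
                             rec_x, rec_y, rec_every,
                             (s - 1L) * n_sub, config$record_visits, TRUE)
    if (nrow(res$events)) events[[s]] <- res$events
    if (config$record_visits && nrow(res$visits)) visits[[s]] <- res$visits
    confinement_violations <- confinement_violations +
      res$confinement_violations
  }

  ev <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  ev <- if (is.null(ev))
    data.frame(particle = integer(0), from = integer(0), to = integer(0),
               t_depart = numeric(0), t_arrive = numeric(0))
  else as.data.frame(ev)
  ekey <- stats::setNames(seq_len(E),
                          paste(pmin(net$edges$i, net$edges$j),
                                pmax(net$edges$i, net$edges$j)))
  ev$edge <- as.integer(ekey[paste(pmin(ev$from, ev$to),
                                   pmax(ev$from, ev$to))])
  structure(list(times = seq_len(n_rec) * config$record_dt,
                 x = rec_x, y = rec_y, events = ev, colour = ip$colour,
                 flow_record = flow_record, net = net, config = config,
                 visits = if (config$record_visits)
                   as.data.frame(do.call(rbind,
                     visits[!vapply(visits, is.null, logical(1))])) else NULL,
                 confinement_violations = confinement_violations),
            class = "particle_trajectories")
}

# vectorised forms of the kinematic laws (T_half, b0 per event)
pinch_b_vec <- function(t, T_half, R, b0) {
  (R + b0) / 2 + (R - b0) * cos(pi * t / T_half) / 2
}
pinch_bdot_vec <- function(t, T_half, R, b0) {
  -pi * (R - b0) / (2 * T_half) * sin(pi * t / T_half)
}

#' @method print particle_trajectories
#' @export
print.particle_trajectories <- function(x, ...) {
  cat(sprintf(
    "particle_trajectories: %d particles, %.3g s, %d snapshots, %d traversal events\n",
    nrow(x$x), x$config$t_end, ncol(x$x), nrow(x$events)))
  invisible(x)
}

#' One Brownian-dynamics step (reference implementation)
#'
#' Single-particle update in a straight tubule of radius `a`: explicit Euler
#' advection by the local flow `(u, v)` plus isotropic Gaussian displacements
#' of variance `2 D dt` per axis, with specular wall reflection. This is the
#' scalar reference for the compiled ensemble kernel.
#'
#' @param pos numeric `c(z, y1, y2)` (um).
#' @param u,v local axial and radial flow velocities (um/s).
#' @param a local tubule radius (um).
#' @param D diffusivity (um^2/s).
#' @param dt time step (s).
#' @param rp particle radius (um).
#' @return updated `c(z, y1, y2)`.
#' @export
step_particle <- function(pos, u, v, a, D, dt, rp = 0.0025) {
  z <- pos[1]; y1 <- pos[2]; y2 <- pos[3]
  r <- sqrt(y1^2 + y2^2)
  sig <- sqrt(2 * D * dt)
  z <- z + u * dt + sig * stats::rnorm(1)
  if (r > 0) {
    y1 <- y1 + v * y1 / r * dt
    y2 <- y2 + v * y2 / r * dt
  }
  y1 <- y1 + sig * stats::rnorm(1)
  y2 <- y2 + sig * stats::rnorm(1)
  aeff <- a - rp
  r <- sqrt(y1^2 + y2^2)
  if (aeff <= 0) {
    y1 <- 0; y2 <- 0
  } else if (r > aeff) {
    rr <- r; it <- 0
    while (rr > aeff && it < 10) { rr <- abs(2 * aeff - rr); it <- it + 1 }
    if (rr > aeff) rr <- 0
    sc <- if (r > 0) rr / r else 0
    y1 <- y1 * sc; y2 <- y2 * sc
  }
  c(z, y1, y2)
}

#' Peclet-weighted node transition probabilities
#'
#' A particle at a junction enters incident tubule `i` with probability
#' proportional to `max(Pe_i + 1, 0)`, where `Pe_i = U_i R / D` and `U_i` is
#' the cross-sectionally averaged flow speed at the node-side end of tubule
#' `i`, positive out of the node. With no flow the choice is uniform; at
#' large Peclet it is proportional to the outgoing flow speeds.
#'
#' @param U mean outflow speeds (um/s, positive away from the node).
#' @param R tubule radius (um).
#' @param D diffusivity (um^2/s).
#' @return vector of probabilities summing to 1.
#' @export
node_transition_probs <- function(U, R, D) {
  w <- pmax(U * R / D + 1, 0)
  if (sum(w) <= 0) rep(1 / length(U), length(U)) else w / sum(w)
}

#' Two-colour mixing experiment
#'
#' Seeds two particle colours uniformly, one per half of the network (split at
#' the median edge-midpoint x-coordinate), simulates transport, and tracks the
#' homogenisation measure `Var(phi(t)) = Var(nb - nr)` over `n_strips`
#' equal-width vertical strips: the variance over strips of the difference
#' between blue and red particle counts. Zero variance is perfect
#' homogeneity.
#'
#' @param net a `tubular_network` (typically a honeycomb).
#' @param config a [transport_config()].
#' @param schedule optional pinch schedule (NULL = pure diffusion).
#' @param n_strips number of vertical strips (default 20).
#' @return data.frame `time`, `var` (class `mixing_result`), with the
#'   trajectories attached as attribute `trajectories`.
#' @export
mixing_experiment <- function(net, config, schedule = NULL, n_strips = 20) {
  traj <- simulate_ensemble(net, config, schedule = schedule,
                            colour_split = TRUE)
  v <- mixing_variance(traj, net, n_strips)
  attr(v, "trajectories") <- traj
  class(v) <- c("mixing_result", "data.frame")
  v
}

#' Strip-count mixing variance of recorded trajectories
#'
#' @param traj a `particle_trajectories` object with two colours.
#' @param net the network (strip extent from node coordinates).
#' @param n_strips number of strips.
#' @return data.frame with `time` and `var`.
#' @export
mixing_variance <- function(traj, net, n_strips = 20) {
  brk <- seq(min(net$nodes$x), max(net$nodes$x), length.out = n_strips + 1)
  blue <- traj$colour == 1L; red <- traj$colour == 2L
  out <- vapply(seq_along(traj$times), function(k) {
    xs <- traj$x[, k]
    sb <- findInterval(xs[blue], brk, rightmost.closed = TRUE,
                       all.inside = TRUE)
    sr <- findInterval(xs[red], brk, rightmost.closed = TRUE,
                       all.inside = TRUE)
    nb <- tabulate(sb, n_strips); nr <- tabulate(sr, n_strips)
    stats::var(nb - nr)
  }, numeric(1))
  data.frame(time = traj$times, var = out)
}
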