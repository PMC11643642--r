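#' Instantaneous particle speeds
#'
#' Finite-difference speed magnitudes in the global frame,
#' `V_n = |X(t_{n+1}) - X(t_n)| / dt`, sampled at the tracking cadence
#' (default 18 ms). The recording cadence of the trajectories must divide
#' `dt`.
#'
#' @param traj a `particle_trajectories` object.
#' @param dt sampling interval (s; default 0.018).
#' @return numeric vector of speeds (um/s), pooled over particles.
#' @export
instantaneous_speeds <- function(traj, dt = 0.018) {
  rec <- traj$config$record_dt
  k <- dt / rec
  if (abs(k - round(k)) > 1e-9)
    stop("recording cadence does not divide dt")
  k <- round(k)
  cols <- seq(1, ncol(traj$x), by = k)
  if (length(cols) < 2) return(numeric(0))
  dx <- traj$x[, cols[-1], drop = FALSE] - traj$x[, cols[-length(cols)], drop = FALSE]
  dy <- traj$y[, cols[-1], drop = FALSE] - traj$y[, cols[-length(cols)], drop = FALSE]
  as.numeric(sqrt(dx^2 + dy^2) / dt)
}

#' Edge traversal events from node-visit annotations
#'
#' A particle traverses edge `(i, j)` when it travels from node `i` to node
#' `j` (or back) without visiting either node in between; the traversal time
#' is the time between the arrival at the target node and the most recent
#' departure from the origin node, and the traversal speed is the edge length
#' divided by that time. Because node residence is instantaneous, every visit
#' is also a departure, so consecutive distinct node visits delimit exactly
#' one traversal and repeated visits to the same node refresh the departure
#' time.
#'
#' @param visits data.frame with columns `particle`, `time`, `node`, ordered
#'   in time within each particle.
#' @param net a `tubular_network` (for edge lookup and lengths).
#' @return data.frame `particle`, `from`, `to`, `edge`, `t_depart`,
#'   `t_arrive`, `speed` (um/s).
#' @export
edge_traversal_events <- function(visits, net) {
  ekey <- stats::setNames(seq_len(nrow(net$edges)),
                          paste(pmin(net$edges$i, net$edges$j),
                                pmax(net$edges$i, net$edges$j)))
  out <- list()
  for (p in unique(visits$particle)) {
    v <- visits[visits$particle == p, ]
    v <- v[order(v$time), ]
    last_node <- NA_integer_; depart <- NA_real_
    for (k in seq_len(nrow(v))) {
      m <- v$node[k]; t <- v$time[k]
      if (!is.na(last_node) && m != last_node) {
        out[[length(out) + 1L]] <- data.frame(
          particle = p, from = last_node, to = m,
          t_depart = depart, t_arrive = t)
      }
      last_node <- m; depart <- t
    }
  }
  ev <- if (length(out)) do.call(rbind, out)
  else data.frame(particle = integer(0), from = integer(0), to = integer(0),
                  t_depart = numeric(0), t_arrive = numeric(0))
  ev$edge <- as.integer(ekey[paste(pmin(ev$from, ev$to),
                                   pmax(ev$from, ev$to))])
  ev$speed <- net$edges$length[ev$edge] / (ev$t_arrive - ev$t_depart)
  ev
}

#' Traversal events of a simulated ensemble
#'
#' Returns the traversal events extracted online during the simulation, with
#' the traversal speed (edge length / traversal time) attached.
#'
#' @param traj a `particle_trajectories` object.
#' @return data.frame as in [edge_traversal_events()].
#' @export
traversal_events <- function(traj) {
  ev <- traj$events
  ev$speed <- traj$net$edges$length[ev$edge] / (ev$t_arrive - ev$t_depart)
  ev
}

#' Average edge traversal speeds
#'
#' Per-edge mean of the traversal speeds over all traversal events of that
#' edge; the distribution over edges of these means is the headline transport
#' observable.
#'
#' @param events output of [traversal_events()] or
#'   [edge_traversal_events()].
#' @param net the network.
#' @return data.frame `edge`, `n_events`, `mean_speed` (um/s), one row per
#'   edge with at least one traversal.
#' @export
average_edge_traversal_speeds <- function(events, net) {
  if (!nrow(events))
    return(data.frame(edge = integer(0), n_events = integer(0),
                      mean_speed = numeric(0)))
  sp <- split(events$speed, events$edge)
  data.frame(edge = as.integer(names(sp)),
             n_events = vapply(sp, length, integer(1)),
             mean_speed = vapply(sp, mean, numeric(1)),
             row.names = NULL)
}

#' Fit a speed distribution
#'
#' Maximum-likelihood fit of a log-normal or normal family to (average edge
#' traversal) speeds, reporting the fitted parameters, the fitted mean and the
#' raw sample mean.
#'
#' @param x speed samples (um/s); all positive for the log-normal family.
#' @param family `"lognormal"` or `"normal"`.
#' @return list with `family`, `estimate`, `fitted_mean`, `sample_mean`,
#'   `degenerate` (TRUE when the sample is essentially constant).
#' @export
fit_speed_distribution <- function(x, family = c("lognormal", "normal")) {
  family <- match.arg(family)
  if (length(x) < 10) stop("need at least 10 samples")
  if (family == "lognormal" && any(x <= 0))
    stop("invalid argument: log-normal fit requires positive samples")
  if (stats::sd(x) < 1e-12 * max(abs(mean(x)), 1)) {
    return(list(family = family,
                estimate = if (family == "lognormal")
                  c(meanlog = log(mean(x)), sdlog = 0)
                else c(mean = mean(x), sd = 0),
                fitted_mean = mean(x), sample_mean = mean(x),
                degenerate = TRUE))
  }
  fit <- fitdistrplus::fitdist(x, if (family == "lognormal") "lnorm" else "norm")
  est <- fit$estimate
  fm <- if (family == "lognormal") exp(est["meanlog"] + est["sdlog"]^2 / 2)
  else est["mean"]
  list(family = family, estimate = est, fitted_mean = unname(fm),
       sample_mean = mean(x), degenerate = FALSE)
}

#' Flow statistics from recorded flux snapshots
#'
#' Mean flow speed (time- and edge-average of `|Q| / (pi R^2)`, the magnitude
#' of the cross-sectionally averaged axial velocity at the edge entry) and the
#' per-edge frequency of flow-direction alternation (sign changes of the entry
#' flux per second, averaged over edges).
#'
#' @param flow_record matrix of entry fluxes Q1 (intervals x edges), e.g.
#'   `traj$flow_record`.
#' @param R tubule radius (um), scalar or per edge.
#' @param dt_flow interval length (s).
#' @return list `mean_speed` (um/s), `alternation_frequency` (1/s).
#' @export
flow_statistics <- function(flow_record, R, dt_flow) {
  speeds <- sweep(abs(flow_record), 2, pi * rep_len(R, ncol(flow_record))^2, "/")
  total_t <- nrow(flow_record) * dt_flow
  nflips <- apply(flow_record, 2, function(q) {
    s <- sign(q); s <- s[s != 0]
    if (length(s) < 2) 0L else sum(diff(s) != 0)
  })
  list(mean_speed = mean(speeds),
       alternation_frequency = mean(nflips / total_t))
}

#' Spatial profile of edge speeds
#'
#' Bins edges by the x-coordinate of their midpoints and averages a per-edge
#' speed within each bin, projecting the transport field onto one dimension
#' (used to contrast the sharp decay away from a contracting sheet with the
#' flat junction-driven profile).
#'
#' @param edge_speeds data.frame with `edge` and `mean_speed` (e.g. from
#'   [average_edge_traversal_speeds()]).
#' @param net the network.
#' @param n_bins number of x bins.
#' @return data.frame `x` (bin centre), `speed` (NA where a bin holds no
#'   edge).
#' @export
spatial_speed_profile <- function(edge_speeds, net, n_bins = 10) {
  ii <- match(net$edges$i, net$nodes$id); jj <- match(net$edges$j, net$nodes$id)
  mx <- (net$nodes$x[ii] + net$nodes$x[jj]) / 2
  brk <- seq(min(mx), max(mx), length.out = n_bins + 1)
  centre <- (brk[-1] + brk[-length(brk)]) / 2
  bin <- findInterval(mx[edge_speeds$edge], brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
  sp <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    sel <- bin == k
    if (any(sel)) sp[k] <- mean(edge_speeds$mean_speed[sel])
  }
  data.frame(x = centre, speed = sp)
}
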