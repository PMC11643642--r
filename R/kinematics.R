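#' Stochastic pinch parameter distributions
#'
#' The measured pinch kinematics: the pinch duration 2T is exponential with
#' rate log(10)/0.167 per second (mean 0.0725 s), the wait between successive
#' pinches on a site is exponential with rate log(10)/0.851 per second (mean
#' 0.370 s), and the pinch length 2L is uniform with mean 0.14 um and
#' standard deviation 0.040 um (support mean +/- sqrt(3) * sd, i.e.
#' [0.0707, 0.2093] um). Rate multipliers alpha (faster events: durations and
#' waits scaled by 1/alpha) and beta (more frequent events: waits scaled by
#' 1/beta) rescale the time laws.
#'
#' @param alpha duration speed-up factor (>= 1 in the named experiments;
#'   any positive value is accepted). Durations 2T are scaled by `1/alpha`.
#' @param beta frequency factor; waits are scaled by `1/(alpha * beta)` when
#'   both are given so that `alpha` alone "fast-forwards" the whole process.
#'   With the conventions used here, `alpha` divides both 2T and Twait (the
#'   fast-forward experiments) and `beta` additionally divides the wait.
#' @param duration_rate,wait_rate exponential rates (1/s) for 2T and Twait.
#' @param length_mean,length_sd mean and sd (um) of the uniform 2L law.
#' @param b0_fraction minimum pinch radius as a fraction of the tubule radius.
#' @return a list of class `pinch_params`.
#' @export
pinch_params <- function(alpha = 1, beta = 1,
                         duration_rate = log(10) / 0.167,
                         wait_rate = log(10) / 0.851,
                         length_mean = 0.14, length_sd = 0.040,
                         b0_fraction = 0.01) {
  stopifnot(alpha > 0, beta > 0, duration_rate > 0, wait_rate > 0,
            length_mean - sqrt(3) * length_sd > 0)
  structure(list(alpha = alpha, beta = beta,
                 duration_rate = duration_rate, wait_rate = wait_rate,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_mean - sqrt(3) * length_sd,
                 length_max = length_mean + sqrt(3) * length_sd,
                 b0_fraction = b0_fraction),
            class = "pinch_params")
}

# raw draws from the three stochastic laws (before any clamping)
draw_durations <- function(n, params) {
  stats::rexp(n, rate = params$duration_rate) / params$alpha
}
draw_waits <- function(n, params) {
  stats::rexp(n, rate = params$wait_rate) / (params$alpha * params$beta)
}
draw_lengths <- function(n, params) {
  stats::runif(n, params$length_min, params$length_max)
}

#' Sample a stochastic pinch schedule
#'
#' Places one pinch site at the midpoint of every edge and generates, per
#' site, an independent alternating renewal process of pinch events (duration
#' 2T) and waits (Twait) covering `[0, t_end]`. Each site starts in a wait
#' whose remaining duration is a fresh exponential draw (the process is
#' memoryless, so this is the stationary start). The pinch half-length L is
#' resampled per event; events whose full length 2L exceeds the hosting edge
#' are clamped to the edge length (with `length_policy = "full"` every event
#' spans the whole tubule, the "maximally long pinches" configuration).
#'
#' @param net a `tubular_network`.
#' @param params a [pinch_params()] object.
#' @param t_end schedule horizon in seconds.
#' @param seed optional integer seed.
#' @param length_policy `"sampled"` (default) or `"full"`.
#' @return a data.frame of class `pinch_schedule` with one row per event:
#'   `edge` (edge index), `t0` (event start, s), `T_half` (half-duration T, s),
#'   `L` (half-length, um), `b0` (minimum radius, um), `z0` (axial centre, um).
#' @export
sample_pinch_schedule <- function(net, params = pinch_params(), t_end,
                                  seed = NULL, length_policy = c("sampled", "full")) {
  length_policy <- match.arg(length_policy)
  stopifnot(t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  E <- nrow(net$edges)
  out <- vector("list", E)
  for (e in seq_len(E)) {
    l <- net$edges$length[e]
    R <- net$edges$radius[e]
    t <- 0
    t0 <- numeric(0); Th <- numeric(0); Lh <- numeric(0)
    repeat {
      t <- t + draw_waits(1, params)
      if (t >= t_end) break
      dur <- draw_durations(1, params)
      len2 <- if (length_policy == "full") l else min(draw_lengths(1, params), l)
      t0 <- c(t0, t); Th <- c(Th, dur / 2); Lh <- c(Lh, len2 / 2)
      t <- t + dur
    }
    if (length(t0))
      out[[e]] <- data.frame(edge = e, t0 = t0, T_half = Th, L = Lh,
                             b0 = params$b0_fraction * R, z0 = l / 2)
  }
  sched <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sched))
    sched <- data.frame(edge = integer(0), t0 = numeric(0), T_half = numeric(0),
                        L = numeric(0), b0 = numeric(0), z0 = numeric(0))
  attr(sched, "params") <- params
  attr(sched, "t_end") <- t_end
  class(sched) <- c("pinch_schedule", "data.frame")
  sched
}

#' Minimum pinch radius over time
#'
#' The sinusoidal kinematic law for the radius at the centre of a pinch:
#' `b(t) = (R + b0)/2 + (R - b0) * cos(pi * t / T) / 2` for `t` in `[0, 2T]`
#' (contraction over `[0, T]`, relaxation over `[T, 2T]`); `b = R` outside
#' the event. `pinch_bdot` is its time derivative, which vanishes at the event
#' boundaries so the volume source is continuous.
#'
#' @param t time since the event started (s).
#' @param T_half half-duration T of the event (s).
#' @param R tubule radius (um).
#' @param b0 minimum pinch radius (um).
#' @return radius (um) or its rate of change (um/s).
#' @export
pinch_b <- function(t, T_half, R, b0) {
  inside <- t >= 0 & t <= 2 * T_half
  out <- rep(R, length(t))
  out[inside] <- (R + b0) / 2 + (R - b0) * cos(pi * t[inside] / T_half) / 2
  out
}

#' @rdname pinch_b
#' @export
pinch_bdot <- function(t, T_half, R, b0) {
  inside <- t >= 0 & t <= 2 * T_half
  out <- numeric(length(t))
  out[inside] <- -pi * (R - b0) / (2 * T_half) * sin(pi * t[inside] / T_half)
  out
}

#' Instantaneous pinch radius profile a(z, t)
#'
#' Piecewise-linear radius of a pinching tubule: `a = b(t) + (R - b(t)) *
#' |z - z0| / L` within the pinch region `|z - z0| <= L`, and `R` outside it
#' (and at all times outside the event).
#'
#' @param site one row of a [sample_pinch_schedule()] data.frame (or any list
#'   with `t0`, `T_half`, `L`, `b0`, `z0`).
#' @param z axial position along the edge (um).
#' @param t absolute time (s).
#' @param R tubule radius (um).
#' @return radius a(z, t) in um.
#' @export
pinch_radius <- function(site, z, t, R) {
  b <- pinch_b(t - site$t0, site$T_half, R, site$b0)
  dz <- abs(z - site$z0)
  ifelse(dz <= site$L, b + (R - b) * dz / site$L, R)
}

#' Instantaneous volume source of a pinch
#'
#' The net flux mismatch across a pinch acts as a point source at the pinch
#' site: `q = -(2 pi / 3) * bdot * L * (R + 2 b)` (um^3/s), positive while the
#' tubule contracts (bdot < 0) and negative while it relaxes; its integral over
#' a completed contraction + relaxation cycle is zero.
#'
#' @inheritParams pinch_radius
#' @return volumetric source q in um^3/s.
#' @export
pinch_source <- function(site, t, R) {
  tt <- t - site$t0
  b <- pinch_b(tt, site$T_half, R, site$b0)
  bd <- pinch_bdot(tt, site$T_half, R, site$b0)
  -(2 * pi / 3) * bd * site$L * (R + 2 * b)
}

#' Volume source of a contracting tubular junction
#'
#' A junction event of duration 2T expels a volume `f * dV` during the
#' contraction `[0, T]` and takes the same volume back during the relaxation
#' `[T, 2T]`: `q(t) = f * dV * (pi / (2 T)) * sin(pi t / T)`, which is positive
#' on `[0, T]`, negative on `[T, 2T]`, and integrates to `f * dV` over the
#' contraction and to zero over the full event.
#'
#' @param dV junction volume expelled per contraction (um^3).
#' @param T_half half-duration T of the event (s).
#' @param t time since the event started (s); zero outside `[0, 2T]`.
#' @param f fraction of the junction volume expelled (0 < f <= 1).
#' @return source q in um^3/s.
#' @export
junction_source <- function(dV, T_half, t, f = 1) {
  inside <- t >= 0 & t <= 2 * T_half
  out <- numeric(length(t))
  out[inside] <- f * dV * pi / (2 * T_half) * sin(pi * t[inside] / T_half)
  out
}

#' Total volume source of a contracting sheet reservoir
#'
#' A sheet contraction + relaxation lasting 2T produces the total source
#' `S(t) = V_sheet * pi * sin(pi t / T) / (2 T)`; its integral over the
#' contraction equals `V_sheet`.
#'
#' @param V_sheet sheet volume expelled per contraction (um^3).
#' @param T_half half-duration T (s).
#' @param t time since the event started (s); zero outside `[0, 2T]`.
#' @return total source in um^3/s (to be distributed over the sheet nodes by
#'   the hydraulic solver).
#' @export
sheet_source <- function(V_sheet, T_half, t) {
  inside <- t >= 0 & t <= 2 * T_half
  out <- numeric(length(t))
  out[inside] <- V_sheet * pi * sin(pi * t[inside] / T_half) / (2 * T_half)
  out
}

#' Sample junction volumes
#'
#' Truncated-normal rejection sampling of the per-junction expelled volume:
#' normal with mean 0.0045 um^3 and sd 0.0021 um^3, rejecting draws outside
#' the measured range [0.0020, 0.0081] um^3.
#'
#' @param n number of draws.
#' @param seed optional integer seed.
#' @param mean,sd normal parameters (um^3).
#' @param vmin,vmax truncation bounds (um^3).
#' @return numeric vector of volumes in um^3.
#' @export
sample_junction_volumes <- function(n, seed = NULL, mean = 0.0045, sd = 0.0021,
                                    vmin = 0.0020, vmax = 0.0081) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= vmin & x <= vmax])
  }
  out[seq_len(n)]
}

#' Sample a junction (node contraction) schedule
#'
#' Per-node alternating renewal process of contraction + relaxation events
#' (each of total duration 2T, with the relaxation mirroring the contraction
#' through the sinusoidal source) separated by waits. Durations are
#' exponential with the tubule-pinch rate scaled by `1/alpha`; waits with the
#' tubule-pinch wait rate scaled by `1/beta`. Each node keeps a fixed volume
#' `dV` across its events.
#'
#' @param node_ids integer node ids that actively contract.
#' @param volumes per-node expelled volumes (um^3), recycled to the number of
#'   nodes; typically from [sample_junction_volumes()].
#' @param t_end horizon (s).
#' @param alpha,beta rate multipliers (durations / waits scaled by 1/alpha,
#'   1/beta respectively).
#' @param f fraction of the volume expelled per contraction.
#' @param seed optional integer seed.
#' @return data.frame of class `junction_schedule`: `node`, `t0`, `T_half`,
#'   `dV` (already multiplied by `f`).
#' @export
sample_junction_schedule <- function(node_ids, volumes, t_end,
                                     alpha = 1, beta = 1, f = 1, seed = NULL) {
  stopifnot(t_end > 0, f > 0, f <= 1)
  if (!is.null(seed)) set.seed(seed)
  params <- pinch_params()  # base rates; alpha/beta applied explicitly below
  volumes <- rep_len(volumes, length(node_ids))
  out <- vector("list", length(node_ids))
  for (k in seq_along(node_ids)) {
    t <- 0
    t0 <- numeric(0); Th <- numeric(0)
    repeat {
      t <- t + stats::rexp(1, rate = params$wait_rate) / beta
      if (t >= t_end) break
      dur <- stats::rexp(1, rate = params$duration_rate) / alpha
      t0 <- c(t0, t); Th <- c(Th, dur / 2)
      t <- t + dur
    }
    if (length(t0))
      out[[k]] <- data.frame(node = node_ids[k], t0 = t0, T_half = Th,
                             dV = f * volumes[k])
  }
  sched <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(sched))
    sched <- data.frame(node = integer(0), t0 = numeric(0),
                        T_half = numeric(0), dV = numeric(0))
  class(sched) <- c("junction_schedule", "data.frame")
  sched
}
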