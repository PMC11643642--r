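#' Physical constants for the closed-form estimates
#'
#' @param temperature room temperature (K; default 300).
#' @param kc_kBT bending rigidity in units of kBT (default 50; the Gaussian
#'   rigidity is taken of the same magnitude).
#' @param water_viscosity dynamic viscosity of water (Pa s).
#' @param luminal_viscosity_factor luminal fluid viscosity relative to water
#'   (default 10).
#' @param atp_energy energy released by hydrolysis of one ATP (J; default
#'   1e-19).
#' @return list of class `physical_constants` with `kBT`, `kc` (J), `mu`
#'   (Pa s) and `atp_energy`.
#' @export
physical_constants <- function(temperature = 300, kc_kBT = 50,
                               water_viscosity = 1e-3,
                               luminal_viscosity_factor = 10,
                               atp_energy = 1e-19) {
  stopifnot(temperature > 0, kc_kBT > 0, water_viscosity > 0,
            luminal_viscosity_factor > 0, atp_energy > 0)
  kB <- 1.380649e-23
  list(kBT = kB * temperature, kc = kc_kBT * kB * temperature,
       mu = water_viscosity * luminal_viscosity_factor,
       atp_energy = atp_energy)
}

#' Axial displacement produced by a single pinch
#'
#' A particle riding the centreline ahead of a pinch whose flow all escapes
#' through one end is advected, over one contraction, by
#' `dz = (8 L / 3) (1 - b0 / (2 R) - b0^2 / (2 R^2))`, independent of the
#' time course of the contraction; the bound `dz <= 8 L / 3` is attained for
#' a complete closure (`b0 = 0`).
#'
#' @param L pinch half-length (um).
#' @param b0 minimum pinch radius (um; `0 <= b0 <= R`).
#' @param R tubule radius (um).
#' @return displacement in um.
#' @export
single_pinch_displacement <- function(L, b0, R) {
  if (any(b0 > R)) stop("invalid argument: b0 must not exceed R")
  if (any(b0 < 0) || any(L < 0) || any(R <= 0)) stop("invalid argument")
  (8 * L / 3) * (1 - b0 / (2 * R) - b0^2 / (2 * R^2))
}

#' Net displacement of the optimal two-pinch sequence
#'
#' Two pinch sites in series can escape the reciprocity of a single pinch by
#' the four-stroke sequence close-1, close-2, open-1, open-2; the strokes
#' displace a downstream particle by +4L/3, +8L/3, 0 and -4L/3, for a net
#' displacement of 8L/3, equal to the single-pinch upper bound. A reciprocal
#' sequence (close-1 then open-1) yields zero net displacement.
#'
#' @param L pinch half-length (um).
#' @return list with `strokes` (the four displacements), `partial_sums` and
#'   `net` (um).
#' @export
two_pinch_optimal_displacement <- function(L) {
  stopifnot(L > 0)
  strokes <- c(close1 = 4 * L / 3, close2 = 8 * L / 3,
               open1 = 0, open2 = -4 * L / 3)
  list(strokes = strokes, partial_sums = cumsum(strokes),
       net = sum(strokes))
}

#' Peclet number
#'
#' `Pe = U R / D`: the ratio of advective to diffusive transport rates across
#' a tubule of radius `R`.
#'
#' @param U flow speed (um/s).
#' @param R tubule radius (um).
#' @param D diffusivity (um^2/s).
#' @return dimensionless Peclet number.
#' @export
peclet <- function(U, R, D) {
  stopifnot(R > 0, D > 0)
  U * R / D
}

#' Reynolds number
#'
#' `Re = U R / nu` with SI inputs; luminal ER flows have `Re ~ 1e-7`, firmly
#' in the Stokes regime.
#'
#' @param U flow speed (m/s).
#' @param R tubule radius (m).
#' @param nu kinematic viscosity (m^2/s).
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(U, R, nu) {
  stopifnot(R > 0, nu > 0)
  U * R / nu
}

#' Membrane bending energy and force of a tubule pinch
#'
#' Order-of-magnitude estimate of the Helfrich bending-energy difference
#' between the pinched and relaxed tubule, dominated by the high mean
#' curvature near the narrowest section: `dE ~ kc L / sqrt(b0 R)`, and the
#' corresponding force `F ~ dE / R`. With the default rigidity (50 kBT),
#' `L = 70 nm`, `b0 = 10 nm`, `R = 30 nm` this gives `dE ~ 8e-19 J` and
#' `F ~ 30 pN`, comparable to a few molecular motors.
#'
#' @param L pinch half-length (um).
#' @param b0 minimum pinch radius (um).
#' @param R tubule radius (um).
#' @param constants a [physical_constants()] list.
#' @return list with `energy` (J) and `force` (N).
#' @export
pinch_energy_and_force <- function(L = 0.07, b0 = 0.01, R = 0.03,
                                   constants = physical_constants()) {
  stopifnot(L > 0, b0 > 0, R > 0)
  Lm <- L * 1e-6; b0m <- b0 * 1e-6; Rm <- R * 1e-6
  dE <- constants$kc * Lm / sqrt(b0m * Rm)
  list(energy = dE, force = dE / Rm)
}

#' Geometry of an idealised contracting peripheral sheet
#'
#' Two parallel circular membranes of radius `Rs` separated by `2 Dh`,
#' contracting to paraboloids; the relaxed volume `2 pi Rs^2 Dh` is consistent
#' with the measured mean sheet volume (0.12 um^3 at the defaults).
#'
#' @param Rs sheet disc radius (um; default 0.8).
#' @param Dh sheet half-thickness (um; default 0.03).
#' @param T_half contraction duration T (s; default 0.5).
#' @param Vs sheet volume (um^3; default 0.12).
#' @param l representative tubule length (um).
#' @param R tubule radius (um).
#' @return list of class `sheet_geometry`.
#' @export
sheet_geometry <- function(Rs = 0.8, Dh = 0.03, T_half = 0.5, Vs = 0.12,
                           l = 1, R = 0.03) {
  stopifnot(Rs > 0, Dh > 0, T_half > 0, Vs > 0, l > 0, R > 0)
  vol <- 2 * pi * Rs^2 * Dh
  if (abs(vol - Vs) > 0.1 * Vs)
    warning(sprintf(
      "sheet volume 2 pi Rs^2 Dh = %.3g um^3 deviates from Vs = %.3g by > 10%%",
      vol, Vs))
  structure(list(Rs = Rs, Dh = Dh, T_half = T_half, Vs = Vs, l = l, R = R),
            class = "sheet_geometry")
}

#' Work of one peripheral-sheet contraction and its ATP cost
#'
#' Hydrodynamic work done by a contracting peripheral sheet against the
#' luminal fluid, split into the lubrication dissipation inside the sheet,
#' `W_inside = 9 pi mu Rs^4 / (Dh T)`, and the dissipation in the branching
#' tubular network outside, `W_outside = mu Vs^2 l / (pi R^4 T)` (the
#' geometric series over generations of three-fold branching tubules, with
#' the flux scale `Q ~ Vs / 2T`). The total, divided by the ATP hydrolysis
#' energy, is of the order of 1000 ATP per contraction.
#'
#' @param geom a [sheet_geometry()].
#' @param constants a [physical_constants()] (supplies the luminal viscosity).
#' @return list with `W_inside` (J), `W_outside` (J), `atp` (count).
#' @export
sheet_contraction_work <- function(geom = sheet_geometry(),
                                   constants = physical_constants()) {
  mu <- constants$mu
  Rs <- geom$Rs * 1e-6; Dh <- geom$Dh * 1e-6; Tc <- geom$T_half
  Vs <- geom$Vs * 1e-18; l <- geom$l * 1e-6; R <- geom$R * 1e-6
  W_in <- 9 * pi * mu * Rs^4 / (Dh * Tc)
  W_out <- mu * Vs^2 * l / (pi * R^4 * Tc)
  list(W_inside = W_in, W_outside = W_out,
       atp = (W_in + W_out) / constants$atp_energy)
}

#' Dissipation of a branching tubule cascade
#'
#' Partial sums of the series `sum_i 3^i * 8 mu l (Q / 3^i)^2 / (pi R^4)`,
#' the dissipation in successive generations of three-fold branching tubules
#' carrying a total flux `Q`; the series converges geometrically to
#' `4 mu Q^2 l / (pi R^4)`.
#'
#' @param Q total flux (m^3/s).
#' @param l,R tubule length and radius (m).
#' @param mu viscosity (Pa s).
#' @param n_terms number of generations summed.
#' @return list with `partial` (the n-term sum, W) and `limit` (W).
#' @export
branching_dissipation <- function(Q, l, R, mu, n_terms = 50) {
  i <- seq_len(n_terms)
  partial <- sum(3^i * 8 * mu * l * (Q / 3^i)^2 / (pi * R^4))
  list(partial = partial, limit = 4 * mu * Q^2 * l / (pi * R^4))
}

#' Report of all closed-form estimates
#'
#' Evaluates the package's analytic calculators at their defaults (or
#' overrides): the single-pinch displacement bound, Peclet and Reynolds
#' numbers, pinch bending energy and force, and the peripheral-sheet
#' contraction work and ATP cost.
#'
#' @param L2 full pinch length 2L (um; default 0.14).
#' @param b0 minimum pinch radius for the displacement bound (um; default 0,
#'   the bound-attaining value).
#' @param R tubule radius (um).
#' @param U mean flow speed (um/s) for the Peclet number.
#' @param D diffusivity (um^2/s).
#' @param constants a [physical_constants()].
#' @param geom a [sheet_geometry()].
#' @return named list of estimates.
#' @export
estimate_report <- function(L2 = 0.14, b0 = 0, R = 0.03, U = 1.3, D = 0.6,
                            constants = physical_constants(),
                            geom = sheet_geometry()) {
  if (L2 <= 0 || b0 < 0 || R <= 0 || U < 0 || D <= 0)
    stop("validation error: physical quantities must be positive")
  ef <- pinch_energy_and_force(L = L2 / 2, b0 = 0.01, R = R,
                               constants = constants)
  w <- sheet_contraction_work(geom, constants)
  list(dz_max_um = single_pinch_displacement(L2 / 2, b0, R),
       two_pinch_net_um = two_pinch_optimal_displacement(L2 / 2)$net,
       peclet = peclet(U, R, D),
       reynolds = reynolds(U * 1e-6, R * 1e-6, 1e-6),
       pinch_energy_J = ef$energy,
       pinch_force_pN = ef$force * 1e12,
       W_inside_J = w$W_inside,
       W_outside_J = w$W_outside,
       atp_per_contraction = w$atp)
}
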