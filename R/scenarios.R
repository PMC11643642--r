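#' Scenario configuration for alternative flow-generation mechanisms
#'
#' Describes which contractile elements drive the flow: stochastic tubule
#' pinches (optionally sped up by `alpha` and/or spanning whole tubules),
#' contracting tubular junctions with expelled volume fraction `f` and rate
#' multipliers `(alpha, beta)`, a perinuclear-sheet reservoir acting through
#' equal-pressure sheet nodes, or peripheral sheets represented as node
#' contractions (scenario 1: every node expels `Vk / 6`, rates slowed 2.5x;
#' scenario 2: a random third of nodes each expels `Vk / 2`, rates slowed
#' 5x; `Vk ~ N(0.12, 0.04)` um^3).
#'
#' @param mechanism one of `"diffusion"`, `"tubule-pinch"`, `"junction"`,
#'   `"perinuclear-sheet"`, `"peripheral-sheet-1"`, `"peripheral-sheet-2"`.
#' @param alpha,beta rate multipliers (durations scaled by `1/alpha`, waits
#'   by `1/beta`; for tubule pinches `alpha` fast-forwards both).
#' @param length_policy pinch length `"sampled"` or `"full"` (whole tubule).
#' @param f fraction of the junction volume expelled per contraction.
#' @param V_sheet,sheet_T_half perinuclear sheet volume (um^3) and
#'   half-duration T (s); the default 2T = 5 s, V = 10 um^3.
#' @param sheet_node_ids node ids connected to the perinuclear sheet.
#' @param active_fraction fraction of nodes contracting (peripheral scenario 2
#'   uses 1/3).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(mechanism = c("diffusion", "tubule-pinch",
                                          "junction", "perinuclear-sheet",
                                          "peripheral-sheet-1",
                                          "peripheral-sheet-2"),
                            alpha = 1, beta = 1,
                            length_policy = c("sampled", "full"),
                            f = 1, V_sheet = 10, sheet_T_half = 2.5,
                            sheet_node_ids = NULL, active_fraction = 1) {
  mechanism <- match.arg(mechanism)
  length_policy <- match.arg(length_policy)
  if (alpha <= 0 || beta <= 0 || f < 0 || f > 1)
    stop("config-error: alpha, beta must be positive and f in [0, 1]")
  structure(list(mechanism = mechanism, alpha = alpha, beta = beta,
                 length_policy = length_policy, f = f, V_sheet = V_sheet,
                 sheet_T_half = sheet_T_half, sheet_node_ids = sheet_node_ids,
                 active_fraction = active_fraction),
            class = "scenario_config")
}

#' Configure a perinuclear-sheet scenario
#'
#' Marks the given nodes as sheet nodes (they must currently be exit nodes or
#' normal boundary nodes, and must remain disjoint from the exit set) and
#' returns the network plus a matching `scenario_config`. The hydraulic
#' system then gains one source unknown per sheet node, equal-pressure
#' conditions among them, and the prescribed total sheet source.
#'
#' @param net a `tubular_network`.
#' @param sheet_node_ids node ids connected to the sheet (M2 >= 1).
#' @param V_sheet expelled volume (um^3; default 10).
#' @param T2 full contraction + relaxation duration 2T (s; default 5).
#' @return list with elements `net` (roles updated) and `scenario`.
#' @export
configure_perinuclear <- function(net, sheet_node_ids, V_sheet = 10, T2 = 5) {
  stopifnot(length(sheet_node_ids) >= 1)
  net$nodes$role[net$nodes$id %in% sheet_node_ids] <- "sheet"
  ex <- exit_nodes(net)
  if (length(ex) < 1)
    stop("config-error: at least one exit node must remain")
  if (length(intersect(ex, sheet_node_ids)))
    stop("config-error: sheet nodes overlap exit nodes")
  validate_network(net)
  list(net = net,
       scenario = scenario_config("perinuclear-sheet", V_sheet = V_sheet,
                                  sheet_T_half = T2 / 2,
                                  sheet_node_ids = sheet_node_ids))
}

#' Run a transport scenario end to end
#'
#' Orchestrates schedule generation, the hydraulic solves, the Brownian
#' ensemble and the observables for one mechanism, returning a transport
#' summary.
#'
#' @param net a `tubular_network` (for `"perinuclear-sheet"`, one already
#'   carrying sheet-node roles, e.g. from [configure_perinuclear()]).
#' @param scenario a [scenario_config()].
#' @param config a [transport_config()].
#' @return list of class `transport_summary`: `mean_aets` (mean over edges of
#'   the average edge traversal speeds, um/s), `aets` (per-edge data.frame),
#'   `events`, `flow_stats` (when flows were recorded), `trajectories`,
#'   `scenario`, `config`.
#' @export
run_scenario <- function(net, scenario, config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  schedule <- NULL; jsched <- NULL; sheet <- NULL
  mech <- scenario$mechanism
  if (mech == "tubule-pinch") {
    params <- pinch_params(alpha = scenario$alpha, beta = scenario$beta)
    schedule <- sample_pinch_schedule(net, params, config$t_end,
                                      length_policy = scenario$length_policy)
  } else if (mech == "junction") {
    nodes <- setdiff(net$nodes$id, exit_nodes(net))
    if (!length(nodes)) stop("config-error: no non-exit nodes to contract")
    if (scenario$f > 0) {
      vols <- sample_junction_volumes(length(nodes))
      jsched <- sample_junction_schedule(nodes, vols, config$t_end,
                                         alpha = scenario$alpha,
                                         beta = scenario$beta,
                                         f = scenario$f)
    }
  } else if (mech == "perinuclear-sheet") {
    if (!length(sheet_nodes(net)))
      stop("config-error: perinuclear scenario requires sheet nodes")
    sheet <- list(V_sheet = scenario$V_sheet,
                  T_half = scenario$sheet_T_half, t0 = 0)
  } else if (mech %in% c("peripheral-sheet-1", "peripheral-sheet-2")) {
    nodes <- setdiff(net$nodes$id, exit_nodes(net))
    if (mech == "peripheral-sheet-2") {
      frac <- if (scenario$active_fraction < 1) scenario$active_fraction else 1 / 3
      nodes <- sort(sample(nodes, max(1L, round(frac * length(nodes)))))
      vols <- pmax(stats::rnorm(length(nodes), 0.12, 0.04), 1e-4) / 2
      alpha <- 1 / 5
    } else {
      vols <- pmax(stats::rnorm(length(nodes), 0.12, 0.04), 1e-4) / 6
      alpha <- 1 / 2.5
    }
    jsched <- sample_junction_schedule(nodes, vols, config$t_end,
                                       alpha = alpha, beta = 1, f = 1)
  }
  traj <- simulate_ensemble(net, config, schedule = schedule,
                            junction_schedule = jsched, sheet = sheet)
  ev <- traversal_events(traj)
  aets <- average_edge_traversal_speeds(ev, net)
  fs <- if (!is.null(traj$flow_record))
    flow_statistics(traj$flow_record, net$edges$radius, config$dt_flow)
  else NULL
  structure(list(mean_aets = mean(aets$mean_speed), aets = aets,
                 events = ev, flow_stats = fs, trajectories = traj,
                 scenario = scenario, config = config),
            class = "transport_summary")
}

#' @method print transport_summary
#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf(
    "transport_summary [%s]: mean average edge traversal speed %.3g um/s (%d edges, %d events)\n",
    x$scenario$mechanism, x$mean_aets, nrow(x$aets), nrow(x$events)))
  if (!is.null(x$flow_stats))
    cat(sprintf("  mean flow speed %.3g um/s, alternation %.3g /s\n",
                x$flow_stats$mean_speed, x$flow_stats$alternation_frequency))
  invisible(x)
}

#' Sweep junction contraction rates
#'
#' Runs the junction mechanism over a grid of `(alpha, beta)` rate multipliers
#' with shared seeds per cell (common random numbers), returning the mean
#' average edge traversal speed per cell.
#'
#' @param net a `tubular_network`.
#' @param alphas,betas grids of rate multipliers.
#' @param f expelled volume fraction.
#' @param config a [transport_config()]; its seed is combined with each cell.
#' @param seeds one or more integer seeds per cell.
#' @return long-format data.frame `alpha`, `beta`, `seed`, `mean_speed`.
#' @export
junction_sweep <- function(net, alphas, betas, f = 1, config, seeds = 1L) {
  out <- list()
  for (a in alphas) for (b in betas) for (s in seeds) {
    cfg <- config
    cfg$seed <- s
    res <- run_scenario(net, scenario_config("junction", alpha = a, beta = b,
                                             f = f), cfg)
    out[[length(out) + 1L]] <- data.frame(alpha = a, beta = b, seed = s,
                                          mean_speed = res$mean_aets)
  }
  do.call(rbind, out)
}
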