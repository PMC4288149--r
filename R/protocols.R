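# Reconstitution protocols: the experiment matrix of model variants
# (naive dLk = -1.75 nucleosomes, twist-storing dLk = -1.0, the
# increased-affinity variant, isotropic nanoparticles), placement modes,
# nucleosome densities and topoisomerase interventions, expressed as
# timed stage schedules for bd_run().

#' Build a reconstitution protocol schedule
#'
#' The full-scale reference conditions are 100 cores on 22.1 kbp of DNA
#' (high density; low density doubles the DNA for the same cores), run for
#' 0.3 ms of mapped time with a hierarchical switch-on: only the central
#' (H3.H4-tetramer) sites attract until `t_switch_ms`, then the full
#' octamer. A topo-II intervention makes DNA-DNA repulsion finite
#' (soft-core) during `[0.1, 0.2]` ms so thermal motion can pass strands;
#' a topo-I intervention instead scales the twist stiffness to near zero
#' in the same window so the DNA can locally over- or under-wind at
#' little cost. `scale` shrinks DNA length, core count and all times
#' together for desk-size runs.
#'
#' @param variant `"dLk100"` (twist-storing, the default elsewhere),
#'   `"dLk175"` (no stored twist), `"dLk100_boost"` (stored twist with
#'   `eps_boost` site affinity), `"nanoparticle"`.
#' @param density `"high"` (221 bp repeat) or `"low"` (442 bp repeat).
#' @param placement `"regular"`, `"random"` or `"free-solution"`.
#' @param topo `"none"`, `"topo2"` or `"topo1"`.
#' @param scale linear scale factor on DNA length and core count
#'   (1 = full scale; 0.1 gives 2.21 kbp / 10 cores).
#' @param time_scale scale factor on all stage times (defaults to
#'   `sqrt(scale)`: per-nucleosome wrapping kinetics do not shrink with
#'   DNA length, so desk-scale runs keep proportionally more time than a
#'   linear rescaling would give).
#' @param one_step if TRUE all sites are active from t = 0 (single-step
#'   reconstitution) instead of the hierarchical switch-on.
#' @param duration_ms,t_switch_ms,topo_window_ms override the stage times
#'   (before scaling).
#' @return object of class `protocol_schedule`.
#' @export
make_protocol <- function(variant = c("dLk100", "dLk175", "dLk100_boost",
                                      "nanoparticle"),
                          density = c("high", "low"),
                          placement = c("regular", "random",
                                        "free-solution"),
                          topo = c("none", "topo2", "topo1"),
                          scale = 1, time_scale = sqrt(scale),
                          one_step = FALSE,
                          duration_ms = 0.3, t_switch_ms = 0.05,
                          topo_window_ms = c(0.1, 0.2)) {
  variant <- match.arg(variant)
  density <- match.arg(density)
  placement <- match.arg(placement)
  topo <- match.arg(topo)
  n_bp <- round(22100 * scale * if (density == "low") 2 else 1)
  n_cores <- max(1L, round(100 * scale))
  dur <- duration_ms * time_scale
  tsw <- if (one_step || variant == "nanoparticle") 0 else
    t_switch_ms * time_scale
  win <- topo_window_ms * time_scale
  # stage breakpoints: contiguous, non-overlapping
  brk <- sort(unique(c(0, tsw, if (topo != "none") win, dur)))
  brk <- brk[brk <= dur + 1e-12]
  stages <- data.frame(t_start = brk[-length(brk)], t_end = brk[-1])
  stages$tetramer_only <- stages$t_end <= tsw + 1e-12
  in_win <- topo != "none" & stages$t_start >= win[1] - 1e-12 &
    stages$t_end <= win[2] + 1e-12
  stages$softcore_on <- topo == "topo2" & in_win
  stages$twist_relax_on <- topo == "topo1" & in_win
  stages$eps_mult <- if (variant == "dLk100_boost") NA else 1
  structure(list(variant = variant, density = density,
                 placement = placement, topo = topo, scale = scale,
                 time_scale = time_scale,
                 one_step = one_step, n_bp = n_bp, n_cores = n_cores,
                 duration_ms = dur, stages = stages,
                 inputs = list(duration_ms = duration_ms,
                               t_switch_ms = t_switch_ms,
                               topo_window_ms = topo_window_ms)),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf(
    "<protocol_schedule> %s, %s density, %s placement, topo=%s, scale=%g\n",
    x$variant, x$density, x$placement, x$topo, x$scale))
  cat(sprintf("  %d bp, %d cores, %.4g ms\n", x$n_bp, x$n_cores,
              x$duration_ms))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Validate a protocol schedule
#'
#' Stages must be contiguous, non-overlapping, with non-negative
#' increasing times, and no stage may be simultaneously a soft-core and a
#' twist-relaxation window.
#' @param schedule a `protocol_schedule`.
#' @export
validate_protocol <- function(schedule) {
  st <- schedule$stages
  if (any(st$t_start < 0) || any(st$t_end <= st$t_start))
    stop("schedule validation: stage times must be non-negative and increasing",
         call. = FALSE)
  if (nrow(st) > 1 &&
      any(abs(st$t_start[-1] - st$t_end[-nrow(st)]) > 1e-9))
    stop("schedule validation: stages must be contiguous", call. = FALSE)
  if (any(st$softcore_on & st$twist_relax_on))
    stop("schedule validation: contradictory overlapping topo stages",
         call. = FALSE)
  invisible(TRUE)
}

# force-field parameters implied by a protocol variant
protocol_params <- function(schedule, params = ff_params()) {
  if (schedule$variant == "dLk100_boost") {
    schedule$stages$eps_mult <- params$eps_boost
  }
  list(params = params, stages = schedule$stages)
}

# geometry implied by a protocol variant
protocol_geometry <- function(schedule, params = ff_params()) {
  switch(schedule$variant,
         nanoparticle = core_geometry("nanoparticle",
                                      body_diam = params$core_diam),
         dLk175 = core_geometry("octamer", stored_twist = 0,
                                path_radius = params$path_radius,
                                path_pitch = params$path_pitch,
                                body_diam = params$core_diam),
         core_geometry("octamer", stored_twist = 0.75,
                       path_radius = params$path_radius,
                       path_pitch = params$path_pitch,
                       body_diam = params$core_diam))
}

#' Initial state implied by a protocol
#'
#' Draws the DNA in an equilibrium coil and pre-positions the cores per
#' the protocol's placement mode.
#' @param schedule a `protocol_schedule`.
#' @param seed integer seed.
#' @param params [ff_params()].
#' @export
protocol_initial_state <- function(schedule, seed = 1L,
                                   params = ff_params()) {
  chain <- build_dna_chain(schedule$n_bp, "equilibrium-coil", seed = seed,
                           params = params)
  # centre the coil so the confinement sphere encloses it
  chain$positions <- sweep(chain$positions, 2, colMeans(chain$positions))
  geom <- protocol_geometry(schedule, params)
  stage0 <- if (schedule$variant != "nanoparticle" &&
                isTRUE(schedule$stages$tetramer_only[1]))
    "tetramer" else "octamer"
  mode <- if (schedule$variant == "nanoparticle" &&
              schedule$placement == "regular") "free-solution"
          else schedule$placement
  place_cores(chain, schedule$n_cores, mode, seed = seed + 1,
              geometry = geom, stage = stage0)
}

#' Run a replicated reconstitution experiment
#'
#' Replicas differ only in seed. Returns final states, per-replica
#' trajectories (optional) and a manifest sufficient to re-run
#' byte-identically.
#'
#' @param schedule a [make_protocol()] schedule.
#' @param n_replicas number of replicas (>= 1).
#' @param base_seed integer; replica k uses `base_seed + 1000 * k` streams.
#' @param params [ff_params()].
#' @param map [time_mapping()].
#' @param stride snapshot stride (steps).
#' @param keep_trajectories retain full trajectories (memory-hungry).
#' @param max_beads resource guard (beads): refuse larger systems unless
#'   `override = TRUE`.
#' @param override disable the resource guard.
#' @return object of class `experiment_result`: `states` (final), and
#'   `manifest` (config hash, seeds, stage log, versions).
#' @export
run_experiment <- function(schedule, n_replicas = 1L, base_seed = 1L,
                           params = ff_params(), map = time_mapping(),
                           stride = 5000L, keep_trajectories = FALSE,
                           max_beads = 2000L, override = FALSE) {
  stopifnot(n_replicas >= 1)
  validate_protocol(schedule)
  nb <- round(schedule$n_bp / 7.35)
  if (nb > max_beads && !override)
    stop(sprintf(
      "resource guard: %d beads > budget %d; pass override = TRUE",
      nb, max_beads), call. = FALSE)
  pp <- protocol_params(schedule, params)
  sched <- schedule
  sched$stages <- pp$stages
  if (params$confine_R <= 0) {
    # soft sphere a bit larger than the equilibrium coil
    L <- schedule$n_bp * 0.34
    params$confine_R <- max(40, 1.3 * sqrt(params$lp_target * L / 3))
  }
  states <- vector("list", n_replicas)
  trajs <- if (keep_trajectories) vector("list", n_replicas) else NULL
  seeds <- base_seed + 1000L * seq_len(n_replicas)
  for (k in seq_len(n_replicas)) {
    st0 <- protocol_initial_state(schedule, seed = seeds[k], params = params)
    tr <- bd_run(st0, schedule = sched, params = params, map = map,
                 seed = seeds[k], stride = stride,
                 limit_move = 0.45 * params$sigma_dna)
    states[[k]] <- tr$state
    if (keep_trajectories) trajs[[k]] <- tr
  }
  manifest <- list(
    config_hash = config_hash(list(schedule = schedule[
      c("variant", "density", "placement", "topo", "scale", "one_step",
        "n_bp", "n_cores", "duration_ms")],
      params = unclass(params), dt = map$dt)),
    base_seed = base_seed, replica_seeds = seeds,
    n_replicas = n_replicas,
    package_version = as.character(utils::packageVersion("chromassemble")),
    stages = schedule$stages,
    tau_B_seconds = map$tau_B)
  structure(list(states = states, trajectories = trajs,
                 manifest = manifest, schedule = schedule),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d replica(s) of %s/%s/%s\n",
              x$manifest$n_replicas, x$schedule$variant,
              x$schedule$placement, x$schedule$topo))
  invisible(x)
}
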