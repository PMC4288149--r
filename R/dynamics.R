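# Overdamped Langevin (Brownian) dynamics. First-order Euler-Maruyama for
# bead translations and rotations and for rigid cores; no hydrodynamic
# interactions. Mobilities follow Stokes-Einstein: the DNA bead sets the
# unit of time (tau_B = time to diffuse one bead diameter), cores scale
# with their diameter (1/d for translation, 1/d^3 for rotation).

#' Simulation-to-physical time mapping
#'
#' The Brownian time of a DNA bead, tau_B = sigma^2 / D with
#' D = kBT / (3 pi eta sigma), is about 3.6e-8 s for a 2.5 nm bead in
#' water at 300 K, so 0.3 ms of assembly is roughly 8.4e3 tau_B.
#'
#' @param viscosity solvent viscosity, Pa s.
#' @param temperature K.
#' @param sigma_dna bead diameter, nm.
#' @param dt integration step in tau_B (default 0.002; the stiffest mode,
#'   the per-joint twist, relaxes at ~90/tau_B, so this keeps the Euler
#'   discretization bias on its variance under ~10 percent).
#' @return list of class `time_mapping` with `tau_B` (seconds), `dt`, and
#'   the inputs.
#' @export
time_mapping <- function(viscosity = 1e-3, temperature = 300,
                         sigma_dna = 2.5, dt = 0.002) {
  kT <- KB_J * temperature
  sig_m <- sigma_dna * 1e-9
  D <- kT / (3 * pi * viscosity * sig_m)      # m^2/s
  tau_B <- sig_m^2 / D
  structure(list(viscosity = viscosity, temperature = temperature,
                 sigma_dna = sigma_dna, dt = dt, tau_B = tau_B),
            class = c("time_mapping", "list"))
}

#' Convert mapped milliseconds to Brownian times (and back)
#' @param ms,tau time in milliseconds / Brownian times.
#' @param map a [time_mapping()].
#' @export
ms_to_tau <- function(ms, map = time_mapping()) ms * 1e-3 / map$tau_B

#' @rdname ms_to_tau
#' @export
tau_to_ms <- function(tau, map = time_mapping()) tau * map$tau_B * 1e3

#' Advance a system by one Brownian-dynamics step
#'
#' Mainly useful for tests; production runs use [bd_run()].
#'
#' @param state a [system_state()].
#' @param params [ff_params()].
#' @param map [time_mapping()].
#' @param seed integer seed for the thermal noise stream.
#' @param temperature 1 for ambient, 0 to switch off noise.
#' @inheritParams energy_forces
#' @export
bd_step <- function(state, params = ff_params(), map = time_mapping(),
                    seed = 1L, softcore = FALSE, twist_scale = 1,
                    eps_mult = 1, temperature = 1) {
  run_chunk(state, params, map, nsteps = 1L, stride = 1L, seed = seed,
            softcore = softcore, twist_scale = twist_scale,
            eps_mult = eps_mult, temperature = temperature)$state
}

# internal: one uniform-flag chunk of BD integration. limit_move > 0
# clamps per-step displacements (soft launch for overlapping initial
# conditions); disabled, displacements above 0.5 sigma raise the
# unstable-step error.
run_chunk <- function(state, params, map, nsteps, stride, seed,
                      softcore = FALSE, twist_scale = 1, eps_mult = 1,
                      slit_gap0 = -1, slit_gap1 = -1, temperature = 1,
                      limit_move = -1) {
  a <- state_arrays(state)
  r <- cpp_run(a$pos, a$quat, a$chain, a$circ, a$cpos, a$cquat, a$ckind,
               a$site_loc, a$site_dir, a$active, unclass(params),
               softcore, twist_scale, eps_mult, slit_gap0, slit_gap1,
               map$dt, as.integer(nsteps), as.integer(stride),
               as.double(seed), state$time, temperature, limit_move)
  last <- r$snapshots[[length(r$snapshots)]]
  newstate <- state_update(state, last$pos, last$quat, last$cpos,
                           last$cquat, r$times[length(r$times)])
  list(state = newstate, snapshots = r$snapshots, times = r$times)
}

#' Run Brownian dynamics under a protocol schedule
#'
#' Executes the stages of `schedule` in order, switching binding-site
#' activation (tetramer -> octamer), soft-core strand-passing windows
#' (topo-II) and twist-relaxation windows (topo-I) at their scheduled
#' times. With `schedule = NULL` a single plain stage of `duration_tau`
#' is run. Identical seed + configuration gives an identical trajectory.
#'
#' @param state initial [system_state()].
#' @param schedule a [make_protocol()] schedule or NULL.
#' @param duration_tau run length in tau_B (ignored when a schedule is
#'   given; the schedule's stage boundaries define the run).
#' @param params [ff_params()].
#' @param map [time_mapping()].
#' @param seed integer master seed.
#' @param stride snapshot stride in steps.
#' @param limit_move per-step displacement clamp in nm (negative
#'   disables it; then displacements above 0.5 sigma raise the
#'   unstable-step error).
#' @return object of class `bd_trajectory`: list with `times` (tau_B),
#'   `times_ms`, `snapshots`, the final `state` and the stage log.
#' @export
bd_run <- function(state, schedule = NULL, duration_tau = NULL,
                   params = ff_params(), map = time_mapping(), seed = 1L,
                   stride = 1000L, limit_move = -1) {
  if (is.null(schedule)) {
    if (is.null(duration_tau))
      stop("either a schedule or duration_tau is required", call. = FALSE)
    stages <- data.frame(t_start = 0, t_end = tau_to_ms(duration_tau, map),
                         tetramer_only = FALSE, softcore_on = FALSE,
                         twist_relax_on = FALSE, eps_mult = 1)
  } else {
    validate_protocol(schedule)
    stages <- schedule$stages
  }
  all_snaps <- list(); all_times <- numeric(0)
  stage_log <- list()
  for (k in seq_len(nrow(stages))) {
    sg <- stages[k, ]
    # switch site masks for the stage
    stage_name <- if (isTRUE(sg$tetramer_only)) "tetramer" else "octamer"
    state$cores <- lapply(state$cores, function(cp) {
      if (cp$geometry$kind == "octamer") {
        ab <- attr(cp, "attachment_bead")
        cp <- activate_sites(cp, stage_name)
        attr(cp, "attachment_bead") <- ab
      }
      cp
    })
    nst <- max(1L, round(ms_to_tau(sg$t_end - sg$t_start, map) / map$dt))
    ch <- run_chunk(state, params, map, nsteps = nst, stride = stride,
                    seed = seed + 7919 * k,
                    softcore = isTRUE(sg$softcore_on),
                    twist_scale = if (isTRUE(sg$twist_relax_on)) 0.02 else 1,
                    eps_mult = if (is.null(sg$eps_mult) || is.na(sg$eps_mult))
                      params$eps_boost else sg$eps_mult,
                    limit_move = limit_move)
    state <- ch$state
    keep <- if (k > 1) seq_along(ch$times)[-1] else seq_along(ch$times)
    all_snaps <- c(all_snaps, ch$snapshots[keep])
    all_times <- c(all_times, ch$times[keep])
    stage_log[[k]] <- list(stage = k, t_start_ms = sg$t_start,
                           t_end_ms = sg$t_end, flags = as.list(sg))
  }
  structure(list(times = all_times, times_ms = tau_to_ms(all_times, map),
                 snapshots = all_snaps, state = state,
                 template = state, stage_log = stage_log,
                 map = map),
            class = "bd_trajectory")
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d frames, t = %.1f .. %.1f tau_B (%.4f ms)\n",
              length(x$times), min(x$times), max(x$times),
              max(x$times_ms)))
  invisible(x)
}

#' Reconstruct the system state at a stored trajectory frame
#' @param traj a `bd_trajectory`.
#' @param frame frame index (default: last).
#' @export
traj_state <- function(traj, frame = length(traj$times)) {
  sn <- traj$snapshots[[frame]]
  state_update(traj$template, sn$pos, sn$quat, sn$cpos, sn$cquat,
               traj$times[frame])
}
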