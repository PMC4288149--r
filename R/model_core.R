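# Domain types: DNA chain, core geometry, core particle, system state.
#
# Unit conventions used throughout the package: lengths in nm, energies in
# kBT, simulation time in Brownian times (tau_B) with a mapping to
# milliseconds (see time_mapping()). One DNA bead is 2.5 nm = 7.35 bp, so a
# canonical 147 bp nucleosomal wrap is exactly 20 beads.

#' DNA chain constructor
#'
#' A torsionally rigid bead-and-patch polymer: every bead is a rigid body
#' whose orientation quaternion carries a body frame (e1 = tangent,
#' e2 = minor-groove patch direction, e3 = e1 x e2). The patch is both the
#' protein-binding moiety and the reference ribbon used for twist
#' bookkeeping.
#'
#' @param positions n x 3 matrix of bead centres (nm).
#' @param quat n x 4 matrix of scalar-first unit quaternions (one per bead).
#' @param bp_per_bead base pairs represented by one bead (default 7.35,
#'   i.e. 2.5 nm of B-DNA at 0.34 nm/bp).
#' @param topology `"linear"` or `"circular"`.
#' @return An object of class `dna_chain`.
#' @export
dna_chain <- function(positions, quat = NULL, bp_per_bead = 7.35,
                      topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 2)
  if (is.null(quat)) quat <- frames_from_positions(positions)
  quat <- quat_normalize(as.matrix(quat))
  stopifnot(nrow(quat) == nrow(positions))
  structure(list(positions = positions, quat = quat,
                 bp_per_bead = bp_per_bead, topology = topology),
            class = "dna_chain")
}

#' @export
print.dna_chain <- function(x, ...) {
  cat(sprintf("<dna_chain> %d beads (%.0f bp), %s\n", n_beads(x),
              n_beads(x) * x$bp_per_bead, x$topology))
  invisible(x)
}

#' Number of beads in a chain
#' @param chain a `dna_chain`.
#' @export
n_beads <- function(chain) nrow(chain$positions)

#' Convert between base pairs and beads
#'
#' The bead <-> bp mapping is exact and round-trips: a bead holds
#' `bp_per_bead` base pairs.
#' @param bp,beads quantity to convert.
#' @param bp_per_bead base pairs per bead.
#' @export
bp_to_beads <- function(bp, bp_per_bead = 7.35) bp / bp_per_bead

#' @rdname bp_to_beads
#' @export
beads_to_bp <- function(beads, bp_per_bead = 7.35) beads * bp_per_bead

#' Tangent, patch and normal vectors of a chain
#' @param chain a `dna_chain`.
#' @return list with matrices `tangent`, `patch`, `normal` (n x 3).
#' @export
chain_frames <- function(chain) {
  list(tangent = quat_rotate(chain$quat, c(1, 0, 0)),
       patch   = quat_rotate(chain$quat, c(0, 1, 0)),
       normal  = quat_rotate(chain$quat, c(0, 0, 1)))
}

# Per-bead tangents: normalized average of the adjacent bond vectors
# (single bond at the ends). This is the convention used everywhere.
bead_tangents <- function(positions) {
  n <- nrow(positions)
  b <- diff(positions)
  b <- b / sqrt(rowSums(b^2))
  tang <- rbind(b[1, , drop = FALSE],
                (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]),
                b[nrow(b), , drop = FALSE])
  tang / sqrt(rowSums(tang^2))
}

# Build bead quaternions from positions alone: tangent along the averaged
# bond direction, patch parallel-transported from an arbitrary initial
# normal.
frames_from_positions <- function(positions, patch0 = NULL) {
  n <- nrow(positions)
  tang <- bead_tangents(positions)
  q <- matrix(0, n, 4)
  u <- patch0
  if (is.null(u)) {
    p <- if (abs(tang[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- unit3(p - sum(p * tang[1, ]) * tang[1, ])
  }
  for (i in seq_len(n)) {
    if (i > 1) {
      # parallel transport u across the tangent rotation
      R <- rotation_between(tang[i - 1, ], tang[i, ])
      u <- unit3(as.vector(R %*% u))
      u <- unit3(u - sum(u * tang[i, ]) * tang[i, ])
    }
    e3 <- cross3(tang[i, ], u)
    q[i, ] <- quat_from_matrix(cbind(tang[i, ], u, e3))
  }
  q
}

#' Build a DNA chain
#'
#' `straight` lays the chain along +z with zero bend and zero twist.
#' `equilibrium-coil` draws every joint's bending polar angle and twist
#' angle directly from the Boltzmann distribution implied by the bending
#' and torsional stiffnesses, so the returned chain is an exact
#' equilibrium sample of the discrete worm-like chain (no burn-in needed).
#' Self-avoidance is not imposed at build time (the excluded-volume term
#' acts during dynamics), matching the phantom-chain reference statistics.
#'
#' @param n_bp DNA length in base pairs (>= 2 beads' worth).
#' @param conformation `"equilibrium-coil"` or `"straight"`.
#' @param seed integer seed for the coil draw.
#' @param params force-field parameters, see [ff_params()]; the coil uses
#'   `bend_k` and `twist_k`.
#' @param bp_per_bead base pairs per bead.
#' @param topology `"linear"` or `"circular"` (circular only meaningful for
#'   fixtures built elsewhere; the coil draw returns a linear chain).
#' @return a [dna_chain()].
#' @examples
#' ch <- build_dna_chain(2205, "straight")
#' n_beads(ch)  # 300
#' @export
build_dna_chain <- function(n_bp,
                            conformation = c("equilibrium-coil", "straight"),
                            seed = 1L, params = ff_params(),
                            bp_per_bead = 7.35,
                            topology = "linear") {
  conformation <- match.arg(conformation)
  nb <- round(n_bp / bp_per_bead)
  if (nb < 2) stop("n_bp corresponds to fewer than 2 beads", call. = FALSE)
  sigma <- params$sigma_dna
  if (conformation == "straight") {
    pos <- cbind(0, 0, seq(0, by = sigma, length.out = nb))
    # tangent +z, patch +x
    R <- cbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
    q <- matrix(rep(quat_from_matrix(R), each = nb), ncol = 4)
    return(dna_chain(pos, q, bp_per_bead, topology))
  }
  set.seed(seed)
  # effective bending stiffness: explicit Kratky-Porod term plus the
  # alignment springs' series contribution (see ff_params())
  kb <- params$bend_k + params$align_k / 2
  kt <- params$twist_k
  tang <- matrix(0, nb - 1, 3)
  tang[1, ] <- c(0, 0, 1)
  # Boltzmann draw of cos(theta) for E = kb (1 - cos theta):
  # p(c) ~ exp(kb c), c in [-1, 1]
  u <- stats::runif(nb - 2)
  cth <- 1 + log(u + (1 - u) * exp(-2 * kb)) / kb
  psi <- stats::runif(nb - 2, 0, 2 * pi)
  for (i in 2:(nb - 1)) {
    t0 <- tang[i - 1, ]
    # orthonormal pair perpendicular to t0
    p <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit3(p - sum(p * t0) * t0)
    e2 <- cross3(t0, e1)
    s <- sqrt(max(0, 1 - cth[i - 1]^2))
    tang[i, ] <- cth[i - 1] * t0 +
      s * (cos(psi[i - 1]) * e1 + sin(psi[i - 1]) * e2)
  }
  pos <- rbind(c(0, 0, 0), apply(sigma * tang, 2, cumsum))
  # patch: parallel transport plus a Gaussian twist increment per joint
  tw <- stats::rnorm(nb - 1, 0, 1 / sqrt(kt))
  q <- matrix(0, nb, 4)
  u <- c(1, 0, 0)  # perpendicular to initial tangent +z
  bead_t <- rbind(tang[1, , drop = FALSE], tang,
                  tang[nb - 1, , drop = FALSE])  # crude per-bead tangent
  for (i in seq_len(nb)) {
    ti <- if (i == 1) tang[1, ] else if (i == nb) tang[nb - 1, ] else
      unit3(tang[i - 1, ] + tang[i, ])
    if (i > 1) {
      tprev <- if (i == 2) tang[1, ] else unit3(tang[i - 2, ] + tang[i - 1, ])
      R <- rotation_between(tprev, ti)
      u <- unit3(as.vector(R %*% u))
      # twist increment about the tangent
      w <- tw[i - 1]
      u <- unit3(cos(w) * u + sin(w) * cross3(ti, u))
      u <- unit3(u - sum(u * ti) * ti)
    }
    q[i, ] <- quat_from_matrix(cbind(ti, u, cross3(ti, u)))
  }
  dna_chain(pos, q, bp_per_bead, "linear")
}

# ---------------------------------------------------------------------------

#' Core geometry: histone octamer or isotropic nanoparticle
#'
#' The octamer is a single hard sphere of diameter `body_diam` decorated
#' with `n_sites` binding sites arranged on a left-handed helical path
#' (radius `path_radius`, pitch `path_pitch` nm per turn, `path_turns`
#' turns). Each site stores the target position of a docked DNA bead and
#' the direction its minor-groove patch must face. The site patch registry
#' deposits `stored_twist` turns of DNA twist across the full path (the
#' twist-storing nucleosome model uses +0.75 so that the linking-number
#' change per nucleosome is about -1 rather than -1.75).
#'
#' A nanoparticle has the same body but no site list: it attracts any DNA
#' bead isotropically.
#'
#' @param kind `"octamer"` or `"nanoparticle"`.
#' @param stored_twist turns of twist deposited across the wrap (+0.75 for
#'   the twist-storing model, 0 for the naive model).
#' @param path_turns,path_radius,path_pitch helical path geometry (nm).
#' @param n_sites number of binding sites (one per wrapped bead).
#' @param body_diam hard-core diameter of the protein body (nm).
#' @return object of class `core_geometry`.
#' @export
core_geometry <- function(kind = c("octamer", "nanoparticle"),
                          stored_twist = 0.75, path_turns = 1.75,
                          path_radius = 4.2, path_pitch = 3.0,
                          n_sites = 20L, body_diam = 6.75) {
  kind <- match.arg(kind)
  g <- structure(list(kind = kind, body_radius = body_diam / 2,
                      body_diam = body_diam, path_turns = path_turns,
                      path_radius = path_radius, path_pitch = path_pitch,
                      n_sites = if (kind == "octamer") as.integer(n_sites)
                                else 0L,
                      stored_twist = if (kind == "octamer") stored_twist
                                     else 0,
                      handedness = "left"),
                 class = "core_geometry")
  if (kind == "octamer") {
    fr <- ideal_wrap_frames(g)
    g$site_local_positions <- fr$positions
    g$site_local_patch_dirs <- fr$patch_dirs
  } else {
    g$site_local_positions <- matrix(numeric(0), 0, 3)
    g$site_local_patch_dirs <- matrix(numeric(0), 0, 3)
  }
  g
}

#' @export
print.core_geometry <- function(x, ...) {
  cat(sprintf("<core_geometry> %s, %d sites, %.2f turns, dTw=%+.2f\n",
              x$kind, x$n_sites, x$path_turns, x$stored_twist))
  invisible(x)
}

#' Ideal wrapping frames of the octamer binding path
#'
#' Returns, for each binding site, the body-frame target position of a
#' docked DNA bead, the direction its patch must face, and the local path
#' tangent. Site azimuths decrease monotonically viewed along the +z body
#' axis (left-handed path). Patch directions are built by discrete
#' parallel transport of the initial inward radial direction along the
#' path, plus a uniform extra rotation depositing `stored_twist` turns
#' over the full path, so the twist of the registry (measured with
#' [twist()]) equals `stored_twist` exactly.
#'
#' @param geom an octamer [core_geometry()].
#' @return list with `positions`, `patch_dirs`, `tangents` (n_sites x 3)
#'   and `azimuths` (radians, decreasing).
#' @export
ideal_wrap_frames <- function(geom) {
  if (geom$kind != "octamer")
    stop("ideal_wrap_frames is only defined for octamer geometry",
         call. = FALSE)
  S <- geom$n_sites
  th <- seq(0, -2 * pi * geom$path_turns, length.out = S)
  zz <- seq(0, geom$path_pitch * geom$path_turns, length.out = S)
  zz <- zz - mean(zz)
  P <- cbind(geom$path_radius * cos(th), geom$path_radius * sin(th), zz)
  # bond (joint) tangents along the discrete path
  bt <- diff(P)
  bt <- bt / sqrt(rowSums(bt^2))
  tangents <- bead_tangents(P)
  # Patch registry: per-bead patches perpendicular to the bead tangent,
  # constructed so that the measured per-joint dihedral (projection onto
  # the bond, see twist()) equals the per-joint stored twist exactly.
  U <- matrix(0, S, 3)
  u <- unit3(c(-cos(th[1]), -sin(th[1]), 0))  # inward radial, face the core
  u <- unit3(u - sum(u * tangents[1, ]) * tangents[1, ])
  U[1, ] <- u
  dtw <- 2 * pi * geom$stored_twist / (S - 1)
  for (k in 2:S) {
    b <- bt[k - 1, ]
    a <- unit3(u - sum(u * b) * b)
    # target azimuth about the bond: rotate the projection by dtw
    cc <- cos(dtw) * a + sin(dtw) * cross3(b, a)
    # the unit vector perpendicular to the next bead tangent whose
    # projection onto the bond plane lies along cc
    tn <- tangents[k, ]
    u <- unit3(cc - (sum(cc * tn) / sum(b * tn)) * b)
    U[k, ] <- u
  }
  list(positions = P, patch_dirs = U, tangents = tangents, azimuths = th)
}

#' Centreline of the ideal wrap path with entry/exit legs
#'
#' The analytic wrapped-DNA centreline at arbitrary resolution, extended
#' by straight entry and exit legs that leave tangentially with a small
#' tilt (0.08) away from the wrap along the -z / +z body axis. The tilt
#' separates the crossing entry/exit strands cleanly, which is what gives
#' the canonical wrap its full writhe; the open Gauss integral of this
#' curve with 100 nm legs is about -1.75 for 1.75 left-handed turns.
#'
#' @param geom octamer [core_geometry()] (a mirrored copy gives the
#'   right-handed variant).
#' @param n_per_turn vertices per superhelical turn.
#' @param leg leg length in nm.
#' @param tilt leg tilt off the tangent toward the axis (dimensionless).
#' @param mirror if TRUE, mirror the path (right-handed wrap).
#' @return matrix of vertices tracing leg-in, wrap, leg-out.
#' @export
ideal_wrap_path <- function(geom, n_per_turn = 40, leg = 100, tilt = 0.08,
                            mirror = FALSE) {
  th <- seq(0, -2 * pi * geom$path_turns,
            length.out = max(4L, round(n_per_turn * geom$path_turns)) + 1L)
  zz <- seq(0, geom$path_pitch * geom$path_turns, length.out = length(th))
  zz <- zz - mean(zz)
  H <- cbind(geom$path_radius * cos(th), geom$path_radius * sin(th), zz)
  if (mirror) H[, 2] <- -H[, 2]
  n <- nrow(H)
  t0 <- unit3(H[1, ] - H[2, ])
  t1 <- unit3(H[n, ] - H[n - 1, ])
  d0 <- unit3(t0 + c(0, 0, -tilt))
  d1 <- unit3(t1 + c(0, 0, tilt))
  if (leg <= 0) return(H)
  nseg <- max(4L, round(leg / 2.5))
  s <- seq(leg, leg / nseg, length.out = nseg)
  pre <- H[rep(1, nseg), ] + s * matrix(d0, nseg, 3, byrow = TRUE)
  s <- seq(leg / nseg, leg, length.out = nseg)
  post <- H[rep(n, nseg), ] + s * matrix(d1, nseg, 3, byrow = TRUE)
  rbind(pre, H, post)
}

#' Core particle: a rigid body instance of a core geometry
#'
#' @param geometry a [core_geometry()].
#' @param position 3-vector, nm.
#' @param orientation scalar-first unit quaternion.
#' @param active_sites logical mask of switched-on sites (tetramer stage
#'   activates the central half; octamer stage all of them).
#' @export
core_particle <- function(geometry, position = c(0, 0, 0),
                          orientation = c(1, 0, 0, 0),
                          active_sites = NULL) {
  if (is.null(active_sites))
    active_sites <- rep(TRUE, geometry$n_sites)
  stopifnot(length(active_sites) == geometry$n_sites)
  orientation <- as.numeric(orientation)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(geometry = geometry, position = as.numeric(position),
                 orientation = orientation,
                 active_sites = as.logical(active_sites)),
            class = "core_particle")
}

#' Switch binding sites on by assembly stage
#'
#' The H3.H4 tetramer organizes the central portion of nucleosomal DNA and
#' binds first during salt-dialysis reconstitution; the flanking H2A.H2B
#' dimer contacts complete the octamer later. The tetramer stage activates
#' the central half of the sites, the octamer stage all of them. Repeated
#' application is idempotent.
#'
#' @param core a [core_particle()] with octamer geometry.
#' @param stage `"tetramer"` or `"octamer"`.
#' @export
activate_sites <- function(core, stage = c("tetramer", "octamer")) {
  stage <- match.arg(stage)
  if (core$geometry$kind != "octamer")
    stop("activate_sites: nanoparticle cores have no binding sites",
         call. = FALSE)
  S <- core$geometry$n_sites
  mask <- rep(FALSE, S)
  if (stage == "tetramer") {
    k <- S %/% 4
    mask[(k + 1):(S - k)] <- TRUE  # central half (10 of 20)
  } else {
    mask[] <- TRUE
  }
  core$active_sites <- mask
  core
}

#' System state: chains + cores + clock
#'
#' @param chains a [dna_chain()] or list of them.
#' @param cores list of [core_particle()] (possibly empty).
#' @param box half-open cuboid `c(lx, ly, lz)` in nm, or NULL (unbounded).
#' @param time simulation time in tau_B.
#' @export
system_state <- function(chains, cores = list(), box = NULL, time = 0) {
  if (inherits(chains, "dna_chain")) chains <- list(chains)
  if (inherits(cores, "core_particle")) cores <- list(cores)
  structure(list(chains = chains, cores = cores, box = box, time = time),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  nb <- sum(vapply(x$chains, n_beads, 1L))
  cat(sprintf("<system_state> %d chain(s), %d beads, %d core(s), t=%.1f tau_B\n",
              length(x$chains), nb, length(x$cores), x$time))
  invisible(x)
}

#' Place cores along (or around) a DNA chain
#'
#' `regular` and `random` pre-position cores adjacent to the chain at
#' attachment beads (regular: evenly spaced, emulating a strong positioning
#' sequence such as a 601 array; random: uniform draws with a minimum
#' separation of one full wrap, 147 bp). `free-solution` scatters cores
#' uniformly in the box, as in a dilute reconstitution mix.
#'
#' @param chain a [dna_chain()].
#' @param n_cores number of cores (>= 0).
#' @param mode `"regular"`, `"random"` or `"free-solution"`.
#' @param seed integer seed.
#' @param geometry shared [core_geometry()] for all cores.
#' @param stage initial site activation stage (octamer = all on).
#' @param box simulation box for free-solution mode (defaults to the chain
#'   bounding box plus padding).
#' @return a [system_state()].
#' @export
place_cores <- function(chain, n_cores,
                        mode = c("regular", "random", "free-solution"),
                        seed = 1L, geometry = core_geometry(),
                        stage = "octamer", box = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_cores >= 0)
  nb <- n_beads(chain)
  wrap_beads <- max(geometry$n_sites, 1L)
  if (n_cores == 0)
    return(system_state(chain, list(), box = box))
  set.seed(seed)
  if (mode %in% c("regular", "random")) {
    if (n_cores * wrap_beads > nb)
      stop(sprintf(
        "invalid density: %d cores x %d wrap beads exceed chain length %d",
        n_cores, wrap_beads, nb), call. = FALSE)
    if (mode == "regular") {
      sp <- nb / n_cores
      att <- round(sp / 2 + sp * (seq_len(n_cores) - 1))
    } else {
      att <- integer(0)
      for (tries in 1:2000) {
        cand <- sample.int(nb - wrap_beads, 1) + wrap_beads %/% 2
        if (all(abs(cand - att) >= wrap_beads)) att <- c(att, cand)
        if (length(att) == n_cores) break
      }
      if (length(att) < n_cores)
        stop("invalid density: could not place cores with 147 bp separation",
             call. = FALSE)
      att <- sort(att)
    }
    att <- pmin(pmax(att, 1L), nb)
    fr <- chain_frames(chain)
    cores <- vector("list", n_cores)
    for (k in seq_len(n_cores)) {
      i <- att[k]
      tng <- fr$tangent[i, ]
      # offset perpendicular to the chain, random azimuth
      p <- if (abs(tng[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- unit3(p - sum(p * tng) * tng)
      e2 <- cross3(tng, e1)
      phi <- stats::runif(1, 0, 2 * pi)
      nrm <- cos(phi) * e1 + sin(phi) * e2
      cen <- chain$positions[i, ] + geometry$path_radius * nrm
      qr <- quat_from_rotvec(stats::runif(3, -pi, pi))
      cp <- core_particle(geometry, cen, qr)
      attr(cp, "attachment_bead") <- i
      cores[[k]] <- cp
    }
  } else {
    if (is.null(box)) {
      ext <- apply(chain$positions, 2, function(v) diff(range(v)))
      box <- pmax(ext + 30, 60)
    }
    lo <- apply(chain$positions, 2, min) - 15
    cores <- lapply(seq_len(n_cores), function(k) {
      cen <- lo + stats::runif(3) * box
      core_particle(geometry, cen, quat_from_rotvec(stats::runif(3, -pi, pi)))
    })
  }
  cores <- lapply(cores, function(cp) {
    if (cp$geometry$kind == "octamer") {
      ab <- attr(cp, "attachment_bead")
      cp <- activate_sites(cp, stage)
      attr(cp, "attachment_bead") <- ab
    }
    cp
  })
  system_state(chain, cores, box = box)
}

#' Attachment bead indices recorded at placement (NA when unknown)
#' @param state a [system_state()].
#' @export
attachment_beads <- function(state) {
  vapply(state$cores, function(cp) {
    ab <- attr(cp, "attachment_bead")
    if (is.null(ab)) NA_integer_ else as.integer(ab)
  }, 1L)
}

# --- internal: marshal a system_state into the flat arrays the C++ core
# expects. All octamer cores must share one site geometry.
state_arrays <- function(state) {
  pos <- do.call(rbind, lapply(state$chains, `[[`, "positions"))
  quat <- do.call(rbind, lapply(state$chains, `[[`, "quat"))
  nb <- vapply(state$chains, n_beads, 1L)
  chain_id <- rep(seq_along(state$chains) - 1L, nb)
  circ <- vapply(state$chains, function(ch) ch$topology == "circular", TRUE)
  m <- length(state$cores)
  cpos <- matrix(0, m, 3); cquat <- matrix(0, m, 4)
  ckind <- integer(m)
  geom <- NULL
  for (i in seq_len(m)) {
    cp <- state$cores[[i]]
    cpos[i, ] <- cp$position
    cquat[i, ] <- cp$orientation
    ckind[i] <- if (cp$geometry$kind == "nanoparticle") 1L else 0L
    if (ckind[i] == 0L && is.null(geom)) geom <- cp$geometry
  }
  if (is.null(geom)) {
    site_loc <- matrix(numeric(0), 0, 3)
    site_dir <- matrix(numeric(0), 0, 3)
    S <- 0L
  } else {
    site_loc <- geom$site_local_positions
    site_dir <- geom$site_local_patch_dirs
    S <- geom$n_sites
  }
  active <- matrix(0L, m, S)
  for (i in seq_len(m)) {
    cp <- state$cores[[i]]
    if (cp$geometry$kind == "octamer" && S > 0)
      active[i, ] <- as.integer(cp$active_sites)
  }
  list(pos = pos, quat = quat, chain = as.integer(chain_id),
       circ = as.integer(circ), cpos = cpos, cquat = cquat,
       ckind = ckind, site_loc = site_loc, site_dir = site_dir,
       active = active, n_per_chain = nb)
}

# inverse of state_arrays for positions/orientations (topology unchanged)
state_update <- function(state, pos, quat, cpos, cquat, time = state$time) {
  off <- 0L
  for (i in seq_along(state$chains)) {
    nbi <- n_beads(state$chains[[i]])
    idx <- off + seq_len(nbi)
    state$chains[[i]]$positions <- pos[idx, , drop = FALSE]
    state$chains[[i]]$quat <- quat[idx, , drop = FALSE]
    off <- off + nbi
  }
  for (i in seq_along(state$cores)) {
    state$cores[[i]]$position <- cpos[i, ]
    state$cores[[i]]$orientation <- cquat[i, ]
  }
  state$time <- time
  state
}

#' Validate chain invariants
#'
#' Checks bond-length dispersion (within 20 percent of the rest length),
#' frame orthonormality, and the bead/bp mapping.
#' @param chain a [dna_chain()].
#' @param params [ff_params()].
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_chain <- function(chain, params = ff_params()) {
  d <- diff(chain$positions)
  L <- sqrt(rowSums(d^2))
  if (any(abs(L - params$bond_r0) > 0.2 * params$bond_r0))
    stop("bond lengths outside 20% of rest length", call. = FALSE)
  fr <- chain_frames(chain)
  ortho <- abs(rowSums(fr$tangent * fr$patch))
  nrm <- abs(sqrt(rowSums(fr$tangent^2)) - 1)
  if (any(ortho > 1e-8) || any(nrm > 1e-8))
    stop("frames not orthonormal to 1e-8", call. = FALSE)
  invisible(TRUE)
}
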