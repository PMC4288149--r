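# Analysis battery: wrapping quantification, defect taxonomy, simulated
# micrococcal-nuclease digestion and gel rendering, plane flattening,
# AFM-style fibre statistics, the zig-zag nearest-neighbour metric and
# Welch's t-test for replicate comparisons.

#' Defect-classification thresholds
#'
#' The defect classes are qualitative; these thresholds operationalize
#' them and are reported in output metadata. `correct_lo` is just below
#' the canonical 147 bp wrap; `partial_lo` separates genuinely engaged
#' cores from glancing contacts; `loop_gap` is the sequence separation
#' beyond which two bound segments count as a loop rather than a local
#' registry slip; `proximity_bp` is roughly one nucleosome repeat.
#'
#' @param correct_lo minimum contiguous wrapped bp of a correct
#'   nucleosome.
#' @param partial_lo minimum wrapped bp of a partial nucleosome.
#' @param loop_gap sequence gap (bp) separating loop capture from local
#'   mis-registry.
#' @param proximity_bp along-chain separation (bp) under which two
#'   under-wrapped cores form a dimer cluster.
#' @param protection_pad beads adjacent to a bound run protected from
#'   nuclease digestion.
#' @export
defect_thresholds <- function(correct_lo = 130, partial_lo = 25,
                              loop_gap = 500, proximity_bp = 160,
                              protection_pad = 1L) {
  list(correct_lo = correct_lo, partial_lo = partial_lo,
       loop_gap = loop_gap, proximity_bp = proximity_bp,
       protection_pad = as.integer(protection_pad))
}

# internal: bound beads per core. A bead is associated with a core when
# (a) its best site-contact energy is below -bind_frac * eps_site, or
# (b) it lies within the capture radius of an active site,
# or (c) it sits on the binding shell of the core body (surface-proximal
# association, |r - path_radius| < shell_tol), which is what "DNA
# associated with a core" means for nonspecific contacts (nanoparticles,
# right-handed wraps).
bound_bead_table <- function(state, params = ff_params(), bind_frac = 0.5,
                             dist_frac = 1.0, shell_tol = 0.5) {
  a <- state_arrays(state)
  m <- length(state$cores)
  if (m == 0)
    return(data.frame(bead = integer(0), core = integer(0),
                      site = integer(0), energy = numeric(0)))
  rows <- list()
  sc <- site_contacts(state, params)
  if (nrow(sc)) {
    keep <- sc$energy <= -bind_frac * params$eps_site |
      (sc$dist <= dist_frac * params$site_capture &
         sc$cos_beta > params$site_ang_cos)
    sc <- sc[keep, , drop = FALSE]
    if (nrow(sc)) {
      # best site per (bead, core)
      ord <- order(sc$bead, sc$core, sc$energy)
      sc <- sc[ord, ]
      dup <- duplicated(sc[, c("bead", "core")])
      rows[[1]] <- sc[!dup, c("bead", "core", "site", "energy")]
    }
  }
  # surface-shell association (covers nanoparticles and nonspecific wraps)
  for (ic in seq_len(m)) {
    cp <- state$cores[[ic]]
    d <- sqrt(rowSums((a$pos - matrix(cp$position, nrow(a$pos), 3,
                                      byrow = TRUE))^2))
    if (cp$geometry$kind == "nanoparticle") {
      shell <- 0.5 * (params$core_diam + params$sigma_dna)
      # bound where the isotropic well is at least half depth
      hit <- which(d < shell + params$nano_well_w / 2 & d > shell - 1.5)
    } else {
      shell <- params$path_radius
      hit <- which(abs(d - shell) < shell_tol)
    }
    if (length(hit))
      rows[[length(rows) + 1]] <- data.frame(bead = hit, core = ic,
                                             site = NA_integer_,
                                             energy = NA_real_)
  }
  if (!length(rows))
    return(data.frame(bead = integer(0), core = integer(0),
                      site = integer(0), energy = numeric(0)))
  tb <- do.call(rbind, rows)
  # each bead contacts one core surface: attribute it to the best one
  # (site-bound before shell-only, then deepest energy)
  tb <- tb[order(tb$bead, is.na(tb$site), tb$energy), ]
  tb[!duplicated(tb$bead), ]
}

# map a global bead index to (chain, local index)
bead_chain_of <- function(state, beads) {
  nb <- vapply(state$chains, n_beads, 1L)
  cum <- cumsum(nb)
  ch <- findInterval(beads - 1L, c(0L, cum), rightmost.closed = TRUE)
  local <- beads - c(0L, cum)[ch]
  data.frame(chain = ch, bead = local)
}

#' Wrapping assignment of one core
#'
#' Which DNA beads are associated with the core, how many bp that
#' represents, whether the bound run is contiguous, and the wrapping
#' handedness.
#'
#' @param state a [system_state()].
#' @param core_id core index.
#' @param params [ff_params()].
#' @param bind_frac bead counts as site-bound below `-bind_frac*eps_site`.
#' @return object of class `wrap_assignment`: list with `core`, `chain`,
#'   `bound_beads` (data.frame chain/bead/site/energy), `wrapped_bp`,
#'   `contiguous`, `n_segments`, `handedness`.
#' @export
wrapped_bp <- function(state, core_id, params = ff_params(),
                       bind_frac = 0.5) {
  tb <- bound_bead_table(state, params, bind_frac)
  tb <- tb[tb$core == core_id, , drop = FALSE]
  bpb <- state$chains[[1]]$bp_per_bead
  if (!nrow(tb)) {
    wa <- list(core = core_id, chain = 1L,
               bound_beads = data.frame(chain = integer(0),
                                        bead = integer(0),
                                        site = integer(0),
                                        energy = numeric(0)),
               wrapped_bp = 0, contiguous = TRUE, n_segments = 0L,
               handedness = "indeterminate")
    class(wa) <- "wrap_assignment"
    return(wa)
  }
  loc <- bead_chain_of(state, tb$bead)
  dfr <- data.frame(chain = loc$chain, bead = loc$bead, site = tb$site,
                    energy = tb$energy)
  dfr <- dfr[order(dfr$chain, dfr$bead), ]
  # segments: maximal runs of consecutive bead indices within a chain
  brk <- c(TRUE, diff(dfr$bead) != 1L | diff(dfr$chain) != 0L)
  nseg <- sum(brk)
  wa <- list(core = core_id, chain = dfr$chain[1], bound_beads = dfr,
             wrapped_bp = nrow(dfr) * bpb,
             contiguous = nseg == 1L, n_segments = nseg,
             handedness = "indeterminate")
  class(wa) <- "wrap_assignment"
  wa$handedness <- handedness(wa, state$cores[[core_id]], state)
  wa
}

#' @export
print.wrap_assignment <- function(x, ...) {
  cat(sprintf(
    "<wrap_assignment> core %d: %.1f bp in %d segment(s), %s, %s\n",
    x$core, x$wrapped_bp, x$n_segments,
    if (x$contiguous) "contiguous" else "split", x$handedness))
  invisible(x)
}

#' All wrap assignments of a state
#' @inheritParams wrapped_bp
#' @export
wrap_assignments <- function(state, params = ff_params(), bind_frac = 0.5) {
  lapply(seq_along(state$cores), function(i)
    wrapped_bp(state, i, params, bind_frac))
}

#' Handedness of a wrap
#'
#' Chirality of the bound-bead path about the core: the summed axial
#' circulation (cross products of successive bound-bead displacements
#' projected onto the core body axis) multiplied by the sign of the net
#' advance along that axis. The product is invariant to the traversal
#' direction of the DNA, so a wrap docked on the path in reverse site
#' order still reads correctly. The core's left-handed path gives a
#' negative product. Fewer than 5 bound beads, negligible axial advance,
#' or a net circulation below 30 percent of the accumulated magnitude is
#' indeterminate.
#'
#' @param assignment a `wrap_assignment`.
#' @param core the [core_particle()].
#' @param state the [system_state()] (for bead coordinates).
#' @return `"left"`, `"right"` or `"indeterminate"`.
#' @export
handedness <- function(assignment, core, state) {
  bb <- assignment$bound_beads
  if (nrow(bb) < 5) return("indeterminate")
  ch <- state$chains[[bb$chain[1]]]
  P <- ch$positions[bb$bead[bb$chain == bb$chain[1]], , drop = FALSE]
  axis <- as.vector(quat_rotate(matrix(core$orientation, 1), c(0, 0, 1)))
  d <- diff(P)
  if (nrow(d) < 2) return("indeterminate")
  cr <- cbind(d[-nrow(d), 2] * d[-1, 3] - d[-nrow(d), 3] * d[-1, 2],
              d[-nrow(d), 3] * d[-1, 1] - d[-nrow(d), 1] * d[-1, 3],
              d[-nrow(d), 1] * d[-1, 2] - d[-nrow(d), 2] * d[-1, 1])
  proj <- cr %*% axis
  s <- sum(proj)
  adv <- sum((P[nrow(P), ] - P[1, ]) * axis)
  if (abs(s) < 0.3 * sum(abs(proj)) || sum(abs(proj)) < 1e-9 ||
      abs(adv) < 0.5)
    return("indeterminate")
  if (s * sign(adv) < 0) "left" else "right"
}

#' Turns of DNA wrapped around a core
#'
#' Total unwrapped azimuthal circulation of the bound-bead run about the
#' wrap axis (the smallest-variance direction of the bound beads, i.e.
#' the normal of their best-fit plane), in turns. This is the natural
#' observable for isotropically attractive spheres, where the wrap radius
#' fluctuates and a bp-based conversion would undercount loose gyres.
#'
#' @param state a [system_state()].
#' @param core_id core index.
#' @param params [ff_params()].
#' @return number of turns (>= 0); 0 if fewer than 4 bound beads.
#' @export
wrap_turns <- function(state, core_id, params = ff_params()) {
  wa <- wrapped_bp(state, core_id, params)
  bb <- wa$bound_beads
  if (nrow(bb) < 4) return(0)
  ch <- state$chains[[bb$chain[1]]]
  P <- ch$positions[bb$bead, , drop = FALSE]
  cen <- state$cores[[core_id]]$position
  Q <- sweep(P, 2, cen)
  ax <- eigen(crossprod(scale(Q, scale = FALSE)))$vectors[, 3]
  # project radial directions onto the plane perpendicular to the axis
  R <- Q - outer(as.vector(Q %*% ax), ax)
  nrm <- sqrt(rowSums(R^2))
  ok <- nrm > 1e-6
  R <- R[ok, , drop = FALSE] / nrm[ok]
  if (nrow(R) < 3) return(0)
  ang <- 0
  for (k in 2:nrow(R)) {
    crx <- cross3(R[k - 1, ], R[k, ])
    ang <- ang + atan2(sum(crx * ax), sum(R[k - 1, ] * R[k, ]))
  }
  abs(ang) / (2 * pi)
}

#' Classify assembly defects
#'
#' Assigns every core to exactly one class with the documented precedence:
#' `right_handed` (right circulation with at least half-wrap coverage) >
#' `loop` (two bound segments separated by more than `loop_gap` bp in
#' sequence) > `dimer_cluster` (another core's bound range within
#' `proximity_bp` along the chain, both under-wrapped) > `correct`
#' (contiguous, left-handed, single segment, at least `correct_lo` bp) >
#' `locked_partial` (partial coverage plus at least one bead bound out of
#' path registry) > `partial` (everything else, including bare cores).
#'
#' @param state a [system_state()].
#' @param params [ff_params()].
#' @param thresholds [defect_thresholds()].
#' @return data.frame of class `defect_records` with one row per core:
#'   core, class, wrapped_bp, n_segments, handedness, and the evidence
#'   columns max_gap_bp, nn_core_gap_bp, registry_violation.
#' @export
classify_defects <- function(state, params = ff_params(),
                             thresholds = defect_thresholds()) {
  was <- wrap_assignments(state, params)
  bpb <- state$chains[[1]]$bp_per_bead
  m <- length(was)
  ranges <- lapply(was, function(w)
    if (nrow(w$bound_beads)) range(w$bound_beads$bead) else c(NA, NA))
  out <- vector("list", m)
  for (i in seq_len(m)) {
    w <- was[[i]]
    bb <- w$bound_beads
    gaps <- if (nrow(bb) > 1) diff(sort(bb$bead)) - 1L else integer(0)
    max_gap_bp <- if (length(gaps)) max(gaps) * bpb else 0
    # nearest other core along the chain (centre-to-centre, bp), and
    # whether that neighbour is itself under-wrapped
    nn_gap <- Inf
    nn_under <- FALSE
    if (!is.na(ranges[[i]][1])) {
      for (j in seq_len(m)) {
        if (j == i || is.na(ranges[[j]][1])) next
        gap <- abs(mean(ranges[[i]]) - mean(ranges[[j]])) * bpb
        if (gap < nn_gap) {
          nn_gap <- gap
          nn_under <- was[[j]]$wrapped_bp < thresholds$correct_lo
        }
      }
    }
    # registry violation: the bead -> site map is not monotone, or the
    # bound run splits into nearby segments
    reg_viol <- FALSE
    if (nrow(bb) > 1) {
      st <- bb$site[!is.na(bb$site)]
      if (length(st) > 2) {
        ds <- diff(st)
        reg_viol <- !(all(ds >= 0) || all(ds <= 0))
      }
      if (w$n_segments > 1 && max_gap_bp <= thresholds$loop_gap) {
        # out-of-registry only if a secondary segment is site-bound
        # (shell-only grazes of the adjacent linker do not count)
        seg_id <- cumsum(c(TRUE, diff(bb$bead) != 1L))
        main <- which.max(tabulate(seg_id))
        if (any(!is.na(bb$site[seg_id != main]))) reg_viol <- TRUE
      }
    }
    half_wrap_bp <- 0.5 * 147
    cls <- if (w$handedness == "right" && w$wrapped_bp >= half_wrap_bp) {
      "right_handed"
    } else if (w$n_segments >= 2 && max_gap_bp > thresholds$loop_gap) {
      "loop"
    } else if (is.finite(nn_gap) && nn_gap <= thresholds$proximity_bp &&
               w$wrapped_bp < thresholds$correct_lo && nn_under) {
      "dimer_cluster"
    } else if (w$wrapped_bp >= thresholds$correct_lo && w$contiguous &&
               w$handedness == "left") {
      "correct"
    } else if (w$wrapped_bp >= thresholds$partial_lo && reg_viol) {
      "locked_partial"
    } else {
      "partial"
    }
    out[[i]] <- data.frame(core = i, class = cls, wrapped_bp = w$wrapped_bp,
                           n_segments = w$n_segments,
                           handedness = w$handedness,
                           max_gap_bp = max_gap_bp,
                           nn_core_gap_bp = nn_gap,
                           registry_violation = reg_viol)
  }
  res <- do.call(rbind, out)
  attr(res, "thresholds") <- thresholds
  class(res) <- c("defect_records", "data.frame")
  res
}

#' Per-class counts of a defect classification
#' @param records output of [classify_defects()].
#' @export
defect_counts <- function(records) {
  lv <- c("correct", "partial", "locked_partial", "loop", "right_handed",
          "dimer_cluster")
  table(factor(records$class, levels = lv))
}

# --------------------------------------------------------------- digestion --

#' Simulated micrococcal-nuclease digestion
#'
#' Any bead not protected by binding to a core (same association criterion
#' as [wrapped_bp()], padded by `protection_pad` beads) is cut with
#' probability `1 - exp(-rate)`; a cut severs the bond on the 5' side of
#' the bead. The structure is held fixed during digestion. Fragment
#' lengths are reported in bp and always sum to the total DNA length.
#'
#' @param state a [system_state()].
#' @param rate expected cuts per unprotected bead (>= 0; `Inf` cuts every
#'   unprotected bond).
#' @param seed integer seed.
#' @param params [ff_params()].
#' @param thresholds [defect_thresholds()] (for the protection pad).
#' @return object of class `fragment_set`: list with `fragments_bp`,
#'   `cut_bonds`, `protected` (logical per bead), `seed`.
#' @export
digest <- function(state, rate, seed = 1L, params = ff_params(),
                   thresholds = defect_thresholds()) {
  if (rate < 0) stop("digestion rate must be >= 0", call. = FALSE)
  set.seed(seed)
  ch <- state$chains[[1]]
  nb <- n_beads(ch)
  tb <- bound_bead_table(state, params)
  loc <- if (nrow(tb)) bead_chain_of(state, tb$bead) else
    data.frame(chain = integer(0), bead = integer(0))
  prot <- rep(FALSE, nb)
  prot[loc$bead[loc$chain == 1]] <- TRUE
  pad <- thresholds$protection_pad
  if (pad > 0 && any(prot)) {
    idx <- which(prot)
    for (k in seq_len(pad))
      prot[pmin(pmax(c(idx - k, idx + k), 1L), nb)] <- TRUE
  }
  p_cut <- if (is.infinite(rate)) 1 else 1 - exp(-rate)
  unprot <- which(!prot)
  cut_at <- unprot[stats::runif(length(unprot)) < p_cut]
  cut_bonds <- sort(unique(cut_at[cut_at > 1L]))  # bond (i-1, i)
  bounds <- c(1L, cut_bonds, nb + 1L)
  frag_beads <- diff(bounds)
  structure(list(fragments_bp = frag_beads * ch$bp_per_bead,
                 cut_bonds = cut_bonds, protected = prot, seed = seed),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments, total %.0f bp\n",
              length(x$fragments_bp), sum(x$fragments_bp)))
  invisible(x)
}

#' Render digestion fragments as a simulated electrophoresis gel
#'
#' Migration distance is linear in -log10(length), so shorter fragments
#' run farther; band intensity is proportional to the total bp at that
#' length. Lanes are smoothed with a narrow Gaussian in migration
#' coordinate, plus a reference ladder lane.
#'
#' @param fragments one `fragment_set` or a list of them (one lane each).
#' @param ladder reference lengths in bp for the ladder lane.
#' @param bp_range gel calibration range (bp) mapped onto migration 0..1.
#' @param ngrid points of the lane intensity profile.
#' @param bandwidth Gaussian smoothing bandwidth in migration units.
#' @return object of class `gel`: `migration` grid, `profiles` matrix
#'   (ngrid x lanes), `bands` (list of data.frames with bp, migration,
#'   intensity), `ladder`.
#' @export
gel_render <- function(fragments, ladder = c(147, 368, 589, 810, 1031),
                       bp_range = c(50, 25000), ngrid = 400,
                       bandwidth = 0.012) {
  if (inherits(fragments, "fragment_set")) fragments <- list(fragments)
  stopifnot(length(fragments) >= 1)
  mig <- function(bp) (log10(bp_range[2]) - log10(pmax(bp, bp_range[1]))) /
    (log10(bp_range[2]) - log10(bp_range[1]))
  grid <- seq(0, 1, length.out = ngrid)
  lanes <- lapply(fragments, function(fs) {
    bp <- fs$fragments_bp
    x <- mig(bp)
    prof <- numeric(ngrid)
    for (k in seq_along(bp))
      prof <- prof + bp[k] * stats::dnorm(grid, x[k], bandwidth)
    agg <- stats::aggregate(list(intensity = bp),
                            by = list(bp = round(bp)), FUN = sum)
    list(profile = prof,
         bands = data.frame(bp = agg$bp, migration = mig(agg$bp),
                            intensity = agg$intensity))
  })
  structure(list(migration = grid,
                 profiles = vapply(lanes, `[[`, numeric(ngrid), "profile"),
                 bands = lapply(lanes, `[[`, "bands"),
                 ladder = data.frame(bp = ladder, migration = mig(ladder))),
            class = "gel")
}

#' Band-contrast score of a gel lane
#'
#' Peak-to-trough ratio of the smoothed lane profile (mean over detected
#' peaks); ordered fibres give sharp ladders and high contrast, disordered
#' fibres smear and score low.
#'
#' @param gel a `gel` object.
#' @param lane lane index.
#' @export
gel_contrast <- function(gel, lane = 1) {
  p <- gel$profiles[, lane]
  n <- length(p)
  pk <- which(p > c(-Inf, p[-n]) & p >= c(p[-1], -Inf) & p > max(p) * 0.05)
  if (length(pk) < 2) return(1)
  tr <- vapply(seq_len(length(pk) - 1), function(k)
    min(p[pk[k]:pk[k + 1]]), 1)
  mean(p[pk[-length(pk)]] / pmax(tr, 1e-9))
}

#' @export
plot.gel <- function(x, ...) {
  nl <- ncol(x$profiles)
  graphics::image(x = seq_len(nl + 1), y = x$migration,
                  z = t(cbind(x$profiles,
                              {
                                lad <- numeric(length(x$migration))
                                for (b in x$ladder$migration)
                                  lad <- lad + stats::dnorm(x$migration, b,
                                                            0.008)
                                lad * max(x$profiles) / max(lad)
                              })),
                  col = grDevices::gray.colors(64, 0.95, 0.05),
                  xlab = "lane (last = ladder)", ylab = "migration", ...)
  invisible(x)
}

# -------------------------------------------------------------- flattening --

#' Flatten a configuration onto a plane
#'
#' Simulates deposition for microscopy comparison: auxiliary Brownian
#' dynamics inside a planar slit whose gap narrows slowly from the current
#' z-extent to one core diameter, with binding and topology forces active
#' and soft-core off. Warns if the target gap is not reached within the
#' step budget.
#'
#' @param state a [system_state()].
#' @param seed integer seed.
#' @param params [ff_params()].
#' @param map [time_mapping()].
#' @param steps total integration steps for the narrowing schedule.
#' @param gap_end final slit gap (defaults to the core diameter).
#' @return object of class `flattened_config`: `state` (final 3D state),
#'   `xy` (projected bead coordinates), `core_xy`, `gap`, `converged`.
#' @export
flatten <- function(state, seed = 1L, params = ff_params(),
                    map = time_mapping(), steps = 60000,
                    gap_end = NULL) {
  if (is.null(gap_end)) gap_end <- params$core_diam
  # centre the configuration in z
  zs <- c(state$chains[[1]]$positions[, 3],
          vapply(state$cores, function(cp) cp$position[3], 1))
  zmid <- mean(range(zs))
  for (i in seq_along(state$chains))
    state$chains[[i]]$positions[, 3] <-
      state$chains[[i]]$positions[, 3] - zmid
  for (i in seq_along(state$cores))
    state$cores[[i]]$position[3] <- state$cores[[i]]$position[3] - zmid
  gap0 <- max(diff(range(zs)) + 2, gap_end * 2)
  ch <- run_chunk(state, params, map, nsteps = steps,
                  stride = max(steps, 1L), seed = seed,
                  slit_gap0 = gap0, slit_gap1 = gap_end,
                  limit_move = 0.45 * params$sigma_dna)
  st <- ch$state
  # brief settle at the final gap
  ch2 <- run_chunk(st, params, map, nsteps = max(2000L, steps %/% 10),
                   stride = max(steps, 1L), seed = seed + 1,
                   slit_gap0 = gap_end, slit_gap1 = gap_end,
                   limit_move = 0.45 * params$sigma_dna)
  st <- ch2$state
  zf <- c(st$chains[[1]]$positions[, 3],
          vapply(st$cores, function(cp) cp$position[3], 1))
  converged <- max(abs(zf)) <= gap_end / 2 + 1.5
  if (!converged)
    warning(sprintf("partial flatten: achieved |z| extent %.1f nm (gap %.1f)",
                    2 * max(abs(zf)), gap_end))
  structure(list(state = st,
                 xy = st$chains[[1]]$positions[, 1:2, drop = FALSE],
                 core_xy = t(vapply(st$cores,
                                    function(cp) cp$position[1:2],
                                    numeric(2))),
                 gap = gap_end, converged = converged),
            class = "flattened_config")
}

# ------------------------------------------------------------- AFM metrics --

# internal: nucleosome order along the chain = order of the median bound
# bead; cores with no bound beads are dropped.
nucleosome_order <- function(state, params, min_bp = 25) {
  was <- wrap_assignments(state, params)
  keep <- which(vapply(was, function(w) w$wrapped_bp, 1) >= min_bp)
  med <- vapply(was[keep], function(w) stats::median(w$bound_beads$bead), 1)
  ranges <- lapply(was[keep], function(w) range(w$bound_beads$bead))
  ord <- order(med)
  list(cores = keep[ord], median_bead = med[ord],
       ranges = ranges[ord])
}

#' AFM-style statistics of a (flattened) fibre
#'
#' The four distributions measured from AFM images of reconstituted
#' fibres: (i) the angle at the middle nucleosome of consecutive triplets;
#' (ii) the 2D distance from each nucleosome to its spatial nearest
#' neighbour; (iii) the DNA contour length between consecutive nucleosomes
#' along the fibre (linker, bead path summed between bound ranges);
#' (iv) the full pairwise 2D separation distribution.
#'
#' @param x a `flattened_config` or a [system_state()] (3D positions are
#'   then used as-is, with their first two coordinates).
#' @param params [ff_params()].
#' @param min_bp minimum wrapped bp for a core to count as a nucleosome.
#' @return list of class `afm_stats` with numeric vectors `triplet_angle`
#'   (degrees), `nn_dist` (nm), `contour_linker` (nm), `pairwise_dist`
#'   (nm), and the nucleosome order used.
#' @export
afm_stats <- function(x, params = ff_params(), min_bp = 25) {
  state <- if (inherits(x, "flattened_config")) x$state else x
  ord <- nucleosome_order(state, params, min_bp)
  ids <- ord$cores
  n <- length(ids)
  xy <- t(vapply(state$cores[ids], function(cp) cp$position[1:2],
                 numeric(2)))
  tri <- numeric(0)
  if (n >= 3) {
    tri <- vapply(2:(n - 1), function(k) {
      v1 <- xy[k - 1, ] - xy[k, ]; v2 <- xy[k + 1, ] - xy[k, ]
      a <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(pmax(a, -1), 1)) * 180 / pi
    }, 1)
  }
  nn <- numeric(0); pw <- numeric(0)
  if (n >= 2) {
    D <- as.matrix(stats::dist(xy))
    diag(D) <- Inf
    nn <- apply(D, 1, min)
    pw <- D[upper.tri(D)]
  }
  cl <- numeric(0)
  if (n >= 2) {
    P <- state$chains[[1]]$positions
    bl <- sqrt(rowSums(diff(P)^2))
    cl <- vapply(seq_len(n - 1), function(k) {
      a <- ord$ranges[[k]][2]; b <- ord$ranges[[k + 1]][1]
      if (b <= a) return(0)
      sum(bl[a:(b - 1)])
    }, 1)
  }
  structure(list(triplet_angle = tri, nn_dist = nn, contour_linker = cl,
                 pairwise_dist = pw, cores = ids),
            class = "afm_stats")
}

#' Zig-zag nearest-neighbour fraction
#'
#' Fraction of nucleosomes whose spatial nearest neighbour is its
#' next-but-one neighbour along the fibre (i +/- 2). A straight
#' beads-on-a-string fibre scores 0; a two-start zig-zag scores 1.
#'
#' @param x a [system_state()] or `flattened_config`.
#' @param params [ff_params()].
#' @param min_bp minimum wrapped bp for a core to count.
#' @param use_2d use only x,y coordinates (natural after flattening).
#' @export
zigzag_fraction <- function(x, params = ff_params(), min_bp = 25,
                            use_2d = inherits(x, "flattened_config")) {
  state <- if (inherits(x, "flattened_config")) x$state else x
  ord <- nucleosome_order(state, params, min_bp)
  ids <- ord$cores
  n <- length(ids)
  if (n < 3) return(NA_real_)
  pos <- t(vapply(state$cores[ids], function(cp) cp$position, numeric(3)))
  if (use_2d) pos[, 3] <- 0
  D <- as.matrix(stats::dist(pos))
  diag(D) <- Inf
  nni <- apply(D, 1, which.min)
  mean(abs(nni - seq_len(n)) == 2)
}

#' Persistence length from tangent-correlation decay
#'
#' Fits `exp(-s / lp)` to the mean tangent-tangent correlation of one or
#' more chains (log-linear fit through the origin over lags of
#' 1..`max_lag` beads).
#'
#' @param x a [dna_chain()], [system_state()], or list of either.
#' @param max_lag largest bead separation used in the fit.
#' @return persistence length in nm.
#' @export
persistence_length <- function(x, max_lag = 10) {
  chains <- if (inherits(x, "dna_chain")) list(x)
    else if (inherits(x, "system_state")) x$chains
    else lapply(x, function(e) if (inherits(e, "system_state"))
      e$chains[[1]] else e)
  lags <- seq_len(max_lag)
  num <- numeric(max_lag); den <- numeric(max_lag)
  sigma <- NULL
  for (ch in chains) {
    b <- diff(ch$positions)
    bl <- sqrt(rowSums(b^2))
    tng <- b / bl
    n <- nrow(tng)
    if (is.null(sigma)) sigma <- mean(bl)
    for (L in lags) {
      num[L] <- num[L] + sum(rowSums(tng[1:(n - L), , drop = FALSE] *
                                       tng[(1 + L):n, , drop = FALSE]))
      den[L] <- den[L] + (n - L)
    }
  }
  mc <- num / den
  fit <- stats::lm(log(mc) ~ 0 + lags)
  -sigma / unname(stats::coef(fit)[1])
}

#' Welch's unequal-variance t-test
#'
#' Thin wrapper over [stats::t.test()] (Welch-Satterthwaite degrees of
#' freedom, two-sided) with the degenerate cases called out explicitly.
#'
#' @param a,b numeric samples (each >= 2 values).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t needs at least 2 values per sample", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (identical(mean(a), mean(b))) return(list(t = 0, df = Inf, p = 1))
    stop("exact separation: both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
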