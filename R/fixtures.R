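# Synthetic structure generator: ideal fibres and the defect archetypes
# used to validate the classifier and every analysis observable. Each
# fixture is built deterministically to satisfy the defining geometric
# rule of its class (and to violate the others), with nuisance degrees of
# freedom (global pose, small positional jitter) randomized under the
# seed.

# straight run of beads from a to b inclusive of endpoints spacing ~sigma
interp_beads <- function(a, b, n) {
  tseq <- seq(0, 1, length.out = n + 2)[2:(n + 1)]
  outer(1 - tseq, a) + outer(tseq, b)
}

# build one wrapped nucleosome's bead block in world coordinates
# returns positions, patch dirs, plus entry/exit points & directions
wrap_block <- function(geom, centre, Rw, occupied = seq_len(geom$n_sites),
                       mirror = FALSE) {
  fr <- ideal_wrap_frames(geom)
  P <- fr$positions; U <- fr$patch_dirs
  if (mirror) {
    P[, 2] <- -P[, 2]
    U[, 2] <- -U[, 2]
  }
  Pw <- P %*% t(Rw) + matrix(centre, nrow(P), 3, byrow = TRUE)
  Uw <- U %*% t(Rw)
  n <- nrow(Pw)
  t0 <- unit3(Pw[1, ] - Pw[2, ])
  t1 <- unit3(Pw[n, ] - Pw[n - 1, ])
  zax <- as.vector(Rw %*% c(0, 0, 1))
  list(pos = Pw[occupied, , drop = FALSE],
       patch = Uw[occupied, , drop = FALSE],
       entry = Pw[min(occupied), ], exit = Pw[max(occupied), ],
       dir_in = unit3(t0 - 0.08 * zax), dir_out = unit3(t1 + 0.08 * zax),
       all_pos = Pw)
}

# assemble a chain from a list of blocks: straight leading tail, wraps
# joined by straight linkers, straight trailing tail. Patch vectors for
# linker beads are parallel-transported; wrapped beads use the site
# registry.
compose_chain <- function(blocks, linker_beads, tail_beads = 10L,
                          sigma = 2.5, bp_per_bead = 7.35) {
  pos <- NULL; patch <- NULL; wrapped <- NULL
  nblk <- length(blocks)
  # leading tail along -dir_in of the first block
  b1 <- blocks[[1]]
  tail0 <- matrix(b1$entry, tail_beads, 3, byrow = TRUE) +
    outer(seq(tail_beads, 1) * sigma, b1$dir_in)
  pos <- tail0
  patch <- matrix(NA_real_, nrow(tail0), 3)
  wrapped <- rep(0L, nrow(tail0))
  for (k in seq_len(nblk)) {
    bk <- blocks[[k]]
    pos <- rbind(pos, bk$pos)
    patch <- rbind(patch, bk$patch)
    wrapped <- c(wrapped, rep(k, nrow(bk$pos)))
    if (k < nblk) {
      nxt <- blocks[[k + 1]]
      gap_vec <- nxt$entry - bk$exit
      nlink <- if (length(linker_beads) >= k && !is.na(linker_beads[k]))
        linker_beads[k] else
        max(1L, round(sqrt(sum(gap_vec^2)) / sigma) - 1L)
      lb <- interp_beads(bk$exit, nxt$entry, nlink)
      pos <- rbind(pos, lb)
      patch <- rbind(patch, matrix(NA_real_, nlink, 3))
      wrapped <- c(wrapped, rep(0L, nlink))
    }
  }
  bl <- blocks[[nblk]]
  tailN <- matrix(bl$exit, tail_beads, 3, byrow = TRUE) +
    outer(seq(1, tail_beads) * sigma, bl$dir_out)
  pos <- rbind(pos, tailN)
  patch <- rbind(patch, matrix(NA_real_, tail_beads, 3))
  wrapped <- c(wrapped, rep(0L, tail_beads))
  q <- registry_frames(pos, patch)
  list(chain = dna_chain(pos, q, bp_per_bead), wrapped = wrapped)
}

# Build bead quaternions honouring a (partial) patch registry: beads with
# a prescribed patch keep it (projected perpendicular to the bead
# tangent); unregistered runs are filled by zero-measured-twist transport
# outward from the nearest registered bead, so the stored twist of a wrap
# stays confined to the wrap (any registry mismatch between two wraps is
# absorbed at a single mid-linker joint).
registry_frames <- function(pos, patch) {
  n <- nrow(pos)
  Tn <- bead_tangents(pos)
  bonds <- diff(pos)
  bonds <- bonds / sqrt(rowSums(bonds^2))
  U <- matrix(NA_real_, n, 3)
  reg <- !is.na(patch[, 1])
  for (i in which(reg)) {
    u <- patch[i, ] - sum(patch[i, ] * Tn[i, ]) * Tn[i, ]
    U[i, ] <- unit3(u)
  }
  # zero-twist step: move the patch from bead i to bead j = i +/- 1 so
  # that the measured dihedral at the connecting bond is exactly zero
  step0 <- function(u, b, tn) {
    a <- u - sum(u * b) * b
    unit3(a - (sum(a * tn) / sum(b * tn)) * b)
  }
  if (!any(reg)) {
    return(frames_from_positions(pos))
  }
  runs <- rle(reg)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    a <- starts[k]; b <- ends[k]
    has_prev <- a > 1L
    has_next <- b < n
    if (has_prev && has_next) {
      nf <- ceiling((b - a + 1L) / 2)
      fwd <- a:(a + nf - 1L)
      bwd <- if (a + nf <= b) (a + nf):b else integer(0)
    } else if (has_prev) {
      fwd <- a:b; bwd <- integer(0)
    } else {
      fwd <- integer(0); bwd <- a:b
    }
    for (i in fwd)
      U[i, ] <- step0(U[i - 1, ], bonds[i - 1, ], Tn[i, ])
    for (i in rev(bwd))
      U[i, ] <- step0(U[i + 1, ], bonds[i, ], Tn[i, ])
  }
  q <- matrix(0, n, 4)
  for (i in seq_len(n))
    q[i, ] <- quat_from_matrix(cbind(Tn[i, ], U[i, ],
                                     cross3(Tn[i, ], U[i, ])))
  q
}

# random rotation matrix under the current RNG
rand_rotation <- function() {
  q <- quat_from_rotvec(stats::runif(3, -pi, pi))
  cbind(as.vector(quat_rotate(q, c(1, 0, 0))),
        as.vector(quat_rotate(q, c(0, 1, 0))),
        as.vector(quat_rotate(q, c(0, 0, 1))))
}

#' Generate a synthetic fixture state
#'
#' Deterministic archetypes of the self-assembly outcomes: the ideal
#' 10-nm fibre and the defect classes (partially wrapped, locked partial,
#' loop capture, right-handed wrap, proximal dimer), plus a two-start
#' zig-zag fibre and a nanoparticle cluster. Used throughout the test
#' suite and available for classifier calibration.
#'
#' @param kind one of `"ideal_fibre"`, `"mononucleosome"` (one fully
#'   wrapped core on an otherwise relaxed chain), `"partial"`,
#'   `"locked_partial"`, `"loop"`, `"right_handed"`, `"dimer"`,
#'   `"zigzag"`, `"nanoparticle_cluster"`.
#' @param params named list of overrides: `n_cores` (fibres), `linker_bp`
#'   (default 74), `jitter` (bead positional noise, nm, default 0.05),
#'   `stored_twist` (default +0.75), `occupied_sites` (partial classes).
#' @param seed integer seed for the nuisance randomization.
#' @param ff [ff_params()].
#' @return a [system_state()]; cores carry an `attachment_bead` attribute.
#' @export
make_fixture <- function(kind = c("ideal_fibre", "mononucleosome",
                                  "partial", "locked_partial", "loop",
                                  "right_handed", "dimer", "zigzag",
                                  "nanoparticle_cluster"),
                         params = list(), seed = 1L, ff = ff_params()) {
  kind <- match.arg(kind)
  set.seed(seed)
  p <- utils::modifyList(
    list(n_cores = 10L, linker_bp = 74, jitter = 0.05, stored_twist = 0.75,
         occupied_sites = 10L, turn_deg = NA), params)
  geom <- core_geometry("octamer", stored_twist = p$stored_twist,
                        path_radius = ff$path_radius,
                        path_pitch = ff$path_pitch,
                        body_diam = ff$core_diam)
  sigma <- ff$sigma_dna
  linker_beads <- max(1L, round(p$linker_bp / 7.35))

  if (kind == "nanoparticle_cluster") {
    ng <- core_geometry("nanoparticle", body_diam = ff$core_diam)
    n_np <- p$n_cores %||% 4L
    centres <- matrix(stats::rnorm(3 * n_np, sd = 3), n_np, 3) +
      matrix(rep(c(0, 0, 0), each = n_np), n_np, 3)
    # push apart to contact distance
    for (it in 1:200) {
      D <- as.matrix(stats::dist(centres)); diag(D) <- Inf
      if (min(D) >= ff$core_diam) break
      ij <- which(D == min(D), arr.ind = TRUE)[1, ]
      d <- centres[ij[1], ] - centres[ij[2], ]
      centres[ij[1], ] <- centres[ij[1], ] + 0.3 * unit3(d)
      centres[ij[2], ] <- centres[ij[2], ] - 0.3 * unit3(d)
    }
    # DNA meanders over the cluster surface: greedy walk on the contact shell
    shell <- 0.5 * (ff$core_diam + sigma)
    nb <- 80L
    pos <- matrix(0, nb, 3)
    host <- sample.int(n_np, 1)
    u <- unit3(stats::rnorm(3))
    pos[1, ] <- centres[host, ] + shell * u
    for (i in 2:nb) {
      step <- unit3(stats::rnorm(3))
      cand <- pos[i - 1, ] + sigma * step
      host <- which.min(sqrt(rowSums((centres - matrix(cand, n_np, 3,
                                                       byrow = TRUE))^2)))
      v <- cand - centres[host, ]
      pos[i, ] <- centres[host, ] + shell * unit3(v)
      # keep bond length reasonable
      d <- pos[i, ] - pos[i - 1, ]
      L <- sqrt(sum(d^2))
      if (L > 1e-9) pos[i, ] <- pos[i - 1, ] + d / L * sigma
    }
    chain <- dna_chain(pos, bp_per_bead = 7.35)
    cores <- lapply(seq_len(n_np), function(i)
      core_particle(ng, centres[i, ], quat_from_rotvec(stats::runif(3))))
    return(system_state(chain, cores))
  }

  if (kind == "zigzag") {
    # sharp alternating turns so that cores i and i+2 are spatially closest
    n <- p$n_cores
    ang <- 65 * pi / 180
    dirs <- lapply(seq_len(n + 1), function(k)
      c(cos((if (k %% 2) 1 else -1) * ang), sin((if (k %% 2) 1 else -1) * ang), 0))
    centres <- matrix(0, n, 3)
    Lstep <- linker_beads * sigma + 12
    for (k in 2:n)
      centres[k, ] <- centres[k - 1, ] + Lstep * dirs[[k]]
    blocks <- lapply(seq_len(n), function(k) {
      Rw <- rand_rotation()
      wrap_block(geom, centres[k, ], Rw)
    })
    cc <- compose_chain(blocks, linker_beads = rep(NA, n - 1), sigma = sigma)
  } else if (kind %in% c("ideal_fibre", "dimer")) {
    n <- if (kind == "dimer") 2L else p$n_cores
    occ <- if (kind == "dimer") {
      k <- geom$n_sites %/% 4
      (k + 1):(geom$n_sites - k)  # central half only: under-wrapped
    } else seq_len(geom$n_sites)
    lb <- if (kind == "dimer") max(1L, round(110 / 7.35) -
                                     (geom$n_sites - length(occ)))
          else linker_beads
    # solve the core spacing so that the linker bonds sit at the bond
    # rest length: |s x + entry_{k+1} - exit_k| = (lb + 1) sigma
    Rflip2 <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
    fr0 <- ideal_wrap_frames(geom)
    e_in <- fr0$positions[min(occ), ]
    e_out <- fr0$positions[max(occ), ]
    dloc <- as.vector(Rflip2 %*% e_in) - e_out   # odd -> even junction
    targ <- (lb + 1) * sigma
    b_ <- dloc[1]
    c_ <- sum(dloc^2) - targ^2
    s1 <- -b_ + sqrt(max(b_^2 - c_, 0))
    dloc2 <- e_in - as.vector(Rflip2 %*% e_out)  # even -> odd junction
    b2_ <- dloc2[1]
    c2_ <- sum(dloc2^2) - targ^2
    s2 <- -b2_ + sqrt(max(b2_^2 - c2_, 0))
    spacing <- pmax(c(s1, s2), geom$body_diam + 1.5)
    blocks <- vector("list", n)
    xoff <- 0
    for (k in seq_len(n)) {
      Rflip <- if (k %% 2 == 0) Rflip2 else diag(3)
      blocks[[k]] <- wrap_block(geom, c(xoff, 0, 0), Rflip, occupied = occ)
      xoff <- xoff + spacing[if (k %% 2 == 1) 1 else 2]
    }
    cc <- compose_chain(blocks, linker_beads = rep(lb, n - 1), sigma = sigma)
  } else {
    # single-core archetypes
    occ <- switch(kind,
                  partial = seq_len(p$occupied_sites),
                  locked_partial = seq_len(p$occupied_sites),
                  loop = seq_len(p$occupied_sites),
                  right_handed = seq_len(geom$n_sites),
                  mononucleosome = seq_len(geom$n_sites))
    blocks <- list(wrap_block(geom, c(0, 0, 0), diag(3), occupied = occ,
                              mirror = kind == "right_handed"))
    cc <- compose_chain(blocks, linker_beads = integer(0), tail_beads = 30L,
                        sigma = sigma)
  }

  chain <- cc$chain
  n_oct <- length(unique(cc$wrapped[cc$wrapped > 0]))
  cores <- lapply(seq_len(n_oct), function(k)
    core_particle(geom, colMeans(blocks[[k]]$all_pos), c(1, 0, 0, 0)))
  state <- system_state(chain, cores)
  state <- fixture_fit_cores(state, cc$wrapped, geom)

  # extra constructions for locked_partial and loop: bring a distant
  # chain segment back onto an exposed site
  if (kind %in% c("locked_partial", "loop")) {
    gap_beads <- if (kind == "loop") 90L else 25L  # 661 bp vs 184 bp gap
    state <- fixture_add_return(state, geom, occupied = p$occupied_sites,
                                gap_beads = gap_beads, ff = ff)
  }

  # nuisance randomization: global pose + jitter (kept tiny so the
  # binding registry survives)
  Rg <- rand_rotation()
  shift <- stats::rnorm(3, sd = 5)
  for (i in seq_along(state$chains)) {
    ch <- state$chains[[i]]
    posn <- ch$positions %*% t(Rg) +
      matrix(shift, n_beads(ch), 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n_beads(ch), sd = p$jitter), ncol = 3)
    qg <- matrix(quat_from_matrix(Rg), 1)
    qn <- quat_multiply(qg[rep(1, n_beads(ch)), ], ch$quat)
    state$chains[[i]] <- dna_chain(posn, qn, ch$bp_per_bead, ch$topology)
  }
  for (i in seq_along(state$cores)) {
    cp <- state$cores[[i]]
    ab <- attr(cp, "attachment_bead")
    cp$position <- as.vector(Rg %*% cp$position) + shift
    cp$orientation <- as.vector(quat_multiply(
      matrix(quat_from_matrix(Rg), 1), matrix(cp$orientation, 1)))
    attr(cp, "attachment_bead") <- ab
    state$cores[[i]] <- cp
  }
  state
}

# place each core so its sites coincide with its wrapped beads: solve the
# rigid pose from the ideal site positions to the observed bead positions
# (Kabsch on the occupied sites).
fixture_fit_cores <- function(state, wrapped, geom) {
  fr <- ideal_wrap_frames(geom)
  ch <- state$chains[[1]]
  for (k in seq_along(state$cores)) {
    idx <- which(wrapped == k)
    if (!length(idx)) next
    B <- ch$positions[idx, , drop = FALSE]
    nocc <- nrow(B)
    # occupied sites are the first nocc sites unless mirrored (handled by
    # fitting both and keeping the better)
    fits <- lapply(list(fr$positions[seq_len(nocc), , drop = FALSE],
                        {
                          M <- fr$positions[seq_len(nocc), , drop = FALSE]
                          M[, 2] <- -M[, 2]; M
                        }),
                   function(A) kabsch_fit(A, B))
    err <- vapply(fits, `[[`, 1, "rmsd")
    ft <- fits[[which.min(err)]]
    cp <- state$cores[[k]]
    cp$position <- ft$t
    cp$orientation <- quat_from_matrix(ft$R)
    attr(cp, "attachment_bead") <- round(stats::median(idx))
    state$cores[[k]] <- cp
  }
  state
}

# rigid transform minimizing |R A + t - B|
kabsch_fit <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cb - as.vector(R %*% ca)
  fit <- sweep(A %*% t(R), 2, t_, `+`)
  list(R = R, t = t_, rmsd = sqrt(mean(rowSums((fit - B)^2))))
}

# extend the chain's trailing tail and loop it back so that one or more
# beads dock on exposed sites of core 1, with a controlled sequence gap.
fixture_add_return <- function(state, geom, occupied, gap_beads, ff) {
  ch <- state$chains[[1]]
  cp <- state$cores[[1]]
  fr <- ideal_wrap_frames(geom)
  Rw <- cbind(as.vector(quat_rotate(matrix(cp$orientation, 1), c(1, 0, 0))),
              as.vector(quat_rotate(matrix(cp$orientation, 1), c(0, 1, 0))),
              as.vector(quat_rotate(matrix(cp$orientation, 1), c(0, 0, 1))))
  target_site <- occupied + 4L  # an exposed site past the wrapped run
  sp <- cp$position + as.vector(Rw %*% fr$positions[target_site, ])
  su <- as.vector(Rw %*% fr$patch_dirs[target_site, ])
  P <- ch$positions
  n0 <- nrow(P)
  tail_dir <- unit3(P[n0, ] - P[n0 - 1, ])
  # wander out, then come back to the exposed site
  out_beads <- gap_beads - 12L
  arc1 <- interp_beads(P[n0, ], P[n0, ] + (out_beads * 2.5) * tail_dir +
                         c(0, 0, 18), out_beads)
  arc2 <- interp_beads(arc1[nrow(arc1), ], sp, 11L)
  newP <- rbind(P, arc1, arc2, matrix(sp, 1, 3))
  patch <- rbind(quat_rotate(ch$quat, c(0, 1, 0)),
                 matrix(NA_real_, nrow(arc1) + nrow(arc2), 3),
                 matrix(su, 1, 3))
  q <- registry_frames(newP, patch)
  state$chains[[1]] <- dna_chain(newP, q, ch$bp_per_bead, ch$topology)
  state
}
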