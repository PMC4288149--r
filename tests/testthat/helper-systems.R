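# Shared builders for the test suite. Everything is generated in code;
# nothing is read from disk.

# planar circular chain with dLk turns of imposed twist (supercoiled ring)
make_supercoiled_ring <- function(nb = 80, dLk = 4) {
  th <- seq(0, 2 * pi, length.out = nb + 1)[1:nb]
  R <- nb * 2.5 / (2 * pi)
  P <- cbind(R * cos(th), R * sin(th), 0)
  b <- diff(rbind(P, P[1, ]))
  b <- b / sqrt(rowSums(b^2))
  Tn <- b + rbind(b[nrow(b), ], b[-nrow(b), ])
  Tn <- Tn / sqrt(rowSums(Tn^2))
  q <- matrix(0, nb, 4)
  for (i in seq_len(nb)) {
    phi <- 2 * pi * dLk * (i - 1) / nb
    u <- cos(phi) * c(0, 0, 1) +
      sin(phi) * chromassemble:::cross3(Tn[i, ], c(0, 0, 1))
    u <- chromassemble:::unit3(u - sum(u * Tn[i, ]) * Tn[i, ])
    q[i, ] <- chromassemble:::quat_from_matrix(
      cbind(Tn[i, ], u, chromassemble:::cross3(Tn[i, ], u)))
  }
  dna_chain(P, q, topology = "circular")
}

# a chain built from explicit joint angles: every patch transported with
# a prescribed per-joint twist (straight backbone)
make_twisted_rod <- function(nb = 40, total_turns = 1) {
  pos <- cbind(0, 0, seq(0, by = 2.5, length.out = nb))
  phi <- 2 * pi * total_turns * (seq_len(nb) - 1) / (nb - 1)
  q <- matrix(0, nb, 4)
  for (i in seq_len(nb)) {
    u <- c(cos(phi[i]), sin(phi[i]), 0)
    q[i, ] <- chromassemble:::quat_from_matrix(
      cbind(c(0, 0, 1), u, chromassemble:::cross3(c(0, 0, 1), u)))
  }
  dna_chain(pos, q)
}

# trefoil knot polyline (closed), writhe about -3.41 in the continuum
make_trefoil <- function(n = 120) {
  t <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t))
}

quick_map <- function(dt = 0.002) time_mapping(dt = dt)

run_bd_chunk <- function(state, params, nsteps, seed, ...) {
  chromassemble:::run_chunk(state, params, quick_map(), nsteps = nsteps,
                            stride = nsteps, seed = seed, ...)$state
}

rotate_state_rigidly <- function(chain, seed = 1) {
  set.seed(seed)
  q <- chromassemble:::quat_from_rotvec(stats::runif(3, -pi, pi))
  R <- cbind(as.vector(chromassemble:::quat_rotate(q, c(1, 0, 0))),
             as.vector(chromassemble:::quat_rotate(q, c(0, 1, 0))),
             as.vector(chromassemble:::quat_rotate(q, c(0, 0, 1))))
  sh <- stats::rnorm(3, sd = 20)
  qn <- chromassemble:::quat_multiply(
    matrix(chromassemble:::quat_from_matrix(R), 1)[rep(1, n_beads(chain)), ],
    chain$quat)
  dna_chain(sweep(chain$positions %*% t(R), 2, sh, `+`), qn,
            chain$bp_per_bead, chain$topology)
}
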