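# Potentials and exact gradients.

test_that("parameter derivations match the physical inputs", {
  p <- ff_params()
  # torsional rigidity 3e-19 erg cm -> ~72 nm twist persistence length
  expect_equal(p$twist_k * p$sigma_dna, 72.4, tolerance = 0.01)
  # discrete-chain bending calibration: explicit KP + alignment series
  expect_equal(p$bend_k + p$align_k / 2, 1 / (1 - exp(-2.5 / 50)),
               tolerance = 1e-10)
  expect_error(ff_params(softcore_cap = Inf))
})

test_that("twist energy follows the chosen periodic closed form", {
  # one joint at 10 degrees: E = twist_k * (1 - cos(10 deg))
  ch <- make_twisted_rod(2, total_turns = 10 / 360)
  p <- ff_params()
  bf <- bonded_energy_forces(ch, p)
  phi <- 10 * pi / 180
  expect_equal(unname(bf$terms["twist"]), p$twist_k * (1 - cos(phi)),
               tolerance = 1e-8)
  # which agrees with the harmonic 0.5 k phi^2 up to the phi^2/12
  # relative Taylor remainder (~2.5e-3 at 10 degrees)
  expect_equal(unname(bf$terms["twist"]), 0.5 * p$twist_k * phi^2,
               tolerance = 4e-3)
})

test_that("forces and torques are exact gradients (finite differences)", {
  set.seed(4)
  p <- ff_params()
  ch <- build_dna_chain(30 * 7.35, "equilibrium-coil", seed = 5)
  core <- core_particle(core_geometry(), ch$positions[15, ] + c(2, 1, 0))
  nano <- core_particle(core_geometry("nanoparticle"),
                        ch$positions[25, ] + c(0, 4, 1))
  st <- system_state(ch, list(core, nano))
  ef <- energy_forces(st, p)
  h <- 1e-6
  rotq <- function(q, w)
    chromassemble:::quat_multiply(chromassemble:::quat_from_rotvec(w),
                                  matrix(q, 1))
  err <- 0
  for (i in c(1, 8, 15, 23, 30)) for (k in 1:3) {
    stp <- st; stm <- st
    stp$chains[[1]]$positions[i, k] <- st$chains[[1]]$positions[i, k] + h
    stm$chains[[1]]$positions[i, k] <- st$chains[[1]]$positions[i, k] - h
    fd <- -(energy_forces(stp, p)$energy - energy_forces(stm, p)$energy) /
      (2 * h)
    err <- max(err, abs(fd - ef$f_bead[i, k]) / max(1, abs(fd)))
    w <- numeric(3); w[k] <- h
    stp <- st; stm <- st
    stp$chains[[1]]$quat[i, ] <- rotq(st$chains[[1]]$quat[i, ], w)
    stm$chains[[1]]$quat[i, ] <- rotq(st$chains[[1]]$quat[i, ], -w)
    fd <- -(energy_forces(stp, p)$energy - energy_forces(stm, p)$energy) /
      (2 * h)
    err <- max(err, abs(fd - ef$t_bead[i, k]) / max(1, abs(fd)))
  }
  for (ic in 1:2) for (k in 1:3) {
    stp <- st; stm <- st
    stp$cores[[ic]]$position[k] <- st$cores[[ic]]$position[k] + h
    stm$cores[[ic]]$position[k] <- st$cores[[ic]]$position[k] - h
    fd <- -(energy_forces(stp, p)$energy - energy_forces(stm, p)$energy) /
      (2 * h)
    err <- max(err, abs(fd - ef$f_core[ic, k]) / max(1, abs(fd)))
    w <- numeric(3); w[k] <- h
    stp <- st; stm <- st
    stp$cores[[ic]]$orientation <- as.vector(
      rotq(st$cores[[ic]]$orientation, w))
    stm$cores[[ic]]$orientation <- as.vector(
      rotq(st$cores[[ic]]$orientation, -w))
    fd <- -(energy_forces(stp, p)$energy - energy_forces(stm, p)$energy) /
      (2 * h)
    err <- max(err, abs(fd - ef$t_core[ic, k]) / max(1, abs(fd)))
  }
  expect_lt(err, 1e-5)
})

test_that("excluded volume is hard normally and capped during soft-core", {
  p <- ff_params()
  # two double-bead strands at 0.9 sigma lateral separation
  pos <- rbind(c(0, 0, 0), c(0, 0, 2.5), c(2.25, 0, 0), c(2.25, 0, 2.5))
  st <- system_state(dna_chain(pos))
  hard <- pair_energy_forces(st, p, softcore = FALSE)
  expect_gt(unname(hard$terms["rep"]), 20)
  soft <- pair_energy_forces(st, p, softcore = TRUE)
  expect_lte(unname(soft$terms["soft"]), 2 * p$softcore_cap + 1e-9)
  expect_equal(unname(soft$terms["rep"]), 0)
})

test_that("a perfectly docked bead sits at minus eps_site", {
  p <- ff_params()
  g <- core_geometry("octamer")
  fr <- ideal_wrap_frames(g)
  # one bead placed exactly on site 8 with the registered patch
  i <- 8
  t <- fr$tangents[i, ]; u <- fr$patch_dirs[i, ]
  q <- chromassemble:::quat_from_matrix(
    cbind(t, u, chromassemble:::cross3(t, u)))
  ch <- dna_chain(rbind(fr$positions[i, ],
                        fr$positions[i, ] + 2.5 * t),
                  rbind(q, q))
  st <- system_state(ch, list(core_particle(g)))
  pe <- pair_energy_forces(st, p)
  expect_lt(abs(min(site_contacts(st, p)$energy) + p$eps_site), 1e-6)
})

test_that("interaction pairs obey Newton's third law", {
  p <- ff_params()
  set.seed(9)
  g <- core_geometry("octamer")
  ch <- build_dna_chain(6 * 7.35, "equilibrium-coil", seed = 3)
  core <- core_particle(g, ch$positions[3, ] + c(3, 1, -1),
                        chromassemble:::quat_from_rotvec(runif(3)))
  st <- system_state(ch, list(core))
  pe <- pair_energy_forces(st, p)
  net_f <- colSums(pe$f_bead) + colSums(pe$f_core)
  expect_lt(max(abs(net_f)), 1e-10)
  # net torque about the origin: sum of r x F plus the spin torques
  tq <- colSums(pe$t_bead) + colSums(pe$t_core)
  for (i in seq_len(n_beads(ch)))
    tq <- tq + chromassemble:::cross3(ch$positions[i, ], pe$f_bead[i, ])
  tq <- tq + chromassemble:::cross3(core$position, pe$f_core[1, ])
  expect_lt(max(abs(tq)), 1e-9)
})

test_that("free-chain dynamics keeps the 50 nm persistence length", {
  p <- ff_params()
  lps <- vapply(1:4, function(s) {
    ch <- build_dna_chain(150 * 7.35, "equilibrium-coil", seed = 40 + s)
    st <- system_state(ch)
    vals <- numeric(3)
    for (k in 1:3) {
      st <- run_bd_chunk(st, p, nsteps = 12000, seed = s * 31 + k,
                         limit_move = 1.1)
      vals[k] <- persistence_length(st$chains[[1]])
    }
    mean(vals)
  }, 1)
  expect_lt(abs(mean(lps) - 50) / 50, 0.10)
})

test_that("twist fluctuations are consistent with the torsional rigidity", {
  p <- ff_params()
  map <- quick_map(dt = 5e-4)
  ch <- build_dna_chain(50 * 7.35, "straight")
  st <- system_state(ch)
  tw <- c()
  for (k in 1:30) {
    st <- chromassemble:::run_chunk(st, p, map, nsteps = 2000,
                                    stride = 2000, seed = 700 + k)$state
    if (k > 8) {
      chx <- st$chains[[1]]
      P <- chx$positions
      U <- chromassemble:::quat_rotate(chx$quat, c(0, 1, 0))
      b <- diff(P); b <- b / sqrt(rowSums(b^2))
      n <- nrow(P)
      a1 <- U[-n, ]; a2 <- U[-1, ]
      a1 <- a1 - rowSums(a1 * b) * b
      a2 <- a2 - rowSums(a2 * b) * b
      crx <- cbind(a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2],
                   a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3],
                   a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1])
      tw <- c(tw, atan2(rowSums(crx * b), rowSums(a1 * a2)))
    }
  }
  expect_lt(abs(var(tw) * p$twist_k - 1), 0.15)
})

test_that("deterministic descent decreases the energy monotonically", {
  p <- ff_params()
  ch <- build_dna_chain(50 * 7.35, "equilibrium-coil", seed = 11)
  st <- system_state(ch)
  e <- energy_forces(st, p)$energy
  for (k in 1:5) {
    st <- run_bd_chunk(st, p, nsteps = 200, seed = k, temperature = 0)
    e2 <- energy_forces(st, p)$energy
    expect_lte(e2, e + 1e-4 * 200)
    e <- e2
  }
})
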