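# Brownian-dynamics integrator: time mapping, diffusion, equilibrium
# sampling, determinism, rigid bodies.

test_that("the Brownian time maps to physical milliseconds", {
  map <- time_mapping()
  expect_equal(map$tau_B, 3.56e-8, tolerance = 0.01)
  expect_equal(ms_to_tau(0.3, map), 8.4e3, tolerance = 0.01)
  expect_equal(tau_to_ms(ms_to_tau(0.12, map), map), 0.12)
})

test_that("zero forces at zero temperature leave the state unchanged", {
  p <- ff_params(bond_k = 0, bend_k = 0, twist_k = 0, align_k = 0,
                 eps_rep = 0)
  ch <- build_dna_chain(5 * 7.35, "straight")
  st <- system_state(ch)
  st2 <- run_bd_chunk(st, p, nsteps = 100, seed = 1, temperature = 0)
  expect_equal(st2$chains[[1]]$positions, st$chains[[1]]$positions,
               tolerance = 1e-14)
})

test_that("a free bead diffuses with the Stokes-Einstein coefficient", {
  p <- ff_params(bond_k = 0, bend_k = 0, twist_k = 0, align_k = 0,
                 eps_rep = 0)
  ch <- build_dna_chain(2 * 7.35, "straight")
  st <- system_state(ch)
  nst <- 300L
  msd <- unlist(lapply(1:600, function(s) {
    st2 <- run_bd_chunk(st, p, nsteps = nst, seed = 5000 + s)
    rowSums((st2$chains[[1]]$positions - st$chains[[1]]$positions)^2)
  }))
  expect_lt(abs(mean(msd) - 6 * 6.25 * nst * 0.002) /
              (6 * 6.25 * nst * 0.002), 0.05)
})

test_that("a harmonic bond equilibrates to the Boltzmann distribution", {
  p <- ff_params(bend_k = 0, twist_k = 0, align_k = 0, eps_rep = 0)
  ch <- build_dna_chain(6 * 7.35, "straight")
  st <- system_state(ch)
  lens <- c()
  for (k in 1:120) {
    st <- run_bd_chunk(st, p, nsteps = 300, seed = 900 + k)
    if (k > 20)
      lens <- c(lens, sqrt(rowSums(diff(st$chains[[1]]$positions)^2)))
  }
  # p(r) ~ r^2 exp(-k/2 (r - r0)^2); compare via the numerical CDF
  rr <- seq(1.0, 4.5, length.out = 2000)
  dens <- rr^2 * exp(-p$bond_k / 2 * (rr - p$bond_r0)^2)
  cdf <- cumsum(dens) / sum(dens)
  ks <- suppressWarnings(
    stats::ks.test(lens, function(q) approx(rr, cdf, q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(var(lens) - 1 / p$bond_k) / (1 / p$bond_k), 0.20)
})

test_that("trajectories are reproducible and duration zero is a no-op", {
  p <- ff_params()
  st <- make_fixture("mononucleosome", seed = 2)
  t1 <- bd_run(st, duration_tau = 10, params = p, seed = 7, stride = 1000,
               limit_move = 1.1)
  t2 <- bd_run(st, duration_tau = 10, params = p, seed = 7, stride = 1000,
               limit_move = 1.1)
  expect_identical(t1$snapshots, t2$snapshots)
  t3 <- bd_run(st, duration_tau = 10, params = p, seed = 8, stride = 1000,
               limit_move = 1.1)
  expect_false(identical(t1$snapshots[[length(t1$snapshots)]]$pos,
                         t3$snapshots[[length(t3$snapshots)]]$pos))
  t0 <- chromassemble:::run_chunk(st, p, quick_map(), nsteps = 0,
                                  stride = 1, seed = 1)
  expect_equal(length(t0$times), 1L)
})

test_that("overlapping hard beads trigger the unstable-step error", {
  p <- ff_params(eps_rep = 50)
  pos <- rbind(c(0, 0, 0), c(0, 0, 2.5), c(0.6, 0, 0.2), c(0.6, 0, 2.7))
  st <- system_state(dna_chain(pos))
  expect_error(
    chromassemble:::run_chunk(st, p, quick_map(), nsteps = 5, stride = 5,
                              seed = 1),
    "unstable step")
})

test_that("rigid cores keep their site geometry exactly", {
  p <- ff_params()
  st <- make_fixture("mononucleosome", seed = 3)
  st2 <- run_bd_chunk(st, p, nsteps = 2000, seed = 3, limit_move = 1.1)
  site_d <- function(cp) {
    a <- state <- cp$geometry$site_local_positions
    q <- matrix(cp$orientation, 1)
    w <- chromassemble:::quat_rotate(q[rep(1, nrow(a)), ], a)
    as.vector(dist(w))
  }
  expect_equal(site_d(st2$cores[[1]]), site_d(st$cores[[1]]),
               tolerance = 1e-10)
  expect_equal(sum(st2$cores[[1]]$orientation^2), 1, tolerance = 1e-10)
})
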