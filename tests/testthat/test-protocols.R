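# Protocol schedules and replicated experiments.

test_that("protocol schedules encode the experiment matrix", {
  s2 <- make_protocol("dLk100", "high", "regular", "topo2")
  expect_equal(s2$n_bp, 22100)
  expect_equal(s2$n_cores, 100)
  win <- s2$stages[s2$stages$softcore_on, ]
  expect_equal(sum(win$t_end - win$t_start), 0.1, tolerance = 1e-9)
  expect_equal(min(win$t_start), 0.1)
  s0 <- make_protocol("dLk100", topo = "none")
  expect_false(any(s0$stages$softcore_on))
  s1 <- make_protocol("dLk100", topo = "topo1")
  expect_true(any(s1$stages$twist_relax_on))
  expect_false(any(s1$stages$softcore_on))
  sl <- make_protocol("dLk100", density = "low")
  expect_equal(sl$n_bp, 44200)
  so <- make_protocol("dLk100", one_step = TRUE)
  expect_false(any(so$stages$tetramer_only))
  expect_equal(so$stages$t_start[1], 0)
  sh <- make_protocol("dLk100")
  expect_true(sh$stages$tetramer_only[1])
  expect_error(make_protocol("unknown-variant"))
})

test_that("invalid schedules are rejected before any stepping", {
  s <- make_protocol("dLk100", topo = "topo2")
  bad <- s
  bad$stages$twist_relax_on <- bad$stages$softcore_on
  expect_error(validate_protocol(bad), "contradictory")
  bad2 <- s
  bad2$stages$t_start[2] <- bad2$stages$t_start[2] + 0.01
  expect_error(validate_protocol(bad2), "contiguous")
  bad3 <- s
  bad3$stages$t_end[1] <- 0
  expect_error(validate_protocol(bad3), "increasing")
})

test_that("schedules serialize losslessly through YAML", {
  s <- make_protocol("dLk100_boost", "low", "random", "topo1",
                     scale = 0.1, one_step = TRUE)
  f <- tempfile(fileext = ".yaml")
  write_protocol_yaml(s, f)
  s2 <- read_protocol_yaml(f)
  expect_equal(s2$stages, s$stages)
  expect_equal(s2$n_bp, s$n_bp)
  expect_equal(s2$variant, s$variant)
})

test_that("replicated experiments are seeded, deterministic and guarded", {
  sched <- make_protocol("dLk100", "high", "regular", "none",
                         scale = 0.02, time_scale = 0.02)
  r1 <- run_experiment(sched, n_replicas = 3, base_seed = 11)
  expect_length(r1$states, 3)
  expect_equal(length(unique(r1$manifest$replica_seeds)), 3)
  r2 <- run_experiment(sched, n_replicas = 3, base_seed = 11)
  expect_identical(r1$states[[2]]$chains[[1]]$positions,
                   r2$states[[2]]$chains[[1]]$positions)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  big <- make_protocol("dLk100", scale = 1)
  expect_error(run_experiment(big, 1, 1), "resource guard")
})

test_that("topo-I windows drain injected twist", {
  p <- ff_params()
  rod <- make_twisted_rod(100, total_turns = 2)
  st <- system_state(rod)
  # relaxation window with the twist stiffness scaled to near zero,
  # then a short re-quench so the thermal twist fluctuations (which are
  # huge while the stiffness is off) settle before measuring
  st1 <- run_bd_chunk(st, p, nsteps = 25000, seed = 5, twist_scale = 0.02,
                      limit_move = 1.1)
  tws <- c()
  for (k in 1:5) {
    st1 <- run_bd_chunk(st1, p, nsteps = 3000, seed = 50 + k,
                        limit_move = 1.1)
    tws <- c(tws, twist(st1$chains[[1]]))
  }
  expect_lt(abs(mean(tws)) / 2, 0.15)
  # without the window the injected twist persists far longer
  st2 <- run_bd_chunk(st, p, nsteps = 1000, seed = 6, limit_move = 1.1)
  expect_gt(twist(st2$chains[[1]]), 1)
})
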