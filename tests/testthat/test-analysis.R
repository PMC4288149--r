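# Wrapping quantification, defect taxonomy, digestion, gel, flattening,
# AFM statistics, zig-zag metric, Welch's t-test.

test_that("wrapped_bp reports the canonical and partial wrap lengths", {
  st <- make_fixture("ideal_fibre", seed = 3)
  wa <- wrapped_bp(st, 5)
  expect_equal(wa$wrapped_bp, 147, tolerance = 0.05)
  expect_true(wa$contiguous)
  expect_equal(wa$n_segments, 1L)
  expect_equal(wa$handedness, "left")
  # bare core far from any DNA
  bare <- system_state(build_dna_chain(300, "straight"),
                       list(core_particle(core_geometry(),
                                          c(200, 200, 200))))
  expect_equal(wrapped_bp(bare, 1)$wrapped_bp, 0)
  # half occupancy
  stp <- make_fixture("partial", params = list(occupied_sites = 10L),
                      seed = 2)
  expect_equal(wrapped_bp(stp, 1)$wrapped_bp, 73.5, tolerance = 0.35)
})

test_that("wrapped_bp is monotone under adding a bound bead", {
  st <- make_fixture("partial", params = list(occupied_sites = 10L),
                     seed = 2)
  b10 <- wrapped_bp(st, 1)$wrapped_bp
  st2 <- make_fixture("partial", params = list(occupied_sites = 14L),
                      seed = 2)
  expect_gte(wrapped_bp(st2, 1)$wrapped_bp, b10)
})

test_that("the defect classifier recalls every archetype", {
  kinds <- c("partial", "locked_partial", "loop", "right_handed", "dimer")
  for (kind in kinds) {
    for (s in seq_len(20)) {
      st <- make_fixture(kind, seed = s)
      cls <- classify_defects(st)$class
      want <- if (kind == "dimer") "dimer_cluster" else kind
      expect_true(all(cls == want),
                  label = sprintf("%s seed %d -> %s", kind, s,
                                  paste(cls, collapse = ",")))
    }
  }
  for (s in seq_len(20)) {
    st <- make_fixture("ideal_fibre", params = list(n_cores = 4L), seed = s)
    expect_true(all(classify_defects(st)$class == "correct"),
                label = sprintf("ideal seed %d", s))
  }
})

test_that("class counts always total the number of cores", {
  for (kind in c("ideal_fibre", "dimer", "loop", "nanoparticle_cluster")) {
    st <- make_fixture(kind, seed = 7)
    cd <- classify_defects(st)
    expect_equal(sum(defect_counts(cd)), length(st$cores))
  }
})

test_that("handedness distinguishes mirror wraps and glancing contacts", {
  st <- make_fixture("mononucleosome", seed = 6)
  expect_equal(wrapped_bp(st, 1)$handedness, "left")
  str_ <- make_fixture("right_handed", seed = 6)
  expect_equal(wrapped_bp(str_, 1)$handedness, "right")
  # straight DNA tangent to one site: too little circulation
  g <- core_geometry("octamer")
  fr <- ideal_wrap_frames(g)
  t <- fr$tangents[10, ]
  pos <- fr$positions[rep(10, 8), ] + outer(seq(-3.5, 3.5), t) * 2.5
  ch <- dna_chain(pos)
  expect_equal(wrapped_bp(system_state(ch, list(core_particle(g))),
                          1)$handedness, "indeterminate")
})

test_that("digestion conserves DNA length for any rate and seed", {
  st <- make_fixture("ideal_fibre", seed = 3)
  total <- n_beads(st$chains[[1]]) * 7.35
  for (rate in c(0, 0.2, 2, Inf)) {
    for (s in 1:4) {
      fs <- digest(st, rate, seed = s)
      expect_equal(sum(fs$fragments_bp), total, tolerance = 1e-9)
    }
  }
  fs0 <- digest(st, 0, seed = 1)
  expect_length(fs0$fragments_bp, 1)
  expect_error(digest(st, -1), "rate")
})

test_that("exhaustive digestion leaves mononucleosome-size fragments", {
  st <- make_fixture("ideal_fibre", seed = 3)
  fs <- digest(st, Inf, seed = 2)
  big <- fs$fragments_bp[fs$fragments_bp > 120]
  # one mononucleosome band per core: the protected wrap (within a bead
  # or two of 147 bp) plus the pad and the one leading unprotected bead
  expect_length(big, 10)
  expect_true(all(big > 0.8 * 147 & big < 1.35 * 147))
  modal <- as.numeric(names(sort(table(round(big)), decreasing = TRUE))[1])
  expect_lt(abs(modal - 147) / 147, 0.20)
})

test_that("gel migration is monotone and the ladder is evenly spaced", {
  st <- make_fixture("ideal_fibre", seed = 3)
  frs <- lapply(1:10, function(s) digest(st, 0.12, seed = s))
  gel <- gel_render(frs)
  b <- gel$bands[[1]]
  b <- b[b$bp >= 50, ]  # below the calibration range migration saturates
  expect_true(all(diff(b$migration[order(b$bp)]) < 0))
  # ladder spacing: the centre-to-centre distance between the mono- and
  # di-nucleosome clusters equals the repeat length
  bp <- unlist(lapply(frs, `[[`, "fragments_bp"))
  bp <- bp[bp > 120 & bp < 1000]
  kk <- round(bp / 221)
  expect_true(all(c(1, 2) %in% kk))
  spacing <- mean(bp[kk == 2]) - mean(bp[kk == 1])
  expect_lt(abs(spacing - 221) / 221, 0.15)
})

test_that("ordered fibres give higher gel band contrast than disordered", {
  st <- make_fixture("ideal_fibre", seed = 3)
  frs_o <- lapply(1:8, function(s) digest(st, 0.12, seed = s))
  # disorder the same fibre: displace each core along random directions
  # so the protection pattern loses its regular repeat
  std <- st
  set.seed(41)
  for (i in seq_along(std$cores))
    std$cores[[i]]$position <- std$cores[[i]]$position +
      stats::rnorm(3, sd = 6)
  frs_d <- lapply(1:8, function(s) digest(std, 0.12, seed = s))
  g <- gel_render(c(list(), frs_o))
  gd <- gel_render(frs_d)
  expect_gt(gel_contrast(g), gel_contrast(gd))
})

test_that("flattening preserves connectivity and reaches the slit gap", {
  st <- make_fixture("ideal_fibre", params = list(n_cores = 5L), seed = 8)
  # equilibrate briefly in 3D so before/after compares like with like
  st <- run_bd_chunk(st, ff_params(), nsteps = 5000, seed = 2,
                     limit_move = 1.1)
  fl <- flatten(st, seed = 3)
  expect_true(fl$converged)
  z <- fl$state$chains[[1]]$positions[, 3]
  expect_lt(max(abs(z)), ff_params()$core_diam / 2 + 1.5)
  bl0 <- sqrt(rowSums(diff(st$chains[[1]]$positions)^2))
  bl1 <- sqrt(rowSums(diff(fl$state$chains[[1]]$positions)^2))
  expect_lt(abs(mean(bl1) - mean(bl0)) / mean(bl0), 0.10)
  expect_lt(max(bl1), 1.5 * ff_params()$bond_r0)  # no ruptured bonds
})

test_that("AFM statistics reproduce the constructed fibre geometry", {
  st <- make_fixture("ideal_fibre", params = list(n_cores = 6L,
                                                  jitter = 0.01), seed = 2)
  af <- afm_stats(st)
  expect_length(af$triplet_angle, 4)
  expect_length(af$pairwise_dist, 6 * 5 / 2)
  # collinear centres by construction
  expect_true(all(af$triplet_angle > 150))
  sp <- unique(round(af$nn_dist))
  expect_equal(length(unique(round(af$nn_dist / min(af$nn_dist)))), 1)
  # linker contour: 10 linker beads + boundary bonds at 2.5 nm spacing
  expect_lt(abs(median(af$contour_linker) - 27.5) / 27.5, 0.25)
})

test_that("the zig-zag metric separates rails from beads-on-a-string", {
  zz <- make_fixture("zigzag", seed = 4)
  expect_equal(zigzag_fraction(zz), 1)
  id <- make_fixture("ideal_fibre", seed = 4)
  expect_equal(zigzag_fraction(id), 0)
  for (s in 1:5) {
    v <- zigzag_fraction(make_fixture("zigzag", seed = s))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("welch_t matches the closed-form statistic and its invariances", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3) + 0)$p, 1)
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  t_hand <- (2 - 5) / sqrt(1 / 3 + 1 / 3)
  df_hand <- (1 / 3 + 1 / 3)^2 / ((1 / 3)^2 / 2 + (1 / 3)^2 / 2)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(t_hand, df_hand), tolerance = 1e-12)
  r2 <- welch_t(c(1, 2, 3) + 10, c(4, 5, 6) + 10)
  expect_equal(r2$t, r$t)
  expect_error(welch_t(1, c(1, 2)), "2 values")
  expect_error(welch_t(c(1, 1), c(2, 2)), "separation")
})
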