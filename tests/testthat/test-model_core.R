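# Domain types and geometry builders.

test_that("bead/bp mapping reproduces configured lengths and round-trips", {
  ch <- build_dna_chain(22100, "straight")
  expect_equal(n_beads(ch), 3007)
  ch2 <- build_dna_chain(147, "straight")
  expect_equal(n_beads(ch2), 20)
  for (k in c(1, 7, 300, 3007))
    expect_equal(bp_to_beads(beads_to_bp(k)), k)
  expect_error(build_dna_chain(7), "2 beads")
})

test_that("straight chains have zero bend and zero twist", {
  ch <- build_dna_chain(147, "straight")
  expect_equal(twist(ch), 0, tolerance = 1e-12)
  bf <- bonded_energy_forces(ch)
  expect_equal(unname(bf$terms["bend"]), 0, tolerance = 1e-10)
  expect_equal(unname(bf$terms["twist"]), 0, tolerance = 1e-10)
  validate_chain(ch)
})

test_that("equilibrium coil matches worm-like-chain end-to-end statistics", {
  # internal-distance averaging over many seeds against the WLC closed
  # form <R^2> = 2 lp L - 2 lp^2 (1 - exp(-L/lp))
  lp <- 50
  span <- 50L  # beads per (non-overlapping) sub-chain sample
  L <- (span - 1) * 2.5
  tot <- 0; cnt <- 0
  for (s in 1:200) {
    ch <- build_dna_chain(300 * 7.35, "equilibrium-coil", seed = s)
    P <- ch$positions
    for (o in seq(1, n_beads(ch) - span, by = span)) {
      tot <- tot + sum((P[o + span - 1, ] - P[o, ])^2)
      cnt <- cnt + 1
    }
  }
  wlc <- 2 * lp * L - 2 * lp^2 * (1 - exp(-L / lp))
  expect_lt(abs(tot / cnt - wlc) / wlc, 0.05)
})

test_that("equilibrium coil reproduces the target persistence length", {
  chs <- lapply(1:40, function(s)
    build_dna_chain(300 * 7.35, "equilibrium-coil", seed = s))
  expect_lt(abs(persistence_length(chs) - 50) / 50, 0.05)
})

test_that("octamer site path is left-handed with the full azimuthal sweep", {
  g <- core_geometry("octamer")
  fr <- ideal_wrap_frames(g)
  expect_true(all(diff(fr$azimuths) < 0))
  sweep_deg <- abs(fr$azimuths[g$n_sites] - fr$azimuths[1]) * 180 / pi
  expect_lt(abs(sweep_deg - g$path_turns * 360), 1)
  expect_equal(nrow(fr$positions), 20L)
})

test_that("wrap registry deposits exactly the stored twist", {
  for (s in c(0, 0.4, 0.75)) {
    g <- core_geometry("octamer", stored_twist = s)
    fr <- ideal_wrap_frames(g)
    q <- matrix(0, g$n_sites, 4)
    for (i in seq_len(g$n_sites)) {
      t <- fr$tangents[i, ]; u <- fr$patch_dirs[i, ]
      q[i, ] <- chromassemble:::quat_from_matrix(
        cbind(t, u, chromassemble:::cross3(t, u)))
    }
    ch <- dna_chain(fr$positions, q)
    expect_lt(abs(twist(ch) - s), 1e-6)
  }
})

test_that("nanoparticle geometry has no sites and rejects wrap frames", {
  g <- core_geometry("nanoparticle")
  expect_equal(g$n_sites, 0L)
  expect_equal(nrow(g$site_local_positions), 0L)
  expect_error(ideal_wrap_frames(g), "octamer")
})

test_that("regular placement gives the nucleosome repeat spacing", {
  ch <- build_dna_chain(22100, "straight")
  st <- place_cores(ch, 100, "regular", seed = 1)
  att <- attachment_beads(st)
  sp <- diff(att) * 7.35
  expect_true(all(abs(sp - 221) < 8))   # 221 bp repeat, 74 bp linker
  st0 <- place_cores(ch, 0, "regular")
  expect_length(st0$cores, 0)
})

test_that("random placement keeps cores at least one wrap apart", {
  ch <- build_dna_chain(4410, "straight")
  for (s in 1:10) {
    st <- place_cores(ch, 15, "random", seed = s)
    att <- sort(attachment_beads(st))
    expect_true(all(diff(att) * 7.35 >= 147))
  }
})

test_that("over-dense placement is rejected", {
  ch <- build_dna_chain(735, "straight")  # 100 beads
  expect_error(place_cores(ch, 8, "regular"), "density")
})

test_that("core orientation is normalized and sites follow activation", {
  cp <- core_particle(core_geometry(), orientation = c(2, 1, 0, 0))
  expect_equal(sum(cp$orientation^2), 1, tolerance = 1e-10)
  tet <- activate_sites(cp, "tetramer")
  expect_equal(sum(tet$active_sites), 10L)
  expect_true(all(which(tet$active_sites) == 6:15))
  oct <- activate_sites(tet, "octamer")
  expect_equal(sum(oct$active_sites), 20L)
  expect_identical(activate_sites(tet, "tetramer")$active_sites,
                   tet$active_sites)
  np <- core_particle(core_geometry("nanoparticle"))
  expect_error(activate_sites(np, "tetramer"), "site")
})
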